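# Internal coding conventions (used throughout the package):
#   genotypes: 0, 1, 2 copies of allele "1"; 3 = missing
#   alleles:   0 or 1; 9 = missing/unresolved
GENO_MISSING <- 3L
ALLELE_MISSING <- 9L

#' Read a genotype file
#'
#' One whitespace-delimited row per genotyped individual: the identifier
#' followed by one code per SNP. Codes outside `{0, 1, 2}` (including the
#' on-disk missing code, 9 by default) are stored internally as 3 (missing).
#'
#' @param path path to the genotype file.
#' @param missing_code integer code used for missing genotypes on disk
#'   (default 9).
#' @param ped optional [pedigree]; row ids absent from it trigger a warning.
#' @param strict if `TRUE`, codes that are neither valid genotypes nor the
#'   missing code raise an error instead of being treated as missing.
#' @return Integer matrix (individuals x SNP, codes 0/1/2/3) with rownames.
#' @export
load_genotypes <- function(path, missing_code = 9L, ped = NULL, strict = FALSE) {
  dt <- data.table::fread(path, header = FALSE, colClasses = list(character = 1))
  if (nrow(dt) == 0) stop("empty genotype file: ", path)
  ids <- dt[[1]]
  g <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  if (anyNA(g)) stop("non-numeric or ragged genotype rows in ", path,
                     " (first bad row: ", which(rowSums(is.na(g)) > 0)[1], ")")
  bad <- !(g %in% c(0L, 1L, 2L)) & g != missing_code
  if (strict && any(bad)) {
    stop("invalid genotype code(s) at row ",
         which(rowSums(matrix(bad, nrow(g))) > 0)[1])
  }
  g[bad | g == missing_code] <- GENO_MISSING
  dimnames(g) <- list(ids, NULL)
  if (!is.null(ped)) {
    unknown <- setdiff(ids, ped$id)
    if (length(unknown)) {
      warning(length(unknown), " genotyped individual(s) absent from pedigree: ",
              paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  g
}

#' Read a SNP map file
#'
#' Whitespace-delimited columns: snp_id, chromosome, position. Chromosome
#' `"0"` marks unmapped SNP, which are handled by the peeling-only path and
#' excluded from long-range phasing.
#'
#' @param path path to the map file.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`, `mapped`.
#' @export
load_snp_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("snp_id", "chrom", "pos"))
  df$chrom <- as.character(df$chrom)
  df$mapped <- df$chrom != "0"
  df
}

#' Per-SNP allele frequency
#'
#' Frequency of allele "1" from non-missing genotypes, with a half-count
#' shrinkage towards 0.5 so that monomorphic SNP never get a degenerate
#' founder prior. By convention frequencies are estimated from the
#' high-density animals only; low-density animals observe a MAF-biased
#' subset of loci.
#'
#' @param geno genotype matrix (codes 0/1/2/3).
#' @param rows optional row subset (ids or indices) to estimate from.
#' @return Numeric vector of allele-1 frequencies in (0, 1).
#' @export
snp_allele_freq <- function(geno, rows = NULL) {
  if (!is.null(rows)) geno <- geno[rows, , drop = FALSE]
  obs <- geno != GENO_MISSING
  cnt <- colSums(geno * obs)
  n2 <- 2 * colSums(obs)
  (cnt + 0.5) / (n2 + 1)
}

#' Split genotyped animals into high- and low-density sets
#'
#' An individual is high density when its fraction of non-missing SNP is at
#' least `hd_threshold`; remaining genotyped individuals (at least one
#' non-missing SNP) form the low-density set. Ungenotyped individuals belong
#' to neither.
#'
#' @param geno genotype matrix.
#' @param hd_threshold fraction in (0, 1] (default 0.9).
#' @return `list(hd = <ids>, ld = <ids>)`.
#' @export
split_density <- function(geno, hd_threshold = 0.9) {
  stopifnot(hd_threshold > 0, hd_threshold <= 1)
  frac <- rowMeans(geno != GENO_MISSING)
  list(hd = rownames(geno)[frac >= hd_threshold],
       ld = rownames(geno)[frac > 0 & frac < hd_threshold])
}

#' Check genotypes for Mendelian inconsistencies
#'
#' A conflict is a parent and offspring homozygous for opposite alleles at
#' the same SNP (0 vs 2). Both members of every conflicting pair are set to
#' missing in the cleaned matrix, so a second pass finds no conflicts.
#'
#' @param ped a [pedigree] object.
#' @param geno genotype matrix with rownames present in the pedigree.
#' @return `list(conflicts = data.frame(individual, parent, snp),
#'   geno = cleaned matrix)`.
#' @export
check_mendelian <- function(ped, geno) {
  stopifnot(inherits(ped, "pedigree"))
  row_of <- match(ped$id, rownames(geno))   # pedigree index -> geno row or NA
  conflicts <- list()
  clean <- geno
  for (side in c("sire", "dam")) {
    par_idx <- ped[[side]]
    has <- par_idx > 0L & !is.na(row_of) & !is.na(row_of[pmax(par_idx, 1L)])
    if (!any(has)) next
    ci <- row_of[has]
    pi <- row_of[par_idx[has]]
    gc <- geno[ci, , drop = FALSE]
    gp <- geno[pi, , drop = FALSE]
    bad <- (gp == 0L & gc == 2L) | (gp == 2L & gc == 0L)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)
      conflicts[[side]] <- data.frame(
        individual = rownames(geno)[ci[w[, 1]]],
        parent = rownames(geno)[pi[w[, 1]]],
        snp = w[, 2],
        stringsAsFactors = FALSE
      )
      clean[cbind(ci[w[, 1]], w[, 2])] <- GENO_MISSING
      clean[cbind(pi[w[, 1]], w[, 2])] <- GENO_MISSING
    }
  }
  conf <- if (length(conflicts)) do.call(rbind, unname(conflicts)) else
    data.frame(individual = character(), parent = character(), snp = integer())
  rownames(conf) <- NULL
  list(conflicts = conf, geno = clean)
}

#' Routine SNP editing
#'
#' Drops SNP with minor allele frequency below `maf_min` or missing rate
#' above `miss_max`, computed on the given rows (typically the high-density
#' set).
#'
#' @param geno genotype matrix.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param miss_max maximum missing rate (default 0.1).
#' @param rows optional row subset used for the statistics.
#' @return Integer vector of retained SNP indices.
#' @export
edit_snps <- function(geno, maf_min = 0.01, miss_max = 0.1, rows = NULL) {
  g <- if (is.null(rows)) geno else geno[rows, , drop = FALSE]
  p <- snp_allele_freq(g)
  maf <- pmin(p, 1 - p)
  miss <- colMeans(g == GENO_MISSING)
  which(maf >= maf_min & miss <= miss_max)
}

#' Design a low-density SNP panel
#'
#' Reproduces the window-based panel design used for testing: the mapped SNP
#' are tiled into contiguous 5-SNP windows, enough evenly spaced windows are
#' selected to reach the target retained count, and from each selected window
#' the SNP with the highest minor allele frequency is retained (ties broken
#' by lower index). When more SNP are needed than there are windows, further
#' rounds take the next-best SNP per window.
#'
#' @param geno genotype matrix (used for MAF; see `rows`).
#' @param masked_fraction fraction of mapped SNP to mask, in \[0, 1).
#' @param rows rows used to compute MAF (default all; give the HD set).
#' @param mapped optional integer indices of mapped SNP (default: all).
#' @param window window size in SNP (default 5).
#' @return `list(retained = <sorted SNP indices>, masked_fraction = <value>)`.
#' @export
design_low_density_panel <- function(geno, masked_fraction, rows = NULL,
                                     mapped = NULL, window = 5L) {
  stopifnot(masked_fraction >= 0, masked_fraction < 1)
  if (is.null(mapped)) mapped <- seq_len(ncol(geno))
  n_map <- length(mapped)
  n_retain <- round((1 - masked_fraction) * n_map)
  if (n_retain < 1) stop("panel design retains fewer than 1 SNP")
  p <- snp_allele_freq(geno, rows)[mapped]
  maf <- pmin(p, 1 - p)
  win_of <- (seq_len(n_map) - 1L) %/% window + 1L   # final window may be short
  n_win <- max(win_of)
  # within-window order: MAF descending, ties to the lower index
  ord <- order(win_of, -maf, seq_len(n_map))
  by_win <- split(ord, win_of[ord])
  if (n_retain <= n_win) {
    sel <- round(seq(1, n_win, length.out = n_retain))
    keep <- vapply(by_win[sel], `[`, integer(1), 1L)
  } else {
    keep <- integer(0)
    round_k <- 1L
    while (length(keep) < n_retain) {
      layer <- unlist(lapply(by_win, function(w) if (length(w) >= round_k) w[round_k]))
      layer <- layer[seq_len(min(length(layer), n_retain - length(keep)))]
      if (!length(layer)) break
      keep <- c(keep, layer)
      round_k <- round_k + 1L
    }
  }
  list(retained = sort(mapped[keep]), masked_fraction = masked_fraction)
}

#' Apply a panel design to a genotype matrix
#'
#' Masks (sets to missing) all SNP outside the panel for the given rows.
#'
#' @param geno genotype matrix.
#' @param panel result of [design_low_density_panel()].
#' @param rows rows (ids or indices) to mask; default all rows.
#' @return The masked genotype matrix.
#' @export
apply_panel <- function(geno, panel, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(geno))
  drop_snp <- setdiff(seq_len(ncol(geno)), panel$retained)
  geno[rows, drop_snp] <- GENO_MISSING
  geno
}

fmt_allele <- function(m) {
  m[m == ALLELE_MISSING] <- 9L
  m
}

#' Write imputation outputs
#'
#' Writes three plain-text files to `dir`, each row starting with the
#' individual identifier:
#' \describe{
#'   \item{phased_alleles.txt}{two rows per individual (paternal then
#'     maternal gamete); alleles 0/1, 9 where unresolved.}
#'   \item{allele_probs.txt}{two rows per individual; probability that the
#'     allele is 1, 4 decimals.}
#'   \item{dosages.txt}{one row per individual; expected allele-1 count in
#'     \[0, 2\], 4 decimals.}
#' }
#'
#' @param phase `list(pat, mat)` integer matrices (0/1/9) with rownames.
#' @param probs `list(pat, mat)` numeric matrices of P(allele = 1).
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(phase, probs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(phase$pat)
  ids <- rownames(phase$pat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  interleave <- function(a, b) {
    out <- matrix(NA, 2L * n, ncol(a))
    out[seq(1, 2 * n, 2), ] <- a
    out[seq(2, 2 * n, 2), ] <- b
    out
  }
  paths <- file.path(dir, c("phased_alleles.txt", "allele_probs.txt", "dosages.txt"))
  ph <- interleave(fmt_allele(phase$pat), fmt_allele(phase$mat))
  data.table::fwrite(data.table::data.table(id = rep(ids, each = 2), ph),
                     paths[1], sep = " ", col.names = FALSE)
  fmt4 <- function(m) {
    out <- sprintf("%.4f", m)
    dim(out) <- dim(m)
    out
  }
  pr <- interleave(fmt4(probs$pat), fmt4(probs$mat))
  data.table::fwrite(data.table::data.table(id = rep(ids, each = 2), pr),
                     paths[2], sep = " ", col.names = FALSE, quote = FALSE)
  dos <- fmt4(probs$pat + probs$mat)
  data.table::fwrite(data.table::data.table(id = ids, dos),
                     paths[3], sep = " ", col.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a phased-allele file
#'
#' Inverse of the phased-allele output of [write_outputs()]; also the format
#' accepted for externally phased input (two rows per individual, paternal
#' gamete first, parental origin known).
#'
#' @param path path to the file.
#' @return `list(pat, mat)` integer matrices (codes 0/1/9) with rownames.
#' @export
read_phase <- function(path) {
  dt <- data.table::fread(path, header = FALSE, colClasses = list(character = 1))
  ids <- dt[[1]][seq(1, nrow(dt), 2)]
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  pat <- m[seq(1, nrow(m), 2), , drop = FALSE]
  mat <- m[seq(2, nrow(m), 2), , drop = FALSE]
  dimnames(pat) <- dimnames(mat) <- list(ids, NULL)
  list(pat = pat, mat = mat)
}
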