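#' Phasing configuration
#'
#' Settings for long-range phasing and haplotype-library construction of the
#' high-density animals.
#'
#' @param core_length core size in SNP (default 100).
#' @param n_rounds number of phasing rounds with shifted core boundaries
#'   (default 4); overlapping cores across rounds let phasing errors be
#'   detected by disagreement.
#' @param max_mismatch opposing-homozygote loci tolerated when declaring a
#'   surrogate within a core (default 0).
#' @param min_agree minimum number of informative surrogates required to
#'   phase a heterozygous locus (default 1).
#' @param min_complete minimum resolved alleles a partial gamete needs
#'   before unique-match library completion is attempted (default 20;
#'   guards short edge cores against spurious completions).
#' @param surrogate_flank extra SNP on each side of a core over which
#'   surrogacy is declared (default one core length): identity by descent
#'   produces long shared segments, so screening for opposing homozygotes
#'   well beyond the core separates true haplotype sharing from chance
#'   compatibility.
#' @return A list of class `phase_config`.
#' @export
phase_config <- function(core_length = 100L, n_rounds = 4L,
                         max_mismatch = 0L, min_agree = 1L,
                         min_complete = 20L, surrogate_flank = core_length) {
  stopifnot(core_length >= 10, n_rounds >= 1, max_mismatch >= 0, min_agree >= 1)
  structure(list(core_length = as.integer(core_length),
                 n_rounds = as.integer(n_rounds),
                 max_mismatch = as.integer(max_mismatch),
                 min_agree = as.integer(min_agree),
                 min_complete = as.integer(min_complete),
                 surrogate_flank = as.integer(surrogate_flank)),
            class = "phase_config")
}

#' Build the core layouts for all phasing rounds
#'
#' Round `r` (0-based) shifts the core boundaries by
#' `floor(r * core_length / n_rounds)` SNP, so every SNP is phased as part of
#' differently bounded cores across rounds. First and last cores may be
#' short; every SNP belongs to exactly one core per round.
#'
#' @param n_snp number of SNP on the chromosome.
#' @param core_length core size in SNP.
#' @param n_rounds number of rounds.
#' @return List (one element per round) of data frames with columns
#'   `lo`, `hi` (1-based, inclusive SNP indices).
#' @export
build_core_layout <- function(n_snp, core_length = 100L, n_rounds = 1L) {
  stopifnot(n_snp >= 1, core_length >= 1, n_rounds >= 1)
  lapply(seq_len(n_rounds) - 1L, function(r) {
    off <- floor(r * core_length / n_rounds)
    if (n_snp <= core_length) return(data.frame(lo = 1L, hi = n_snp))
    starts <- unique(c(1L, seq.int(off + 1L, n_snp, core_length)))
    starts <- starts[starts <= n_snp]
    data.frame(lo = starts, hi = c(starts[-1] - 1L, n_snp))
  })
}

#' Classify surrogate sides from the pedigree
#'
#' For every high-density animal, classifies every other high-density animal
#' as a paternal-side or maternal-side relative, or unassignable, by
#' exhaustive ancestor walk: a candidate lies on the paternal side when its
#' ancestor set (including itself) meets the sire's ancestor set but not the
#' dam's, and the candidate does not descend from the target (descendants
#' share the target's own gametes, not a parental gamete).
#'
#' @param ped a [pedigree] object.
#' @param hd_ids identifiers of high-density animals.
#' @return Integer matrix n x n (pedigree order): 0 unassigned, 1 paternal,
#'   2 maternal; rows are targets, columns candidates.
#' @export
surrogate_sides <- function(ped, hd_ids) {
  hd <- ped$id %in% hd_ids
  .surrogate_sides_cpp(ped$sire, ped$dam, hd)
}

#' Find surrogate parents within a SNP region
#'
#' Surrogates of a target are high-density animals with at most
#' `max_mismatch` opposing-homozygote loci versus the target within the
#' region, assigned to the paternal or maternal side by the pedigree
#' ([surrogate_sides()]); genotyped parents are always surrogates of their
#' side. Candidates whose side cannot be determined are not used.
#'
#' @param geno pedigree-aligned genotype matrix (n x L).
#' @param ped a [pedigree].
#' @param region integer `c(lo, hi)`, 1-based inclusive SNP interval.
#' @param max_mismatch opposing-homozygote tolerance (default 0).
#' @param hd_ids high-density animal identifiers.
#' @param targets identifiers to find surrogates for (default `hd_ids`).
#' @param sides optional precomputed [surrogate_sides()] matrix.
#' @return List with `pat` and `mat`: per target, integer vectors of
#'   pedigree row indices of its surrogates.
#' @export
find_surrogates <- function(geno, ped, region, max_mismatch = 0L,
                            hd_ids = rownames(geno), targets = hd_ids,
                            sides = NULL) {
  if (is.null(sides)) sides <- surrogate_sides(ped, hd_ids)
  t_idx <- ped_index(ped, targets)
  .find_surrogates_cpp(geno, sides, ped$sire, ped$dam, t_idx,
                       as.integer(region[1]), as.integer(region[2]),
                       as.integer(max_mismatch))
}

#' Phase one core by surrogate consensus
#'
#' Homozygous genotypes phase themselves. At a heterozygous locus the
#' paternal allele is set when every informative paternal surrogate (one
#' homozygous at that locus) agrees and at least `min_agree` are informative;
#' the maternal allele is the complement (and symmetrically for the maternal
#' side). Conflicting surrogate evidence leaves the locus unphased.
#'
#' @param geno pedigree-aligned genotype matrix.
#' @param surrogates result of [find_surrogates()] for `targets`.
#' @param core `c(lo, hi)` SNP interval.
#' @param targets identifiers being phased.
#' @param ped the [pedigree].
#' @param min_agree minimum informative surrogates (default 1).
#' @return `list(pat, mat)`: integer matrices n x core-length (codes 0/1/9).
#' @export
phase_core <- function(geno, surrogates, core, targets, ped, min_agree = 1L) {
  t_idx <- ped_index(ped, targets)
  .phase_core_cpp(geno, surrogates$pat, surrogates$mat, t_idx,
                  as.integer(core[1]), as.integer(core[2]),
                  as.integer(min_agree))
}

#' Build a haplotype library for a core
#'
#' Inserts every fully resolved gamete-haplotype over the core, counting
#' duplicates once per gamete carrying them. Partially resolved gametes are
#' first completed against the growing library when exactly one library
#' haplotype matches all their resolved positions.
#'
#' @param pat,mat n x core-length allele matrices (codes 0/1/9) as returned
#'   by [phase_core()].
#' @param rows integer row indices contributing gametes (the HD animals).
#' @param complete logical; run unique-match completion (default `TRUE`).
#' @param min_complete minimum resolved alleles required before a gamete is
#'   eligible for completion (default 1).
#' @return List with `haps` (distinct haplotype matrix H x core-length),
#'   `counts` (integer H), and `pat`, `mat` (the, possibly completed,
#'   inputs).
#' @export
build_library <- function(pat, mat, rows, complete = TRUE, min_complete = 1L) {
  gam <- rbind(pat[rows, , drop = FALSE], mat[rows, , drop = FALSE])
  tab_lib <- function(g) {
    full <- rowSums(g == ALLELE_MISSING) == 0
    if (!any(full)) {
      return(list(haps = matrix(0L, 0, ncol(g)), counts = integer(0)))
    }
    gf <- g[full, , drop = FALSE]
    key <- do.call(paste0, lapply(seq_len(ncol(gf)), function(j) gf[, j]))
    first <- !duplicated(key)
    haps <- gf[first, , drop = FALSE]
    list(haps = haps, counts = tabulate(match(key, key[first])))
  }
  lib <- tab_lib(gam)
  if (complete && nrow(lib$haps) > 0) {
    cg <- .complete_gametes_cpp(gam, lib$haps, as.integer(min_complete))
    gam <- cg$gam
    lib <- tab_lib(gam)
  }
  m <- length(rows)
  list(haps = lib$haps, counts = lib$counts,
       pat = gam[seq_len(m), , drop = FALSE],
       mat = gam[m + seq_len(m), , drop = FALSE])
}

#' Long-range phasing and haplotype-library construction
#'
#' Phases every high-density animal over shifted core tilings
#' (`n_rounds` rounds), builds a haplotype library per core, completes
#' partial gametes against the library, and resolves base animals (who have
#' no parental side to orient against) into unordered haplotype pairs per
#' core by finding the unique genotype-consistent pair of library
#' haplotypes. Phase calls that disagree between rounds are treated as
#' phasing errors and removed.
#'
#' Externally phased animals (`phased_input`) are taken as ground truth and
#' skipped by the surrogate machinery; their haplotypes still enter the
#' libraries.
#'
#' @param ped a [pedigree].
#' @param geno genotype matrix (rows = genotyped animals).
#' @param hd_ids high-density animal identifiers.
#' @param cfg a [phase_config()].
#' @param phased_input optional `list(pat, mat)` of externally phased
#'   alleles (rownames = animal ids, parental origin known).
#' @return Object of class `phase_result`: list with merged oriented `pat`,
#'   `mat` (n x L, codes 0/1/9), and `rounds` — per round a list
#'   `(layout, A, B, libs)` where `A`/`B` hold each animal's per-core
#'   haplotype pair (oriented animals: paternal/maternal; base animals:
#'   arbitrary per-core order) and `libs` is one library per core.
#' @export
phase_hd <- function(ped, geno, hd_ids, cfg = phase_config(),
                     phased_input = NULL) {
  g <- align_genotypes(ped, geno)
  n <- nrow(g); L <- ncol(g)
  hd_idx <- ped_index(ped, hd_ids)
  base_idx <- hd_idx[ped$sire[hd_idx] == 0L & ped$dam[hd_idx] == 0L]
  sides <- surrogate_sides(ped, hd_ids)
  layouts <- build_core_layout(L, cfg$core_length, cfg$n_rounds)

  ext_rows <- integer(0)
  if (!is.null(phased_input)) {
    ext_rows <- ped_index(ped, rownames(phased_input$pat))
  }

  merged_pat <- merged_mat <- matrix(ALLELE_MISSING, n, L,
                                     dimnames = list(ped$id, NULL))
  merge_in <- function(merged, new, rows) {
    m <- merged[rows, , drop = FALSE]; v <- new[rows, , drop = FALSE]
    fresh <- m == ALLELE_MISSING & v != ALLELE_MISSING
    clash <- m != ALLELE_MISSING & m != -1L & v != ALLELE_MISSING & v != m
    m[fresh] <- v[fresh]
    m[clash] <- -1L
    merged[rows, ] <- m
    merged
  }

  rounds <- vector("list", cfg$n_rounds)
  for (r in seq_len(cfg$n_rounds)) {
    layout <- layouts[[r]]
    A <- B <- matrix(ALLELE_MISSING, n, L, dimnames = list(ped$id, NULL))
    libs <- vector("list", nrow(layout))
    for (ci in seq_len(nrow(layout))) {
      lo <- layout$lo[ci]; hi <- layout$hi[ci]
      flo <- max(1L, lo - cfg$surrogate_flank)
      fhi <- min(L, hi + cfg$surrogate_flank)
      surr <- .find_surrogates_cpp(g, sides, ped$sire, ped$dam, hd_idx,
                                   flo, fhi, cfg$max_mismatch)
      pc <- .phase_core_cpp(g, surr$pat, surr$mat, hd_idx, lo, hi,
                            cfg$min_agree)
      if (length(ext_rows)) {
        pc$pat[ext_rows, ] <- phased_input$pat[, lo:hi, drop = FALSE]
        pc$mat[ext_rows, ] <- phased_input$mat[, lo:hi, drop = FALSE]
      }
      # completion loop: each pass enriches the library, which lets further
      # gametes and base-animal pairs be completed on the next pass
      nonbase_t <- setdiff(hd_idx, base_idx)
      for (pass in 1:3) {
        lib <- build_library(pc$pat, pc$mat, hd_idx, complete = FALSE)
        if (nrow(lib$haps) == 0) break
        resolved_before <- sum(pc$pat[hd_idx, ] != ALLELE_MISSING) +
          sum(pc$mat[hd_idx, ] != ALLELE_MISSING)
        # joint pair completion: candidate pairs must fit both gametes'
        # resolved alleles and the genotype, which ties the two gametes
        # together at heterozygous loci
        cp <- .complete_pairs_cpp(pc$pat[nonbase_t, , drop = FALSE],
                                  pc$mat[nonbase_t, , drop = FALSE],
                                  g[nonbase_t, lo:hi, drop = FALSE], lib$haps)
        pc$pat[nonbase_t, ] <- cp$A
        pc$mat[nonbase_t, ] <- cp$B
        # base animals: partial unordered-pair resolution from the library
        unres <- setdiff(base_idx, ext_rows)
        unres <- unres[rowSums(pc$pat[unres, , drop = FALSE] ==
                                 ALLELE_MISSING) > 0]
        if (length(unres)) {
          rp <- .resolve_pairs_cpp(g[unres, lo:hi, drop = FALSE], lib$haps)
          Ai <- pc$pat[unres, , drop = FALSE]
          Bi <- pc$mat[unres, , drop = FALSE]
          wa <- Ai == ALLELE_MISSING & rp$A != ALLELE_MISSING
          wb <- Bi == ALLELE_MISSING & rp$B != ALLELE_MISSING
          Ai[wa] <- rp$A[wa]; Bi[wb] <- rp$B[wb]
          pc$pat[unres, ] <- Ai
          pc$mat[unres, ] <- Bi
        }
        resolved_after <- sum(pc$pat[hd_idx, ] != ALLELE_MISSING) +
          sum(pc$mat[hd_idx, ] != ALLELE_MISSING)
        if (resolved_after == resolved_before) break
      }
      lib <- build_library(pc$pat, pc$mat, hd_idx, complete = FALSE)
      A[, lo:hi] <- pc$pat
      B[, lo:hi] <- pc$mat
      libs[[ci]] <- list(haps = lib$haps, counts = lib$counts)
      # oriented (non-base) phase feeds the cross-round merged calls
      nb <- setdiff(hd_idx, base_idx)
      merged_pat[, lo:hi] <- merge_in(merged_pat[, lo:hi, drop = FALSE], pc$pat, nb)
      merged_mat[, lo:hi] <- merge_in(merged_mat[, lo:hi, drop = FALSE], pc$mat, nb)
      # base-animal homozygous loci are orientation-free
      if (length(base_idx)) {
        hom <- pc$pat[base_idx, , drop = FALSE] ==
          pc$mat[base_idx, , drop = FALSE] &
          pc$pat[base_idx, , drop = FALSE] != ALLELE_MISSING
        sub <- merged_pat[base_idx, lo:hi, drop = FALSE]
        sub[hom] <- pc$pat[base_idx, , drop = FALSE][hom]
        merged_pat[base_idx, lo:hi] <- sub
        merged_mat[base_idx, lo:hi] <- sub
      }
    }
    rounds[[r]] <- list(layout = layout, A = A, B = B, libs = libs)
  }
  merged_pat[merged_pat == -1L] <- ALLELE_MISSING
  merged_mat[merged_mat == -1L] <- ALLELE_MISSING
  if (length(ext_rows)) {
    merged_pat[ext_rows, ] <- phased_input$pat
    merged_mat[ext_rows, ] <- phased_input$mat
  }
  structure(list(pat = merged_pat, mat = merged_mat, rounds = rounds,
                 hd_ids = ped$id[hd_idx], base_ids = ped$id[base_idx],
                 cfg = cfg),
            class = "phase_result")
}
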