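#' Construct a pedigree object
#'
#' Builds a validated pedigree from parallel vectors of individual, sire and
#' dam identifiers. Identifiers are opaque strings; `"0"` (or `NA`) denotes an
#' unknown parent. Parents that are referenced but never listed as individuals
#' are appended automatically as founders. Individuals are re-ordered
#' topologically (oldest first) so that every known parent precedes its
#' offspring, which is the evaluation order used by all downstream algorithms.
#'
#' @param id character vector of individual identifiers (must be unique).
#' @param sire,dam character vectors of parent identifiers, `"0"`/`NA` for
#'   unknown.
#' @return An object of class `pedigree`: a list with elements
#'   \describe{
#'     \item{id}{character vector of identifiers, topological order}
#'     \item{sire,dam}{integer indices into `id` (0 = unknown)}
#'     \item{rank}{integer generation rank, 0 for founders,
#'       `rank(child) > rank(parent)` for every known parent}
#'   }
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
#' identify_base_animals(ped)
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  stopifnot(length(sire) == length(id), length(dam) == length(id))
  sire[is.na(sire)] <- "0"
  dam[is.na(dam)] <- "0"
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s) in pedigree: ",
         paste(unique(id[duplicated(id)])[1:min(5, sum(duplicated(id)))],
               collapse = ", "))
  }
  if (any(id == "0")) stop("\"0\" is reserved for unknown parents and cannot be an individual id")

  # append referenced-but-unlisted parents as founders
  referenced <- setdiff(unique(c(sire, dam)), c("0", id))
  if (length(referenced)) {
    id <- c(id, referenced)
    sire <- c(sire, rep("0", length(referenced)))
    dam <- c(dam, rep("0", length(referenced)))
  }

  n <- length(id)
  idx <- stats::setNames(seq_len(n), id)
  si <- ifelse(sire == "0", 0L, idx[sire])
  di <- ifelse(dam == "0", 0L, idx[dam])

  # Kahn's algorithm: topological sort, detect cycles, assign generation rank
  rank <- rep(NA_integer_, n)
  n_par <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(n_par == 0L)
  rank[queue] <- 0L
  head <- 1L
  order_out <- integer(0)
  pending <- n_par
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      r <- rank[v] + 1L
      if (is.na(rank[ch]) || rank[ch] < r) rank[ch] <- r
      pending[ch] <- pending[ch] - 1L
      if (pending[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n) {
    bad <- id[setdiff(seq_len(n), order_out)][1]
    stop("pedigree contains a cycle involving individual \"", bad, "\"")
  }

  ord <- order(rank, seq_len(n))
  new_idx <- integer(n)
  new_idx[ord] <- seq_len(n)
  remap <- function(v) {
    v <- v[ord]
    v[v > 0L] <- new_idx[v[v > 0L]]
    v
  }
  out <- list(
    id   = id[ord],
    sire = remap(si),
    dam  = remap(di),
    rank = rank[ord]
  )
  class(out) <- "pedigree"
  out
}

#' Read a pedigree file
#'
#' Reads a whitespace-delimited pedigree file with columns
#' (individual, sire, dam); unknown parents are coded `0`. Extra columns are
#' ignored.
#'
#' @param path path to the pedigree file.
#' @param header logical; skip a header row (default `FALSE`).
#' @return A [pedigree] object in topological (oldest-first) order.
#' @export
load_pedigree <- function(path, header = FALSE) {
  df <- utils::read.table(path, header = header, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("pedigree file must have at least 3 columns (id, sire, dam)")
  pedigree(df[[1]], df[[2]], df[[3]])
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", length(x$id), " individuals, ",
      sum(x$sire == 0L & x$dam == 0L), " base animals, max generation rank ",
      max(x$rank, 0L), "\n", sep = "")
  invisible(x)
}

#' Number of individuals in a pedigree
#' @param ped a [pedigree] object.
#' @export
n_individuals <- function(ped) length(ped$id)

#' Identify base animals
#'
#' Base animals are pedigree members with both parents unknown; they anchor
#' the founder allele-frequency prior in segregation analysis and receive the
#' arbitrary paternal/maternal labelling during haplotype assembly.
#'
#' @param ped a [pedigree] object.
#' @return Character vector of base-animal identifiers.
#' @export
identify_base_animals <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$id[ped$sire == 0L & ped$dam == 0L]
}

ped_index <- function(ped, ids) {
  i <- match(as.character(ids), ped$id)
  if (anyNA(i)) stop("unknown individual(s): ",
                     paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
  i
}

#' Classify relationship to the nearest high-density genotyped ancestors
#'
#' Test animals are categorised by which of their closest ancestors carry
#' high-density genotypes, the pattern that drives imputation accuracy:
#' `BothParents` (sire and dam), `SireMGS` (sire and maternal grandsire),
#' `DamPGS` (dam and paternal grandsire), `Sire`, `Dam`, or `Other`.
#' Overlapping conditions resolve in that order of precedence.
#'
#' @param ped a [pedigree] object.
#' @param hd_set character vector of high-density genotyped identifiers.
#' @param ids individuals to classify (default: every pedigree member).
#' @return A factor with levels
#'   `BothParents, SireMGS, DamPGS, Sire, Dam, Other`.
#' @export
classify_ancestry <- function(ped, hd_set, ids = ped$id) {
  stopifnot(inherits(ped, "pedigree"))
  i <- ped_index(ped, ids)
  hd <- ped$id %in% as.character(hd_set)
  in_hd <- function(j) j > 0L & hd[pmax(j, 1L)]
  s <- ped$sire[i]
  d <- ped$dam[i]
  mgs <- ifelse(d > 0L, ped$sire[pmax(d, 1L)], 0L)   # maternal grandsire
  pgs <- ifelse(s > 0L, ped$sire[pmax(s, 1L)], 0L)   # paternal grandsire
  lab <- rep("Other", length(i))
  lab[in_hd(d)] <- "Dam"
  lab[in_hd(s)] <- "Sire"
  lab[in_hd(d) & in_hd(pgs)] <- "DamPGS"
  lab[in_hd(s) & in_hd(mgs)] <- "SireMGS"
  lab[in_hd(s) & in_hd(d)] <- "BothParents"
  factor(lab, levels = c("BothParents", "SireMGS", "DamPGS", "Sire", "Dam", "Other"))
}
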