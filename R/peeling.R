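#' Peeling configuration
#'
#' Settings for single-locus segregation analysis. The call threshold is the
#' posterior allele probability above which an allele is hard-called
#' (imputed as 0 or 1); probabilities below the threshold are retained as
#' real-valued allele probabilities.
#'
#' @param call_threshold probability above which alleles are called
#'   (default 0.99; must lie in (0.5, 1)).
#' @param max_iterations maximum peeling sweeps per locus (default 20).
#' @param convergence_tol stop when no genotype probability changes by more
#'   than this between sweeps (default 1e-4).
#' @param allele_freq optional per-SNP allele-1 frequency vector; estimated
#'   from the high-density genotypes when `NULL`.
#' @return A list of class `peel_config`.
#' @export
peel_config <- function(call_threshold = 0.99, max_iterations = 20L,
                        convergence_tol = 1e-4, allele_freq = NULL) {
  stopifnot(call_threshold > 0.5, call_threshold < 1,
            max_iterations >= 1, convergence_tol > 0)
  structure(list(call_threshold = call_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 allele_freq = allele_freq),
            class = "peel_config")
}

#' Penetrance of an observed genotype
#'
#' Unnormalised likelihood of each ordered genotype state
#' (paternal, maternal) in \{(0,0), (0,1), (1,0), (1,1)\} given an observed
#' genotype code.
#'
#' @param observed genotype code in \{0, 1, 2, 3\} (3 = missing).
#' @return Numeric vector of length 4.
#' @export
penetrance <- function(observed) {
  stopifnot(length(observed) == 1, observed %in% 0:3)
  switch(as.character(observed),
         "0" = c(1, 0, 0, 0),
         "1" = c(0, 0.5, 0.5, 0),
         "2" = c(0, 0, 0, 1),
         "3" = c(0.25, 0.25, 0.25, 0.25))
}

# genotype matrix aligned to pedigree rows (ungenotyped individuals all-missing)
align_genotypes <- function(ped, geno) {
  n <- length(ped$id)
  out <- matrix(GENO_MISSING, n, ncol(geno), dimnames = list(ped$id, NULL))
  hit <- match(rownames(geno), ped$id)
  ok <- !is.na(hit)
  out[hit[ok], ] <- geno[ok, , drop = FALSE]
  out
}

#' Peel all loci of a pedigree
#'
#' Runs iterative single-locus peeling (anterior and posterior sweeps to a
#' fixed point) for every SNP independently, producing ordered-genotype
#' probabilities for every individual. Founders take a Hardy-Weinberg prior
#' at the locus allele frequency; Mendelian transmission links parents and
#' offspring. Exact on loop-free pedigrees; approximate, with damping, when
#' the pedigree contains loops. An individual whose observation leads to a
#' zero-probability deadlock has that observation reset to missing with a
#' warning.
#'
#' @param ped a [pedigree] object.
#' @param geno genotype matrix (rows are genotyped individuals; rownames are
#'   matched against the pedigree, missing individuals are treated as
#'   ungenotyped).
#' @param cfg a [peel_config()].
#' @return Object of class `peel_result`: list with `post` (array
#'   individuals x SNP x 4 ordered-genotype probabilities, dimnames on
#'   individuals), `allele_freq`, `iterations`, `resets`.
#' @export
peel_genotypes <- function(ped, geno, cfg = peel_config()) {
  stopifnot(inherits(ped, "pedigree"))
  g <- align_genotypes(ped, geno)
  p <- cfg$allele_freq
  if (is.null(p)) p <- snp_allele_freq(geno)
  stopifnot(length(p) == ncol(g), all(p > 0), all(p < 1))
  res <- .peel_all_cpp(ped$sire, ped$dam, g, p,
                       cfg$convergence_tol, cfg$max_iterations)
  if (res$resets > 0) {
    warning(res$resets, " zero-probability deadlock(s): observations reset to missing")
  }
  dimnames(res$post) <- list(ped$id, NULL, NULL)
  structure(list(post = res$post, allele_freq = p,
                 iterations = res$iterations, resets = res$resets),
            class = "peel_result")
}

#' Peel a single locus
#'
#' Convenience wrapper around [peel_genotypes()] for one SNP.
#'
#' @param ped a [pedigree] object.
#' @param observed genotype codes (0/1/2/3), one per pedigree individual
#'   (in pedigree order) or named by individual.
#' @param cfg a [peel_config()]; `allele_freq` must be scalar if given.
#' @return Matrix individuals x 4 of ordered-genotype probabilities.
#' @export
peel_locus <- function(ped, observed, cfg = peel_config()) {
  if (!is.null(names(observed))) {
    g <- matrix(as.integer(observed), ncol = 1,
                dimnames = list(names(observed), NULL))
  } else {
    stopifnot(length(observed) == length(ped$id))
    g <- matrix(as.integer(observed), ncol = 1, dimnames = list(ped$id, NULL))
  }
  r <- peel_genotypes(ped, g, cfg)
  out <- r$post[, 1, ]
  dim(out) <- c(length(ped$id), 4L)
  rownames(out) <- ped$id
  out
}

#' Call alleles from peeled genotype probabilities
#'
#' Converts ordered-genotype probabilities into per-gamete allele
#' probabilities (`P(allele = 1)`) and hard calls: an allele is set to 1 when
#' its probability exceeds the call threshold, to 0 when below one minus the
#' threshold, and left unresolved otherwise.
#'
#' @param peel a `peel_result` (or a bare individuals x SNP x 4 array).
#' @param cfg a [peel_config()] supplying the call threshold.
#' @return List with `pat`, `mat` (integer call matrices, 0/1/9) and
#'   `p_pat`, `p_mat` (numeric allele-1 probability matrices).
#' @export
call_alleles <- function(peel, cfg = peel_config()) {
  post <- if (inherits(peel, "peel_result")) peel$post else peel
  p_pat <- post[, , 3, drop = FALSE] + post[, , 4, drop = FALSE]
  p_mat <- post[, , 2, drop = FALSE] + post[, , 4, drop = FALSE]
  dim(p_pat) <- dim(p_mat) <- dim(post)[1:2]
  rownames(p_pat) <- rownames(p_mat) <- dimnames(post)[[1]]
  thr <- cfg$call_threshold
  hard <- function(p) {
    m <- matrix(ALLELE_MISSING, nrow(p), ncol(p), dimnames = dimnames(p))
    m[p > thr] <- 1L
    m[p < 1 - thr] <- 0L
    m
  }
  list(pat = hard(p_pat), mat = hard(p_mat), p_pat = p_pat, p_mat = p_mat)
}
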