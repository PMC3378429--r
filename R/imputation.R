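#' Imputation configuration
#'
#' Tuning parameters of the haplotype-matching imputation engine.
#'
#' @param library_mismatch_threshold disagreements tolerated before a
#'   candidate library haplotype is rejected (default 0).
#' @param vote_accept minimum votes for an allele to be imputed, per outer
#'   iteration (recycled; default `c(1, 2, 2)` — tightened after the first
#'   pass).
#' @param vote_reject maximum votes tolerated for the opposite allele
#'   (default 0).
#' @param n_outer_iterations number of passes over the major sub-steps
#'   (default 3).
#' @param internal_core_lengths core lengths used when haplotype libraries
#'   are rebuilt internally from imputed phase (default `c(50, 100, 200)`).
#' @param max_recombinations per-iteration crossover-count ceilings for the
#'   recombination scan (default `c(10, 20, 40)`, increasingly relaxed).
#' @param min_double_crossover_gap per-iteration minimum SNP span of a
#'   double-crossover interval (default `c(100, 50, 25)`).
#' @param hd_threshold fraction of non-missing SNP above which an animal
#'   counts as high density (default 0.9).
#' @return A list of class `impute_config`.
#' @export
impute_config <- function(library_mismatch_threshold = 0L,
                          vote_accept = c(1L, 2L, 2L), vote_reject = 0L,
                          n_outer_iterations = 3L,
                          internal_core_lengths = c(50L, 100L, 200L),
                          max_recombinations = c(10L, 20L, 40L),
                          min_double_crossover_gap = c(100L, 50L, 25L),
                          hd_threshold = 0.9) {
  stopifnot(all(vote_accept > vote_reject), all(vote_reject >= 0),
            n_outer_iterations >= 0,
            length(max_recombinations) == length(min_double_crossover_gap))
  structure(list(
    library_mismatch_threshold = as.integer(library_mismatch_threshold),
    vote_accept = as.integer(vote_accept),
    vote_reject = as.integer(vote_reject),
    n_outer_iterations = as.integer(n_outer_iterations),
    internal_core_lengths = as.integer(internal_core_lengths),
    max_recombinations = as.integer(max_recombinations),
    min_double_crossover_gap = as.integer(min_double_crossover_gap),
    hd_threshold = hd_threshold), class = "impute_config")
}

#' Create an imputation working state
#'
#' The working state holds the phase, genotype and conflict bookkeeping that
#' the minor and major sub-steps update. Fills are monotone: a resolved
#' allele or genotype is never changed; later contradictory evidence is
#' counted as a conflict and discarded (first writer wins).
#'
#' @param ped a [pedigree].
#' @param geno genotype matrix (rows matched to the pedigree by rowname).
#' @param phase optional `list(pat, mat)` initial phase (e.g. from
#'   [phase_hd()]), pedigree-aligned or rowname-matched.
#' @return An environment of class `impute_state` with integer matrices
#'   `pat`, `mat`, `geno`, the pedigree, and counters `conflicts`, `log`.
#' @export
impute_state <- function(ped, geno, phase = NULL) {
  st <- new.env(parent = emptyenv())
  st$ped <- ped
  st$geno <- align_genotypes(ped, geno)
  n <- length(ped$id); L <- ncol(st$geno)
  st$pat <- matrix(ALLELE_MISSING, n, L, dimnames = list(ped$id, NULL))
  st$mat <- matrix(ALLELE_MISSING, n, L, dimnames = list(ped$id, NULL))
  if (!is.null(phase)) {
    rows <- match(rownames(phase$pat), ped$id)
    st$pat[rows[!is.na(rows)], ] <- phase$pat[!is.na(rows), , drop = FALSE]
    st$mat[rows[!is.na(rows)], ] <- phase$mat[!is.na(rows), , drop = FALSE]
  }
  st$conflicts <- 0L
  st$log <- list()
  class(st) <- "impute_state"
  st
}

#' @export
print.impute_state <- function(x, ...) {
  res <- mean(x$pat != ALLELE_MISSING) / 2 + mean(x$mat != ALLELE_MISSING) / 2
  cat("<impute_state> ", nrow(x$pat), " x ", ncol(x$pat), " SNP; ",
      round(100 * res, 1), "% alleles resolved; ", x$conflicts,
      " conflicts\n", sep = "")
  invisible(x)
}

log_step <- function(st, step, filled, conflicts = 0L) {
  st$log[[length(st$log) + 1L]] <- data.frame(step = step, filled = filled,
                                              conflicts = conflicts)
  invisible(st)
}

# monotone merge of candidate allele values (at cell indices) into one
# gamete; genotype and complement consistency enforced, contradictions
# counted and dropped
fill_cells <- function(st, side, idx, vals, step) {
  if (!length(idx)) return(log_step(st, step, 0L, 0L))
  cur <- st[[side]]
  cv <- cur[idx]
  ov <- st[[if (side == "pat") "mat" else "pat"]][idx]
  gv <- st$geno[idx]
  cand <- cv == ALLELE_MISSING
  bad <- cand & gv != GENO_MISSING &
    ((ov != ALLELE_MISSING & ov + vals != gv) |
     (ov == ALLELE_MISSING & (gv - vals < 0 | gv - vals > 1)))
  ok <- cand & !bad
  cur[idx[ok]] <- vals[ok]
  st[[side]] <- cur
  st$conflicts <- st$conflicts + sum(bad)
  log_step(st, step, sum(ok), sum(bad))
  sum(ok)
}

fill_gamete <- function(st, side, vals, step) {
  idx <- which(vals != ALLELE_MISSING)
  fill_cells(st, side, idx, vals[idx], step)
}

#' Run the four minor phase-propagation rules to a fixed point
#'
#' In order: parent-homozygous fill-in, phase complement from the genotype,
#' imputing parents from progeny complement, and making genotypes from both
#' alleles; iterated until nothing changes.
#'
#' @param st an [impute_state()].
#' @return The state, invisibly; fill/conflict counts are appended to its
#'   log.
#' @export
run_minor_steps <- function(st) {
  r <- .minor_steps_cpp(st$pat, st$mat, st$geno, st$ped$sire, st$ped$dam)
  st$conflicts <- st$conflicts + r[2]
  log_step(st, "minor1-4", r[1], r[2])
  invisible(st)
}

#' Convert peeled allele probabilities to phase calls
#'
#' Merges hard allele calls (posterior probability beyond the call
#' threshold) from segregation analysis into the working state.
#'
#' @param st an [impute_state()].
#' @param calls result of [call_alleles()].
#' @return The state, invisibly.
#' @export
probs_to_phase <- function(st, calls) {
  fill_gamete(st, "pat", calls$pat, "major1")
  fill_gamete(st, "mat", calls$mat, "major1")
  invisible(st)
}

# orientation of a candidate pair against a partially resolved strand:
# 1 = A matches, 2 = B matches, 0 = ambiguous/uninformative
match_strand <- function(strand, candA, candB) {
  ra <- candA != ALLELE_MISSING; rb <- candB != ALLELE_MISSING
  rs <- strand != ALLELE_MISSING
  mmA <- sum(rs & ra & strand != candA)
  mmB <- sum(rs & rb & strand != candB)
  info <- sum(rs & ra & rb & candA != candB)
  if (info == 0) return(0L)
  if (mmA == 0 && mmB > 0) return(1L)
  if (mmB == 0 && mmA > 0) return(2L)
  0L
}

#' Fill in base animals from their per-core haplotype pairs
#'
#' A base animal has no parents to orient its haplotypes against, so the
#' central core of the first phasing round anchors an arbitrary
#' paternal/maternal labelling; the labelling is extended core by core in
#' both directions using the overlapping cores of the other rounds as
#' bridges: a bridge haplotype joins the paternal strand only if it matches
#' the already-labelled strand at every resolved overlapping SNP while the
#' alternative does not. Ambiguous junctions stop the extension.
#'
#' @param st an [impute_state()].
#' @param phres a `phase_result` from [phase_hd()].
#' @return The state, invisibly.
#' @export
fill_base_animals <- function(st, phres) {
  ped <- st$ped
  L <- ncol(st$pat)
  base_rows <- ped_index(ped, phres$base_ids)
  layout0 <- phres$rounds[[1]]$layout
  ncore <- nrow(layout0)
  n_rounds <- length(phres$rounds)
  filled_tot <- 0L
  for (b in base_rows) {
    sp <- sm <- rep(ALLELE_MISSING, L)
    central <- (ncore - 1L) %/% 2L + 1L
    rng <- layout0$lo[central]:layout0$hi[central]
    sp[rng] <- phres$rounds[[1]]$A[b, rng]
    sm[rng] <- phres$rounds[[1]]$B[b, rng]
    extend <- function(cores) {
      for (ci in cores) {
        x <- if (ci > central) layout0$lo[ci] else layout0$hi[ci] + 1L
        done <- FALSE
        for (r in seq_len(n_rounds)[-1]) {
          lay <- phres$rounds[[r]]$layout
          bi <- which(lay$lo < x & lay$hi >= x)
          if (!length(bi)) next
          brng <- lay$lo[bi[1]]:lay$hi[bi[1]]
          bA <- phres$rounds[[r]]$A[b, brng]
          bB <- phres$rounds[[r]]$B[b, brng]
          m <- match_strand(sp[brng], bA, bB)
          m2 <- match_strand(sm[brng], bA, bB)
          if (m == 1L && m2 != 1L) { pa <- bA; ma <- bB }
          else if (m == 2L && m2 != 2L) { pa <- bB; ma <- bA }
          else next
          wr <- brng[sp[brng] == ALLELE_MISSING & pa != ALLELE_MISSING]
          sp[wr] <<- pa[match(wr, brng)]
          wr <- brng[sm[brng] == ALLELE_MISSING & ma != ALLELE_MISSING]
          sm[wr] <<- ma[match(wr, brng)]
          # orient the next round-0 core against the extended strand
          crng <- layout0$lo[ci]:layout0$hi[ci]
          cA <- phres$rounds[[1]]$A[b, crng]
          cB <- phres$rounds[[1]]$B[b, crng]
          mc <- match_strand(sp[crng], cA, cB)
          mc2 <- match_strand(sm[crng], cA, cB)
          if (mc == 1L && mc2 != 1L) { pa <- cA; ma <- cB }
          else if (mc == 2L && mc2 != 2L) { pa <- cB; ma <- cA }
          else next
          wr <- crng[sp[crng] == ALLELE_MISSING & pa != ALLELE_MISSING]
          sp[wr] <<- pa[match(wr, crng)]
          wr <- crng[sm[crng] == ALLELE_MISSING & ma != ALLELE_MISSING]
          sm[wr] <<- ma[match(wr, crng)]
          done <- TRUE
          break
        }
        if (!done) return(invisible(NULL))
      }
    }
    if (central < ncore) extend((central + 1L):ncore)
    if (central > 1L) extend((central - 1L):1L)
    wr <- st$pat[b, ] == ALLELE_MISSING & sp != ALLELE_MISSING
    st$pat[b, wr] <- sp[wr]
    wr2 <- st$mat[b, ] == ALLELE_MISSING & sm != ALLELE_MISSING
    st$mat[b, wr2] <- sm[wr2]
    filled_tot <- filled_tot + sum(wr) + sum(wr2)
  }
  log_step(st, "major2", filled_tot)
  invisible(st)
}

new_votes <- function(st) {
  n <- nrow(st$pat); L <- ncol(st$pat)
  list(p0 = matrix(0L, n, L), p1 = matrix(0L, n, L),
       m0 = matrix(0L, n, L), m1 = matrix(0L, n, L))
}

apply_votes <- function(st, v, accept, reject, step) {
  decide <- function(side, v0, v1) {
    i1 <- which(v1 >= accept & v0 <= reject)
    i0 <- which(v0 >= accept & v1 <= reject)
    fill_cells(st, side, c(i1, i0),
               c(rep(1L, length(i1)), rep(0L, length(i0))), step)
  }
  decide("pat", v$p0, v$p1)
  decide("mat", v$m0, v$m1)
  invisible(st)
}

#' Candidate haplotype-library imputation
#'
#' For every gamete, core and phasing round, library haplotypes with more
#' than the mismatch threshold of disagreements against the gamete's
#' resolved alleles are rejected; unresolved loci where all surviving
#' candidates agree receive a vote, and votes accumulate per chromosome
#' locus across all cores and rounds. An allele is imputed when its vote
#' count reaches `accept` while the opposite allele has at most `reject`
#' votes — a guard against phasing errors from any single round.
#'
#' @param st an [impute_state()].
#' @param phres a `phase_result` (its per-round libraries are the candidate
#'   sets).
#' @param cfg an [impute_config()].
#' @param accept,reject vote thresholds for this pass.
#' @return The state, invisibly.
#' @export
library_imputation <- function(st, phres, cfg, accept = 1L, reject = 0L) {
  v <- new_votes(st)
  for (r in seq_along(phres$rounds)) {
    rd <- phres$rounds[[r]]
    libs <- lapply(rd$libs, `[[`, "haps")
    .library_votes_cpp(st$pat, libs, rd$layout$lo, rd$layout$hi,
                       cfg$library_mismatch_threshold, v$p0, v$p1)
    .library_votes_cpp(st$mat, libs, rd$layout$lo, rd$layout$hi,
                       cfg$library_mismatch_threshold, v$m0, v$m1)
  }
  apply_votes(st, v, accept, reject, "major3")
}

#' Imputation from parental phase
#'
#' As [library_imputation()], but the candidate set for each gamete and core
#' is restricted to the two haplotypes of the corresponding parent from the
#' long-range phasing rounds; only individuals whose parent is high density
#' take part.
#'
#' @inheritParams library_imputation
#' @return The state, invisibly.
#' @export
parent_phase_imputation <- function(st, phres, cfg, accept = 1L, reject = 0L) {
  ped <- st$ped
  hd <- ped$id %in% phres$hd_ids
  src_sire <- ifelse(ped$sire > 0L & hd[pmax(ped$sire, 1L)], ped$sire, 0L)
  src_dam <- ifelse(ped$dam > 0L & hd[pmax(ped$dam, 1L)], ped$dam, 0L)
  v <- new_votes(st)
  for (r in seq_along(phres$rounds)) {
    rd <- phres$rounds[[r]]
    .pair_votes_cpp(st$pat, rd$A, rd$B, src_sire, rd$layout$lo, rd$layout$hi,
                    cfg$library_mismatch_threshold, v$p0, v$p1)
    .pair_votes_cpp(st$mat, rd$A, rd$B, src_dam, rd$layout$lo, rd$layout$hi,
                    cfg$library_mismatch_threshold, v$m0, v$m1)
  }
  apply_votes(st, v, accept, reject, "major4")
}

#' Individual phase imputation
#'
#' The candidate haplotypes for both gametes of a high-density individual
#' are its own two haplotypes from each phasing round; the vote machinery
#' effectively determines the parental origin of each haplotype and fills
#' unresolved alleles from the uniquely matching one.
#'
#' @inheritParams library_imputation
#' @return The state, invisibly.
#' @export
individual_phase_imputation <- function(st, phres, cfg, accept = 1L,
                                        reject = 0L) {
  ped <- st$ped
  self <- ifelse(ped$id %in% phres$hd_ids, seq_along(ped$id), 0L)
  v <- new_votes(st)
  for (r in seq_along(phres$rounds)) {
    rd <- phres$rounds[[r]]
    .pair_votes_cpp(st$pat, rd$A, rd$B, self, rd$layout$lo, rd$layout$hi,
                    cfg$library_mismatch_threshold, v$p0, v$p1)
    .pair_votes_cpp(st$mat, rd$A, rd$B, self, rd$layout$lo, rd$layout$hi,
                    cfg$library_mismatch_threshold, v$m0, v$m1)
  }
  apply_votes(st, v, accept, reject, "major5")
}

internal_libraries <- function(st, core_length) {
  L <- ncol(st$pat)
  layout <- build_core_layout(L, core_length, 1L)[[1]]
  libs <- vector("list", nrow(layout))
  for (ci in seq_len(nrow(layout))) {
    rng <- layout$lo[ci]:layout$hi[ci]
    lib <- build_library(st$pat[, rng, drop = FALSE],
                         st$mat[, rng, drop = FALSE],
                         seq_len(nrow(st$pat)), complete = FALSE)
    libs[[ci]] <- lib$haps
  }
  list(layout = layout, libs = libs)
}

#' Internal candidate haplotype-library imputation
#'
#' Rebuilds haplotype libraries from the phase imputed so far — over several
#' core lengths, so errors are cross-checked at different scales — and
#' reruns the library vote machinery against them.
#'
#' @inheritParams library_imputation
#' @return The state, invisibly.
#' @export
internal_library_imputation <- function(st, cfg, accept = 1L, reject = 0L) {
  if (!length(cfg$internal_core_lengths)) return(invisible(st))
  v <- new_votes(st)
  for (len in cfg$internal_core_lengths) {
    il <- internal_libraries(st, len)
    .library_votes_cpp(st$pat, il$libs, il$layout$lo, il$layout$hi,
                       cfg$library_mismatch_threshold, v$p0, v$p1)
    .library_votes_cpp(st$mat, il$libs, il$layout$lo, il$layout$hi,
                       cfg$library_mismatch_threshold, v$m0, v$m1)
  }
  apply_votes(st, v, accept, reject, "major6")
}

#' Internal imputation from parental phase
#'
#' As [parent_phase_imputation()], but the parents' haplotypes are taken
#' from the current working state — every animal in the pedigree takes part,
#' since its parents may by now carry imputed high-density information —
#' and the candidate cores use the internal core lengths.
#'
#' @inheritParams library_imputation
#' @return The state, invisibly.
#' @export
internal_parent_imputation <- function(st, cfg, accept = 1L, reject = 0L) {
  ped <- st$ped
  v <- new_votes(st)
  pat_now <- st$pat; mat_now <- st$mat   # snapshot: candidates stay fixed
  for (len in cfg$internal_core_lengths) {
    layout <- build_core_layout(ncol(st$pat), len, 1L)[[1]]
    .pair_votes_cpp(st$pat, pat_now, mat_now, ped$sire, layout$lo, layout$hi,
                    cfg$library_mismatch_threshold, v$p0, v$p1)
    .pair_votes_cpp(st$mat, pat_now, mat_now, ped$dam, layout$lo, layout$hi,
                    cfg$library_mismatch_threshold, v$m0, v$m1)
  }
  apply_votes(st, v, accept, reject, "major7")
}

#' Imputation from transmitted-gamete recombination tracking
#'
#' Scans each gamete in both chromosome directions. At loci where both the
#' individual and its parent are heterozygous and phased, the transmitted
#' parental gamete is identified; stretches between two determinations of
#' the same origin inherit that origin (no double crossover assumed), and
#' alleles are imputed where the two directions agree and the parent is
#' phased — subject to a ceiling on the implied crossover count and a
#' minimum SNP span for any double-crossover interval. The restriction
#' schedule is iterated with increasingly relaxed limits, with the minor
#' steps after each iteration.
#'
#' @param st an [impute_state()].
#' @param cfg an [impute_config()] (supplies the schedules).
#' @return The state, invisibly.
#' @export
recombination_scan <- function(st, cfg) {
  ped <- st$ped
  for (k in seq_along(cfg$max_recombinations)) {
    f1 <- .recomb_scan_cpp(st$pat, st$mat, st$pat, st$mat, ped$sire, st$geno,
                           cfg$max_recombinations[k],
                           cfg$min_double_crossover_gap[k])
    f2 <- .recomb_scan_cpp(st$mat, st$pat, st$pat, st$mat, ped$dam, st$geno,
                           cfg$max_recombinations[k],
                           cfg$min_double_crossover_gap[k])
    log_step(st, sprintf("major8.%d", k), f1 + f2)
    run_minor_steps(st)
  }
  invisible(st)
}

#' Recalculate allele probabilities and emit final outputs
#'
#' Reruns segregation analysis on the updated genotypes; alleles still
#' unresolved take their recalculated probability, resolved alleles keep
#' probability 0/1, and the dosage is the per-individual sum of the two
#' gamete probabilities.
#'
#' @param st an [impute_state()].
#' @param peel_cfg a [peel_config()].
#' @param allele_freq per-SNP allele frequencies for the founder prior.
#' @return List with `probs` (`pat`, `mat` probability matrices), `dosage`,
#'   and the peel result.
#' @export
recalc_probabilities <- function(st, peel_cfg = peel_config(),
                                 allele_freq = NULL) {
  cfg <- peel_cfg
  if (!is.null(allele_freq)) cfg$allele_freq <- allele_freq
  pr <- peel_genotypes(st$ped, st$geno, cfg)
  cal <- call_alleles(pr, cfg)
  p_pat <- cal$p_pat; p_mat <- cal$p_mat
  res <- st$pat != ALLELE_MISSING
  p_pat[res] <- st$pat[res]
  res <- st$mat != ALLELE_MISSING
  p_mat[res] <- st$mat[res]
  dimnames(p_pat) <- dimnames(p_mat) <- dimnames(st$pat)
  list(probs = list(pat = p_pat, mat = p_mat), dosage = p_pat + p_mat,
       peel = pr)
}

finalize_result <- function(st, fin, hd_ids, ld_ids, allele_freq) {
  structure(list(
    phase = list(pat = st$pat, mat = st$mat),
    probs = fin$probs,
    dosage = fin$dosage,
    geno = st$geno,
    ped = st$ped,
    hd_ids = hd_ids, ld_ids = ld_ids,
    allele_freq = allele_freq,
    conflicts = st$conflicts,
    log = do.call(rbind, st$log)), class = "impute_result")
}

#' @export
print.impute_result <- function(x, ...) {
  res <- (mean(x$phase$pat != ALLELE_MISSING) +
            mean(x$phase$mat != ALLELE_MISSING)) / 2
  cat("<impute_result> ", nrow(x$dosage), " individuals x ", ncol(x$dosage),
      " SNP\n  alleles called without ambiguity: ", round(100 * res, 1),
      "%\n  conflicts: ", x$conflicts, "\n", sep = "")
  invisible(x)
}

#' Single-locus imputation for unmapped SNP
#'
#' Peeling-only path: no haplotype information is used. Segregation analysis
#' yields allele probabilities; probabilities beyond the call threshold are
#' imputed, the simple phase-propagation rules are run to a fixed point, and
#' probabilities are recalculated from the updated genotypes.
#'
#' @param ped a [pedigree].
#' @param geno genotype matrix.
#' @param cfg a [peel_config()].
#' @return An `impute_result`.
#' @export
impute_unmapped <- function(ped, geno, cfg = peel_config()) {
  cleaned <- check_mendelian(ped, geno)
  dens <- split_density(cleaned$geno)
  freq <- cfg$allele_freq
  if (is.null(freq)) {
    rows <- if (length(dens$hd)) dens$hd else NULL
    freq <- snp_allele_freq(cleaned$geno, rows)
  }
  cfg$allele_freq <- freq
  st <- impute_state(ped, cleaned$geno)
  pr <- peel_genotypes(ped, st$geno, cfg)
  probs_to_phase(st, call_alleles(pr, cfg))
  run_minor_steps(st)
  fin <- recalc_probabilities(st, cfg, freq)
  finalize_result(st, fin, dens$hd, dens$ld, freq)
}

#' Phase and impute a pedigreed population
#'
#' The full pipeline: Mendelian-consistency cleaning; single-locus
#' segregation analysis for every SNP (Step 1); long-range phasing and
#' haplotype-library construction for the high-density animals (Step 2);
#' then the iterated major/minor imputation sub-steps (Step 3) — allele
#' calls from probabilities, base-animal fill-in, candidate-library votes,
#' parental and own-phase votes, internally rebuilt libraries, and the
#' recombination scan — each followed by the four minor propagation rules,
#' the whole cycle repeated `n_outer_iterations` times; finally allele
#' probabilities are recalculated and dosages emitted. SNP without a map
#' position are imputed by the peeling-only path.
#'
#' @param ped a [pedigree].
#' @param geno genotype matrix (rownames = ids; codes 0/1/2, 3 or
#'   `missing_code` = missing).
#' @param map optional data frame from [load_snp_map()]; when present, only
#'   mapped SNP enter the haplotype machinery.
#' @param cfg an [impute_config()].
#' @param peel_cfg a [peel_config()].
#' @param phase_cfg a [phase_config()].
#' @param unmapped_only if `TRUE`, skip long-range phasing and haplotype
#'   imputation entirely and run the peeling-only path on all SNP.
#' @param phased_input optional externally phased alleles (see
#'   [phase_hd()]).
#' @param verbose print step-level progress.
#' @return An `impute_result`: phased alleles (`phase`), per-gamete allele
#'   probabilities (`probs`), `dosage` in \[0, 2\], updated genotypes, the
#'   conflict count and a structured fill log.
#' @export
impute_pedigree <- function(ped, geno, map = NULL, cfg = impute_config(),
                            peel_cfg = peel_config(),
                            phase_cfg = phase_config(),
                            unmapped_only = FALSE, phased_input = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  if (unmapped_only) return(impute_unmapped(ped, geno, peel_cfg))
  mapped <- if (is.null(map)) seq_len(ncol(geno)) else which(map$mapped)
  unmapped <- setdiff(seq_len(ncol(geno)), mapped)

  cleaned <- check_mendelian(ped, geno)
  g <- cleaned$geno
  dens <- split_density(g, cfg$hd_threshold)
  if (!length(dens$hd)) stop("no high-density animals found; lower hd_threshold or use unmapped_only")
  freq <- peel_cfg$allele_freq
  if (is.null(freq)) freq <- snp_allele_freq(g, dens$hd)
  pcfg <- peel_cfg; pcfg$allele_freq <- freq[mapped]

  gm <- g[, mapped, drop = FALSE]
  say <- function(...) if (verbose) message(...)

  say("Step 1: segregation analysis (", length(mapped), " SNP)")
  pr <- peel_genotypes(ped, gm, pcfg)
  calls <- call_alleles(pr, pcfg)

  say("Step 2: long-range phasing of ", length(dens$hd), " HD animals")
  phres <- phase_hd(ped, gm, dens$hd, phase_cfg, phased_input = phased_input)

  st <- impute_state(ped, gm, phase = list(pat = phres$pat, mat = phres$mat))
  run_minor_steps(st)
  acc <- rep(cfg$vote_accept, length.out = max(cfg$n_outer_iterations, 1L))
  for (outer in seq_len(cfg$n_outer_iterations)) {
    a <- acc[outer]; rj <- cfg$vote_reject[1]
    say("Step 3, outer iteration ", outer, " (vote accept ", a, ")")
    probs_to_phase(st, calls);                         run_minor_steps(st)
    fill_base_animals(st, phres);                      run_minor_steps(st)
    library_imputation(st, phres, cfg, a, rj);         run_minor_steps(st)
    parent_phase_imputation(st, phres, cfg, a, rj);    run_minor_steps(st)
    individual_phase_imputation(st, phres, cfg, a, rj); run_minor_steps(st)
    internal_library_imputation(st, cfg, a, rj);       run_minor_steps(st)
    internal_parent_imputation(st, cfg, a, rj);        run_minor_steps(st)
    recombination_scan(st, cfg)
  }
  say("Step 3: recalculating allele probabilities")
  fin <- recalc_probabilities(st, pcfg, freq[mapped])

  if (length(unmapped)) {
    say("Unmapped SNP: peeling-only path (", length(unmapped), " SNP)")
    ucfg <- peel_cfg; ucfg$allele_freq <- freq[unmapped]
    ures <- impute_unmapped(ped, g[, unmapped, drop = FALSE], ucfg)
    # stitch mapped and unmapped columns back into input order
    full <- function(a, b) {
      out <- matrix(NA_real_, nrow(a), ncol(geno), dimnames = list(rownames(a), NULL))
      out[, mapped] <- a; out[, unmapped] <- b
      out
    }
    fulli <- function(a, b) { o <- full(a, b); storage.mode(o) <- "integer"; o }
    st2 <- list(pat = fulli(st$pat, ures$phase$pat),
                mat = fulli(st$mat, ures$phase$mat),
                geno = fulli(st$geno, ures$geno),
                ped = ped, conflicts = st$conflicts + ures$conflicts,
                log = st$log)
    fin2 <- list(probs = list(pat = full(fin$probs$pat, ures$probs$pat),
                              mat = full(fin$probs$mat, ures$probs$mat)))
    fin2$dosage <- fin2$probs$pat + fin2$probs$mat
    return(finalize_result(list2env(st2), fin2, dens$hd, dens$ld, freq))
  }
  finalize_result(st, fin, dens$hd, dens$ld, freq[mapped])
}
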