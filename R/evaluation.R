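#' Imputation accuracy as a true-vs-imputed correlation
#'
#' Accuracy is the Pearson correlation between the true genotype and the
#' imputed genotype or dosage, per animal, computed over the masked SNP only
#' by default (so that genotypes an animal was given are not parroted back
#' into its accuracy). Animals without variance in either vector get `NA`
#' and are excluded from means.
#'
#' @param true_geno numeric vector (or single-row slice) of true genotypes.
#' @param imputed_dosage numeric vector of imputed dosages.
#' @param masked optional integer indices of the masked SNP; when `NULL`
#'   all SNP are used.
#' @return A single correlation, or `NA` when undefined.
#' @export
accuracy_correlation <- function(true_geno, imputed_dosage, masked = NULL) {
  t <- as.numeric(true_geno)
  d <- as.numeric(imputed_dosage)
  if (!is.null(masked)) { t <- t[masked]; d <- d[masked] }
  if (length(t) < 2 || stats::sd(t) == 0 || stats::sd(d) == 0) return(NA_real_)
  stats::cor(t, d)
}

#' Per-animal imputation accuracy report
#'
#' @param result an `impute_result` from [impute_pedigree()].
#' @param truth a `truth_set` (or a true genotype matrix).
#' @param ids animals to evaluate (default: the low-density test animals of
#'   the result).
#' @param masked SNP indices to evaluate over (typically the complement of
#'   the retained panel); `NULL` for all SNP.
#' @param categories optional ancestry category factor (named by id or in
#'   `ids` order), e.g. from [classify_ancestry()].
#' @return A tibble with one row per animal: `id`, `category`, `r`
#'   (true-vs-dosage correlation) and `n_snp` evaluated.
#' @export
imputation_accuracy <- function(result, truth, ids = result$ld_ids,
                                masked = NULL, categories = NULL) {
  tg <- if (inherits(truth, "truth_set")) truth$geno else truth
  ids <- as.character(ids)
  r <- vapply(ids, function(i) {
    accuracy_correlation(tg[i, ], result$dosage[i, ], masked)
  }, numeric(1))
  cat_vec <- if (is.null(categories)) factor(rep(NA_character_, length(ids)))
  else if (!is.null(names(categories))) categories[ids] else categories
  tibble::tibble(id = ids, category = cat_vec, r = unname(r),
                 n_snp = if (is.null(masked)) ncol(tg) else length(masked))
}

#' Percentage of alleles called without ambiguity
#'
#' An allele counts as called without ambiguity when it was hard-called
#' (0/1) by the phasing and imputation rules, rather than left to the final
#' probabilistic fill. Animals whose minimum per-gamete percentage falls
#' below the warning threshold tend to have lower imputation accuracy and
#' are flagged.
#'
#' @param result an `impute_result`.
#' @param ids animals to report (default all).
#' @param warn_below warning threshold in percent (default 90).
#' @return A tibble: `id`, `pct_paternal`, `pct_maternal`, `pct_min`,
#'   `flagged`.
#' @export
ambiguity_profile <- function(result, ids = rownames(result$phase$pat),
                              warn_below = 90) {
  ids <- as.character(ids)
  pp <- 100 * rowMeans(result$phase$pat[ids, , drop = FALSE] != ALLELE_MISSING)
  pm <- 100 * rowMeans(result$phase$mat[ids, , drop = FALSE] != ALLELE_MISSING)
  tibble::tibble(id = ids, pct_paternal = unname(pp), pct_maternal = unname(pm),
                 pct_min = pmin(unname(pp), unname(pm)),
                 flagged = pmin(unname(pp), unname(pm)) < warn_below)
}

#' Mean accuracy by ancestry category
#'
#' Summarises a per-animal accuracy report into the familiar
#' category-by-scenario table (mean correlation and animal count per
#' category, `NA` accuracies excluded; empty categories are omitted).
#'
#' @param report a tibble from [imputation_accuracy()] (may carry extra
#'   grouping columns such as `scenario`).
#' @param ... additional grouping columns (unquoted), e.g. `scenario`.
#' @return A tibble with `category`, group columns, `n`, `mean_r`.
#' @export
category_summary <- function(report, ...) {
  report |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$category, ..., .drop = TRUE) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_r = mean(.data$r, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(.data$n > 0)
}

#' Phasing yield and agreement against simulated truth
#'
#' Compares phased alleles of the high-density animals with the gene-dropped
#' truth. Non-base animals are compared directly (their orientation is
#' anchored by the pedigree); base animals, whose paternal/maternal
#' labelling is arbitrary, are compared under the better of the two global
#' swaps.
#'
#' @param phase `list(pat, mat)` phased alleles (n x L, codes 0/1/9), e.g.
#'   the `phase` element of an `impute_result` or a `phase_result`.
#' @param truth a `truth_set`.
#' @param hd_ids animals to assess.
#' @param base_ids subset of `hd_ids` assessed up to a global swap.
#' @return A tibble: `id`, `yield` (fraction of the 2L allele slots
#'   resolved), `agreement` (fraction of resolved alleles matching truth).
#' @export
phase_accuracy <- function(phase, truth, hd_ids, base_ids = character(0)) {
  hd_ids <- as.character(hd_ids)
  res <- lapply(hd_ids, function(i) {
    sp <- phase$pat[i, ]; sm <- phase$mat[i, ]
    rp <- sp != ALLELE_MISSING; rm <- sm != ALLELE_MISSING
    yield <- (sum(rp) + sum(rm)) / (2 * length(sp))
    agree <- function(a, b) sum(sp[rp] == a[rp]) + sum(sm[rm] == b[rm])
    hits <- agree(truth$pat[i, ], truth$mat[i, ])
    if (i %in% base_ids) {
      hits <- max(hits, agree(truth$mat[i, ], truth$pat[i, ]))
    }
    c(yield, if (sum(rp) + sum(rm) > 0) hits / (sum(rp) + sum(rm)) else NA_real_)
  })
  m <- do.call(rbind, res)
  tibble::tibble(id = hd_ids, yield = m[, 1], agreement = m[, 2])
}

#' Histogram of per-animal imputation accuracy
#'
#' @param report a tibble from [imputation_accuracy()].
#' @param binwidth histogram bin width (default 0.01).
#' @return A ggplot object.
#' @export
plot_accuracy_histogram <- function(report, binwidth = 0.01) {
  ggplot2::ggplot(dplyr::filter(report, !is.na(.data$r)),
                  ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "grey30") +
    ggplot2::labs(x = "correlation between true and imputed genotypes",
                  y = "animals") +
    ggplot2::theme_minimal()
}

#' Accuracy versus percentage of alleles called without ambiguity
#'
#' @param report a tibble from [imputation_accuracy()].
#' @param ambiguity a tibble from [ambiguity_profile()].
#' @return A ggplot object (one panel per gamete).
#' @export
plot_accuracy_vs_ambiguity <- function(report, ambiguity) {
  df <- dplyr::inner_join(report, ambiguity, by = "id") |>
    tidyr_longer()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$r)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::facet_wrap(~gamete) +
    ggplot2::labs(x = "% alleles called without ambiguity",
                  y = "imputation accuracy") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_longer <- function(df) {
  rbind(
    dplyr::transmute(df, id = .data$id, r = .data$r, gamete = "paternal",
                     pct = .data$pct_paternal),
    dplyr::transmute(df, id = .data$id, r = .data$r, gamete = "maternal",
                     pct = .data$pct_maternal))
}

#' Mean accuracy per ancestry category, as bars
#'
#' @param summary a tibble from [category_summary()].
#' @return A ggplot object.
#' @export
plot_category_accuracy <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$category, y = .data$mean_r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "mean correlation") +
    ggplot2::theme_minimal()
}
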