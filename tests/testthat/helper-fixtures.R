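# Shared simulation fixtures, cached so that expensive pipeline runs are
# computed once per test session and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# standard study fixture: 1000 SNP, ~1500 animals, parents HD, 500 youngest
# non-parents as the low-density test set
std_run <- function(seed, mask_fraction, hd_assignment = "parents",
                    hd_fraction = 0.5) {
  key <- paste("std", seed, mask_fraction, hd_assignment, hd_fraction, sep = "_")
  cached(key, {
    cfg <- sim_config(seed = seed, mask_fraction = mask_fraction,
                      hd_assignment = hd_assignment, hd_fraction = hd_fraction)
    sim <- simulate_dataset(cfg)
    res <- suppressWarnings(impute_pedigree(sim$ped, sim$geno))
    list(cfg = cfg, sim = sim, res = res,
         masked = setdiff(seq_len(cfg$n_snp), sim$panel$retained))
  })
}

mean_test_accuracy <- function(run) {
  acc <- imputation_accuracy(run$res, run$sim$truth, ids = run$sim$test_ids,
                             masked = run$masked)
  mean(acc$r, na.rm = TRUE)
}

# small fixture for unit tests: 300 animals, 200 SNP
tiny_sim <- function(seed = 7, mask_fraction = 0.85, ...) {
  key <- paste("tiny", seed, mask_fraction, ..., sep = "_")
  cached(key, {
    cfg <- sim_config(n_founders = 60, n_generations = 4, n_offspring = 80,
                      n_sires = 10, n_dams = 30, n_snp = 200, n_test = 100,
                      mask_fraction = mask_fraction, seed = seed, ...)
    simulate_dataset(cfg)
  })
}
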