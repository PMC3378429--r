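# small helper: a 3-member pedigree state with given phase/genotype content
trio_state <- function(L = 4) {
  ped <- pedigree(c("s", "d", "i"), c("0", "0", "s"), c("0", "0", "d"))
  g <- matrix(3L, 3, L, dimnames = list(ped$id, NULL))
  impute_state(ped, g)
}

test_that("minor rules propagate phase deterministically", {
  st <- trio_state()
  # 1: homozygous sire fills the offspring's paternal gamete
  st$pat["s", ] <- c(1L, 0L, 9L, 1L)
  st$mat["s", ] <- c(1L, 1L, 9L, 1L)
  # 2: genotype + one allele -> complement (i, SNP 4)
  st$geno["i", 4] <- 2L
  # 4: both alleles -> genotype
  st$mat["i", 4] <- 9L
  run_minor_steps(st)
  expect_equal(unname(st$pat["i", 1]), 1L)     # sire hom 1
  expect_equal(unname(st$pat["i", 2]), 9L)     # sire het: no action
  expect_equal(unname(st$mat["i", 4]), 1L)     # complement of genotype 2 and allele 1
  expect_equal(unname(st$geno["i", 1]), 3L)    # one allele known: genotype stays missing
  expect_equal(unname(st$geno["i", 4]), 2L)

  # 3: parent imputed from progeny complement
  st2 <- trio_state()
  st2$pat["s", 1] <- 0L                # sire alleles (0, ?)
  st2$pat["i", 1] <- 1L                # offspring received a 1 from the sire
  run_minor_steps(st2)
  expect_equal(unname(st2$mat["s", 1]), 1L)
  st3 <- trio_state()
  st3$pat["s", 1] <- 0L
  st3$pat["i", 1] <- 0L                # consistent with either: no inference
  run_minor_steps(st3)
  expect_equal(unname(st3$mat["s", 1]), 9L)

  # impossible state is logged as a conflict, not written
  st4 <- trio_state()
  st4$geno["i", 1] <- 0L
  st4$pat["i", 1] <- 1L
  run_minor_steps(st4)
  expect_equal(unname(st4$mat["i", 1]), 9L)
  expect_gt(st4$conflicts, 0)
})

test_that("minor fills are monotone and first-writer-wins", {
  st <- trio_state()
  st$pat["s", ] <- c(0L, 0L, 0L, 0L)
  st$mat["s", ] <- c(0L, 0L, 0L, 0L)
  st$pat["i", 1] <- 1L                 # already resolved differently
  run_minor_steps(st)
  expect_equal(unname(st$pat["i", 1]), 1L)     # existing value kept
  expect_equal(unname(st$pat["i", 2]), 0L)
})

test_that("library votes fill unanimous survivor alleles", {
  ped <- pedigree(c("a", "b"), c("0", "0"), c("0", "0"))
  g <- matrix(3L, 2, 4, dimnames = list(ped$id, NULL))
  st <- impute_state(ped, g)
  st$pat["a", ] <- c(0L, 9L, 1L, 0L)
  phres <- list(rounds = list(list(
    layout = data.frame(lo = 1L, hi = 4L),
    libs = list(list(haps = rbind(c(0L, 1L, 1L, 0L)), counts = 2L)))),
    hd_ids = character(0), base_ids = character(0))
  library_imputation(st, phres, impute_config(), accept = 1L, reject = 0L)
  expect_equal(unname(st$pat["a", 2]), 1L)     # single surviving candidate votes 1

  # non-unanimous survivors vote nowhere
  st2 <- impute_state(ped, g)
  st2$pat["a", ] <- c(0L, 9L, 1L, 0L)
  phres2 <- phres
  phres2$rounds[[1]]$libs[[1]]$haps <- rbind(c(0L, 1L, 1L, 0L),
                                             c(0L, 0L, 1L, 0L))
  library_imputation(st2, phres2, impute_config(), accept = 1L, reject = 0L)
  expect_equal(unname(st2$pat["a", 2]), 9L)

  # a candidate beyond the mismatch threshold is rejected
  st3 <- impute_state(ped, g)
  st3$pat["a", ] <- c(0L, 9L, 1L, 0L)
  phres3 <- phres2
  phres3$rounds[[1]]$libs[[1]]$haps <- rbind(c(0L, 1L, 1L, 0L),
                                             c(1L, 0L, 0L, 1L))
  library_imputation(st3, phres3, impute_config(), accept = 1L, reject = 0L)
  expect_equal(unname(st3$pat["a", 2]), 1L)    # second haplotype mismatches everywhere
})

test_that("vote accept/reject thresholds gate imputation", {
  ped <- pedigree("a", "0", "0")
  g <- matrix(3L, 1, 2, dimnames = list("a", NULL))
  lib1 <- list(haps = rbind(c(1L, 1L)), counts = 1L)
  mk <- function(n_rounds) list(
    rounds = rep(list(list(layout = data.frame(lo = 1L, hi = 2L),
                           libs = list(lib1))), n_rounds),
    hd_ids = character(0), base_ids = character(0))
  st <- impute_state(ped, g)
  # 4 rounds -> 4 unanimous votes for allele 1; accept 2 / reject 0 passes
  library_imputation(st, mk(4), impute_config(), accept = 2L, reject = 0L)
  expect_equal(unname(st$pat["a", ]), c(1L, 1L))
  # accept 2 with a single vote does not
  st2 <- impute_state(ped, g)
  library_imputation(st2, mk(1), impute_config(), accept = 2L, reject = 0L)
  expect_equal(unname(st2$pat["a", ]), c(9L, 9L))
})

test_that("parental-phase candidates vote only when they distinguish", {
  ped <- pedigree(c("s", "d", "i"), c("0", "0", "s"), c("0", "0", "d"))
  g <- matrix(3L, 3, 2, dimnames = list(ped$id, NULL))
  mk_phres <- function(A_s, B_s) {
    A <- B <- matrix(9L, 3, 2, dimnames = list(ped$id, NULL))
    A["s", ] <- A_s; B["s", ] <- B_s
    list(rounds = list(list(layout = data.frame(lo = 1L, hi = 2L),
                            A = A, B = B, libs = list())),
         hd_ids = "s", base_ids = character(0))
  }
  # both candidates survive but disagree at locus 1: no vote
  st <- impute_state(ped, g)
  st$pat["i", ] <- c(9L, 1L)
  parent_phase_imputation(st, mk_phres(c(0L, 1L), c(1L, 1L)),
                          impute_config(), accept = 1L)
  expect_equal(unname(st$pat["i", 1]), 9L)
  # only (0,1) survives: vote 0 at locus 1
  st2 <- impute_state(ped, g)
  st2$pat["i", ] <- c(9L, 1L)
  parent_phase_imputation(st2, mk_phres(c(0L, 1L), c(1L, 0L)),
                          impute_config(), accept = 1L)
  expect_equal(unname(st2$pat["i", 1]), 0L)
  # offspring of a low-density sire is skipped
  st3 <- impute_state(ped, g)
  st3$pat["i", ] <- c(9L, 1L)
  ph3 <- mk_phres(c(0L, 1L), c(1L, 0L)); ph3$hd_ids <- character(0)
  parent_phase_imputation(st3, ph3, impute_config(), accept = 1L)
  expect_equal(unname(st3$pat["i", 1]), 9L)
})

test_that("own-pair candidates determine parental origin of haplotypes", {
  ped <- pedigree("a", "0", "0")
  g <- matrix(c(1L, 1L, 1L), 1, 3, dimnames = list("a", NULL))
  A <- matrix(c(0L, 1L, 1L), 1, 3, dimnames = list("a", NULL))
  B <- matrix(c(1L, 0L, 0L), 1, 3, dimnames = list("a", NULL))
  phres <- list(rounds = list(list(layout = data.frame(lo = 1L, hi = 3L),
                                   A = A, B = B, libs = list())),
                hd_ids = "a", base_ids = character(0))
  st <- impute_state(ped, g)
  st$pat["a", ] <- c(0L, 9L, 9L)
  individual_phase_imputation(st, phres, impute_config(), accept = 1L)
  run_minor_steps(st)
  expect_equal(unname(st$pat["a", ]), c(0L, 1L, 1L))
  expect_equal(unname(st$mat["a", ]), c(1L, 0L, 0L))
})

test_that("recombination scan respects the ambiguity interval around a
           planted crossover", {
  n <- 3; L <- 60
  ped <- pedigree(c("s", "d", "i"), c("0", "0", "s"), c("0", "0", "d"))
  g <- matrix(3L, n, L, dimnames = list(ped$id, NULL))
  st <- impute_state(ped, g)
  st$pat["s", ] <- rep(c(0L, 1L), L / 2)     # het and phased everywhere
  st$mat["s", ] <- rep(c(1L, 0L), L / 2)
  st$pat["d", ] <- st$mat["d", ] <- rep(0L, L)
  xov <- 31L                                  # crossover between SNP 30 and 31
  truth <- c(st$pat["s", 1:(xov - 1)], st$mat["s", xov:L])
  st$mat["i", ] <- 0L                         # from the homozygous dam
  obs <- c(6L, 16L, 26L, 41L, 51L)            # informative loci (child het)
  st$pat["i", obs] <- truth[obs]
  st$geno["i", obs] <- truth[obs]             # child genotype at those loci
  recombination_scan(st, impute_config(max_recombinations = 20L,
                                       min_double_crossover_gap = 1L))
  filled <- st$pat["i", ]
  # informative loci flanking the crossover: 26 (origin pat) and 41 (origin mat)
  expect_equal(unname(filled[1:26]), truth[1:26])
  expect_equal(unname(filled[41:L]), truth[41:L])
  # inside the ambiguity interval the two scan directions disagree: untouched
  expect_true(all(filled[27:40] == 9L))
})

test_that("zero-crossover gametes are fully recovered from a phased parent", {
  n <- 3; L <- 40
  ped <- pedigree(c("s", "d", "i"), c("0", "0", "s"), c("0", "0", "d"))
  g <- matrix(3L, n, L, dimnames = list(ped$id, NULL))
  st <- impute_state(ped, g)
  st$pat["s", ] <- rep(c(0L, 1L), L / 2)
  st$mat["s", ] <- rep(c(1L, 0L), L / 2)
  truth <- st$pat["s", ]                      # transmitted intact
  obs <- c(10L, 20L, 30L)
  st$pat["i", obs] <- truth[obs]
  st$mat["i", obs] <- 1L - truth[obs]
  recombination_scan(st, impute_config(max_recombinations = 10L,
                                       min_double_crossover_gap = 1L))
  expect_equal(unname(st$pat["i", ]), unname(truth))
})

test_that("the full pipeline is a fixed point on complete data", {
  sim <- tiny_sim()
  full <- sim$truth$geno
  res <- suppressWarnings(impute_pedigree(sim$ped, full))
  expect_equal(res$dosage, full + 0, tolerance = 1e-9)
  expect_true(all(res$dosage == round(res$dosage)))
})

test_that("no outer iterations degenerates to phasing plus single-locus calls", {
  sim <- tiny_sim()
  res <- suppressWarnings(
    impute_pedigree(sim$ped, sim$geno,
                    cfg = impute_config(n_outer_iterations = 0L)))
  expect_s3_class(res, "impute_result")
  expect_true(all(res$dosage >= 0 & res$dosage <= 2))
})

test_that("unmapped SNP are stitched back through the peeling-only path", {
  sim <- tiny_sim()
  map <- data.frame(snp_id = paste0("s", 1:200),
                    chrom = c(rep("1", 180), rep("0", 20)),
                    pos = 1:200)
  map$mapped <- map$chrom != "0"
  res <- suppressWarnings(impute_pedigree(sim$ped, sim$geno, map = map))
  expect_equal(ncol(res$dosage), 200L)
  expect_true(all(res$dosage >= 0 & res$dosage <= 2))
})
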