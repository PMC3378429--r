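test_that("genotype loading normalises missing and invalid codes", {
  f <- tempfile()
  writeLines(c("X 0 1 2 9", "Y 0 1 2 3"), f)
  g <- load_genotypes(f, missing_code = 9)
  expect_equal(unname(g["X", ]), c(0L, 1L, 2L, 3L))
  expect_equal(unname(g["Y", ]), c(0L, 1L, 2L, 3L))  # 3 also missing internally
  writeLines("X 0 5 2", f)
  expect_equal(unname(load_genotypes(f)[1, ]), c(0L, 3L, 2L))
  expect_error(load_genotypes(f, strict = TRUE), "invalid")
  unlink(f)
})

test_that("density split uses the non-missing fraction", {
  g <- rbind(full = rep(0L, 20),
             sparse = c(rep(1L, 3), rep(3L, 17)),
             none = rep(3L, 20))
  sp <- split_density(g, 0.9)
  expect_equal(sp$hd, "full")
  expect_equal(sp$ld, "sparse")   # ungenotyped animal in neither set
})

test_that("Mendelian checking flags opposing homozygotes and is idempotent", {
  ped <- pedigree(c("P", "Q", "C"), c("0", "0", "P"), c("0", "0", "Q"))
  g <- rbind(P = c(0L, 0L, 3L), Q = c(1L, 1L, 1L), C = c(2L, 1L, 2L))
  ck <- check_mendelian(ped, g)
  expect_equal(nrow(ck$conflicts), 1L)       # P=0 vs C=2 at SNP 1 only
  expect_equal(ck$conflicts$snp, 1L)
  expect_equal(unname(ck$geno["P", 1]), 3L)
  expect_equal(unname(ck$geno["C", 1]), 3L)
  expect_equal(unname(ck$geno["C", 3]), 2L)          # missing parent cannot conflict
  expect_equal(nrow(check_mendelian(ped, ck$geno)$conflicts), 0L)

  # detection is symmetric across paternal and maternal links
  g2 <- rbind(P = c(1L, 1L), Q = c(2L, 2L), C = c(0L, 1L))
  ck2 <- check_mendelian(ped, g2)
  expect_equal(ck2$conflicts$parent, "Q")
})

test_that("panel design tiles 5-SNP windows and keeps the max-MAF SNP", {
  # 10 SNP, two windows; MAFs put the best SNP at indices 3 and 7
  freqs <- c(.1, .2, .3, .2, .1, .05, .4, .1, .2, .3)
  g <- t(replicate(400, stats::rbinom(10, 2, freqs)))
  storage.mode(g) <- "integer"
  rownames(g) <- paste0("a", 1:400)
  pan <- design_low_density_panel(g, 0.5)
  expect_length(pan$retained, 5L)
  expect_true(all(c(3L, 7L) %in% pan$retained))

  # derived count: 4221 mapped SNP at 99% masking -> 42 retained
  g2 <- matrix(1L, 2, 4221)
  rownames(g2) <- c("x", "y")
  pan2 <- design_low_density_panel(g2, 0.99)
  expect_length(pan2$retained, round(0.01 * 4221))

  # no masking retains every mapped SNP; determinism
  expect_length(design_low_density_panel(g, 0)$retained, 10L)
  expect_identical(design_low_density_panel(g, 0.8),
                   design_low_density_panel(g, 0.8))
  expect_error(design_low_density_panel(g, 0.999), "fewer than 1")
})

test_that("SNP editing drops low-MAF and high-missingness SNP", {
  g <- cbind(rep(0:2, 10),                      # common, complete
             rep(0L, 30),                       # monomorphic
             c(rep(3L, 20), rep(1L, 10)))       # 67% missing
  storage.mode(g) <- "integer"
  keep <- edit_snps(g, maf_min = 0.01, miss_max = 0.1)
  expect_equal(keep, 1L)
})

test_that("output files round-trip the phase matrix and carry dosages", {
  phase <- list(pat = rbind(A = c(1L, 9L, 0L), B = c(0L, 0L, 1L)),
                mat = rbind(A = c(1L, 0L, 9L), B = c(0L, 1L, 1L)))
  probs <- list(pat = rbind(A = c(1, 0.62, 0), B = c(0, 0, 1)),
                mat = rbind(A = c(1, 0, 0.3), B = c(0, 1, 1)))
  dir <- tempfile()
  paths <- write_outputs(phase, probs, dir)
  back <- read_phase(paths[1])
  expect_identical(back$pat, phase$pat)
  expect_identical(back$mat, phase$mat)
  pr <- readLines(paths[2])
  expect_match(pr[1], "0.6200")               # unresolved allele keeps its probability
  dos <- read.table(paths[3])
  expect_equal(dos[dos$V1 == "A", 3], 0.62)   # dosage contribution of 0.62 + 0
  expect_true(all(dos[, -1] >= 0 & dos[, -1] <= 2))
  unlink(dir, recursive = TRUE)
})

test_that("map loading marks unmapped SNP", {
  f <- tempfile()
  writeLines(c("s1 1 100", "s2 0 0", "s3 1 250"), f)
  m <- load_snp_map(f)
  expect_equal(m$mapped, c(TRUE, FALSE, TRUE))
  unlink(f)
})
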