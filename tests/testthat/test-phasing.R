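test_that("core layouts tile the chromosome with per-round offsets", {
  lay <- build_core_layout(250, 100, 2)  # round offsets 0 and 50
  expect_equal(lay[[1]]$lo, c(1L, 101L, 201L))
  expect_equal(lay[[1]]$hi, c(100L, 200L, 250L))
  expect_equal(lay[[2]]$lo, c(1L, 51L, 151L))
  expect_equal(lay[[2]]$hi, c(50L, 150L, 250L))
  # chromosome shorter than a core: single core
  lay2 <- build_core_layout(80, 100, 3)
  for (r in 1:3) expect_equal(unlist(lay2[[r]]), c(lo = 1L, hi = 80L))
  # every SNP in exactly one core per round
  for (r in 1:2) {
    covered <- unlist(Map(seq, lay[[r]]$lo, lay[[r]]$hi))
    expect_equal(sort(covered), 1:250)
    expect_false(any(duplicated(covered)))
  }
})

test_that("surrogates are side-classified by pedigree path and screened for
           opposing homozygotes", {
  # gds/gdd: maternal grandsire/granddam; "aunt" descends only from gdd
  ped <- pedigree(c("gds", "gdd", "s", "d", "i", "aunt"),
                  c("0", "0", "0", "gds", "s", "0"),
                  c("0", "0", "0", "gdd", "d", "gdd"))
  ids <- ped$id
  L <- 20
  g <- matrix(1L, length(ids), L, dimnames = list(ids, NULL))
  g["s", ] <- 0L                     # genotyped sire, no opposing homozygotes
  g["aunt", ] <- 1L
  sur <- find_surrogates(g, ped, c(1, L), hd_ids = ids)
  i_row <- match("i", ids)
  i_pos <- which(ids == "i")
  pat <- sur$pat[[i_pos]]; mat <- sur$mat[[i_pos]]
  expect_true(match("s", ids) %in% pat)       # genotyped sire is paternal
  expect_true(match("aunt", ids) %in% mat)    # connected only via maternal granddam
  expect_true(match("gds", ids) %in% mat)

  # one opposing homozygote with max_mismatch 0 excludes the candidate
  g2 <- g
  g2["aunt", 5] <- 0L
  g2["i", 5] <- 2L
  sur2 <- find_surrogates(g2, ped, c(1, L), hd_ids = ids)
  expect_false(match("aunt", ids) %in% sur2$mat[[i_pos]])
  # ... but a tolerance of 1 readmits it
  sur3 <- find_surrogates(g2, ped, c(1, L), max_mismatch = 1, hd_ids = ids)
  expect_true(match("aunt", ids) %in% sur3$mat[[i_pos]])
})

test_that("core phasing follows surrogate consensus rules", {
  ped <- pedigree(c("s", "d", "i"), c("0", "0", "s"), c("0", "0", "d"))
  ids <- ped$id
  #          s        d        i
  g <- rbind(c(2L, 1L, 2L, 2L),
             c(0L, 1L, 1L, 0L),
             c(1L, 1L, 2L, 1L))
  dimnames(g) <- list(ids, NULL)
  sur <- find_surrogates(g, ped, c(1, 4), hd_ids = ids)
  pc <- phase_core(g, sur, c(1, 4), ids, ped)
  i <- match("i", ids)
  expect_equal(pc$pat[i, 1], 1L)   # sire homozygous 1 -> paternal allele 1
  expect_equal(pc$mat[i, 1], 0L)   # maternal is the complement
  expect_equal(pc$pat[i, 3], 1L)   # homozygote phases itself
  expect_equal(pc$mat[i, 3], 1L)
  expect_equal(pc$pat[i, 2], 9L)   # het sire uninformative, het stays open

  # conflicting informative surrogates leave the locus unphased
  ped2 <- pedigree(c("s", "gs", "d", "i"), c("0", "0", "0", "s"),
                   c("0", "0", "0", "d"))
  g2 <- rbind(s = c(0L), gs = c(2L), d = c(1L), i = c(1L))
  g2 <- matrix(g2, 4, 1, dimnames = list(c("s", "gs", "d", "i"), NULL))
  ped2 <- pedigree(c("gs", "s", "d", "i"), c("0", "gs", "0", "s"),
                   c("0", "0", "0", "d"))
  ids2 <- ped2$id
  g2 <- g2[ids2, , drop = FALSE]
  sur2 <- find_surrogates(g2, ped2, c(1, 1), hd_ids = ids2)
  pc2 <- phase_core(g2, sur2, c(1, 1), ids2, ped2)
  expect_equal(pc2$pat[match("i", ids2), 1], 9L)
})

test_that("haplotype libraries deduplicate, count and complete", {
  pat <- rbind(c(0L, 1L, 1L, 0L), c(0L, 1L, 1L, 0L))
  mat <- rbind(c(1L, 0L, 0L, 1L), c(0L, 9L, 1L, 0L))
  lib <- build_library(pat, mat, rows = 1:2)
  key <- apply(lib$haps, 1, paste, collapse = "")
  expect_equal(sort(key), c("0110", "1001"))
  # (0,?,1,0) uniquely completed to (0,1,1,0) and counted
  expect_equal(lib$counts[key == "0110"], 3L)
  expect_equal(lib$mat[2, 2], 1L)

  # ambiguous partial gamete is not completed
  pat2 <- rbind(c(0L, 1L, 1L, 0L), c(0L, 0L, 1L, 0L), c(9L, 9L, 9L, 9L))
  mat2 <- rbind(c(0L, 9L, 1L, 0L), c(1L, 1L, 1L, 1L), c(9L, 9L, 9L, 9L))
  lib2 <- build_library(pat2, mat2, rows = 1:3)
  expect_equal(lib2$mat[1, 2], 9L)

  # fully homozygous input yields exactly the homozygous haplotypes
  hompat <- rbind(c(0L, 0L), c(1L, 1L))
  lib3 <- build_library(hompat, hompat, rows = 1:2)
  expect_equal(sort(apply(lib3$haps, 1, paste, collapse = "")), c("00", "11"))
})

test_that("long-range phasing of the small fixture is accurate and
           deterministic", {
  sim <- tiny_sim()
  ph <- phase_hd(sim$ped, sim$geno, sim$hd_ids)
  pa <- phase_accuracy(list(pat = ph$pat, mat = ph$mat), sim$truth,
                       setdiff(sim$hd_ids, ph$base_ids))
  expect_gt(mean(pa$agreement, na.rm = TRUE), 0.98)
  expect_gt(mean(pa$yield), 0.9)
  # no phased allele contradicts the observed genotype
  g <- sim$geno[sim$hd_ids, ]
  p <- ph$pat[sim$hd_ids, ]; m <- ph$mat[sim$hd_ids, ]
  both <- p != 9 & m != 9 & g != 3
  expect_true(all((p[both] + m[both]) == g[both]))
  # determinism: identical inputs give identical libraries and phase
  ph2 <- phase_hd(sim$ped, sim$geno, sim$hd_ids)
  expect_identical(ph$pat, ph2$pat)
  expect_identical(ph$rounds[[1]]$libs, ph2$rounds[[1]]$libs)
})

test_that("externally phased input is honoured verbatim", {
  sim <- tiny_sim()
  ids <- sim$hd_ids[1:5]
  ext <- list(pat = sim$truth$pat[ids, , drop = FALSE],
              mat = sim$truth$mat[ids, , drop = FALSE])
  ph <- phase_hd(sim$ped, sim$geno, sim$hd_ids, phased_input = ext)
  expect_identical(ph$pat[ids, ], ext$pat)
  expect_identical(ph$mat[ids, ], ext$mat)
})
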