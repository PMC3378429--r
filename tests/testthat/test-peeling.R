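test_that("penetrance maps genotype codes to ordered-state likelihoods", {
  expect_equal(penetrance(0), c(1, 0, 0, 0))
  expect_equal(penetrance(1), c(0, .5, .5, 0))
  expect_equal(penetrance(2), c(0, 0, 0, 1))
  expect_equal(penetrance(3), rep(.25, 4))
  expect_error(penetrance(5))
})

test_that("peeling reproduces closed-form single-family posteriors", {
  ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
  p <- 0.3
  cfg <- peel_config(allele_freq = p)

  # unobserved founder keeps the Hardy-Weinberg prior
  post <- peel_locus(ped, c(A = 3L, B = 3L, C = 3L), cfg)
  expect_equal(unname(post["A", ]),
               c((1 - p)^2, p * (1 - p), p * (1 - p), p^2), tolerance = 1e-9)

  # homozygous parents force the offspring genotype
  post <- peel_locus(ped, c(A = 0L, B = 0L, C = 3L), cfg)
  expect_equal(unname(post["C", ]), c(1, 0, 0, 0), tolerance = 1e-9)
  post <- peel_locus(ped, c(A = 2L, B = 0L, C = 3L), cfg)
  expect_equal(unname(post["C", ]), c(0, 0, 1, 0), tolerance = 1e-9)  # pat 1, mat 0

  # het x het parents: offspring dosage 1.0 by symmetry
  post <- peel_locus(ped, c(A = 1L, B = 1L, C = 3L), cfg)
  expect_equal(sum(post["C", ] * c(0, 1, 1, 2)), 1, tolerance = 1e-9)
})

test_that("allele calls obey the call threshold", {
  post <- array(0, c(3, 1, 4))
  post[1, 1, ] <- c(0, 0, 0, 1)            # certain (1,1)
  post[2, 1, ] <- c(0.005, 0, 0, 0.995)    # p1 = 0.995 both gametes
  post[3, 1, ] <- c(0.02, 0, 0, 0.98)      # p1 = 0.98: below threshold
  dimnames(post) <- list(c("a", "b", "c"), NULL, NULL)
  cal <- call_alleles(post, peel_config(call_threshold = 0.99))
  expect_equal(unname(cal$pat[, 1]), c(1L, 1L, 9L))
  expect_equal(unname(cal$mat[, 1]), c(1L, 1L, 9L))
  expect_equal(unname(cal$p_pat[3, 1]), 0.98)  # probability retained
})

test_that("called alleles never contradict observed genotypes", {
  set.seed(5)
  for (rep in 1:10) {
    ped <- rand_tree_pedigree(8)
    p <- stats::runif(1, .2, .8)
    obs <- drop_locus(ped, p)
    post <- peel_locus(ped, stats::setNames(obs, ped$id),
                       peel_config(allele_freq = p))
    dim(post) <- c(nrow(post), 1, 4)
    cal <- call_alleles(post, peel_config())
    g <- obs
    both <- cal$pat[, 1] != 9 & cal$mat[, 1] != 9 & g != 3
    expect_true(all((cal$pat[both, 1] + cal$mat[both, 1]) == g[both]))
  }
})

test_that("observing a relative never increases expected uncertainty", {
  # conditional entropy <= marginal entropy, computed exactly via peeling
  set.seed(31)
  for (rep in 1:12) {
    ped <- rand_tree_pedigree(7)
    n <- length(ped$id)
    if (n < 3) next
    p <- stats::runif(1, .2, .8)
    cfg <- peel_config(allele_freq = p, convergence_tol = 1e-10,
                       max_iterations = 60)
    obs <- drop_locus(ped, p, mask = 0.7)
    target <- sample(which(obs == 3L), 1)
    rel <- sample(setdiff(seq_len(n), target), 1)
    obs_rel <- obs
    base <- peel_locus(ped, stats::setNames(obs, ped$id), cfg)
    h0 <- entropy4(base[target, ])
    relg <- base[rel, ]
    pg <- c(relg[1], relg[2] + relg[3], relg[4])   # P(genotype 0/1/2)
    h1 <- 0
    for (gv in 0:2) {
      if (pg[gv + 1] < 1e-12) next
      obs_rel[rel] <- gv
      cond <- peel_locus(ped, stats::setNames(obs_rel, ped$id), cfg)
      h1 <- h1 + pg[gv + 1] * entropy4(cond[target, ])
    }
    expect_lte(h1, h0 + 1e-6)
  }
})

test_that("unmapped-mode imputation handles forced and uninformative cases", {
  # all founders homozygous 0: every descendant dosage exactly 0
  ped <- pedigree(c("A", "B", "C", "D", "E"),
                  c("0", "0", "A", "A", "C"),
                  c("0", "0", "B", "B", "D"))
  g <- rbind(A = 0L, B = 0L)
  g <- matrix(0L, 2, 5, dimnames = list(c("A", "B"), NULL))
  res <- impute_unmapped(ped, g, peel_config(allele_freq = rep(0.4, 5)))
  expect_equal(unname(res$dosage[c("C", "D", "E"), ]),
               matrix(0, 3, 5), tolerance = 1e-9)

  # ungenotyped animal unrelated to genotyped ones: dosage 2p from the prior
  ped2 <- pedigree(c("A", "B", "Z"), c("0", "0", "0"), c("0", "0", "0"))
  g2 <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL))
  res2 <- impute_unmapped(ped2, g2, peel_config(allele_freq = 0.3))
  expect_equal(unname(res2$dosage["Z", 1]), 0.6, tolerance = 1e-9)
})

test_that("mean founder dosage converges to twice the allele frequency", {
  p <- 0.35
  n <- 400
  ped <- pedigree(as.character(1:n), rep("0", n), rep("0", n))
  g <- matrix(3L, 1, 1, dimnames = list("1", NULL))
  res <- impute_unmapped(ped, g, peel_config(allele_freq = p))
  expect_equal(mean(res$dosage), 2 * p, tolerance = 1e-6)
})
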