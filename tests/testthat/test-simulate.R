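test_that("simulated pedigrees have discrete generations and valid ranks", {
  cfg <- sim_config(n_founders = 10, n_generations = 1, seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_length(ped$id, 10L)
  expect_true(all(ped$sire == 0L & ped$dam == 0L))

  cfg2 <- sim_config(n_founders = 20, n_generations = 3, n_offspring = 10,
                     n_sires = 3, n_dams = 5, seed = 2)
  ped2 <- simulate_pedigree(cfg2)
  expect_length(ped2$id, 40L)
  known <- ped2$sire > 0
  expect_true(all(ped2$rank[known] > ped2$rank[ped2$sire[known]]))
})

test_that("founder haplotypes honour drawn frequencies and the LD dial", {
  cfg <- sim_config(n_founders = 1000, n_snp = 300, ld_decay = 0, seed = 5)
  fh <- simulate_founder_haplotypes(cfg)
  emp <- colMeans(fh$haps)
  # law of large numbers at 2000 haplotypes: binomial standard error ~ 0.011
  expect_lt(max(abs(emp - fh$freq)), 0.05)
  # ld_decay = 0: adjacent loci essentially uncorrelated
  r_adj <- sapply(2:300, function(j) abs(cor(fh$haps[, j - 1], fh$haps[, j])))
  expect_lt(mean(r_adj), 0.03)

  cfg2 <- sim_config(n_founders = 1000, n_snp = 300, ld_decay = 0.97, seed = 5)
  fh2 <- simulate_founder_haplotypes(cfg2)
  r_adj2 <- sapply(2:300, function(j) cor(fh2$haps[, j - 1], fh2$haps[, j]))
  expect_gt(mean(r_adj2, na.rm = TRUE), 0.5)   # strong neighbour correlation
})

test_that("gene dropping transmits haplotypes with Poisson crossovers", {
  # morgans = 0: every gamete is an intact parental haplotype
  cfg <- sim_config(n_founders = 6, n_generations = 2, n_offspring = 20,
                    n_sires = 2, n_dams = 3, n_snp = 50, morgans = 0, seed = 3)
  ped <- simulate_pedigree(cfg)
  fh <- simulate_founder_haplotypes(cfg)
  tr <- gene_drop(ped, fh, cfg)
  for (i in which(ped$sire > 0)) {
    s <- ped$sire[i]
    expect_true(identical(tr$pat[i, ], tr$pat[s, ]) ||
                  identical(tr$pat[i, ], tr$mat[s, ]))
  }
  # genotype identity and Mendelian consistency by construction
  expect_identical(tr$geno, tr$pat + tr$mat)
  expect_equal(nrow(check_mendelian(ped, tr$geno)$conflicts), 0L)

  # crossover counts have the right mean
  cfg2 <- sim_config(n_founders = 40, n_generations = 2, n_offspring = 2000,
                     n_sires = 10, n_dams = 20, n_snp = 20, morgans = 1.5,
                     seed = 4)
  ped2 <- simulate_pedigree(cfg2)
  tr2 <- gene_drop(ped2, simulate_founder_haplotypes(cfg2), cfg2)
  nx <- unlist(lapply(tr2$crossovers[ped2$sire > 0],
                      function(x) lengths(x)))
  expect_equal(mean(nx), 1.5, tolerance = 0.1)
})

test_that("scenarios mask to the designed panel without altering kept SNP", {
  sim <- tiny_sim()
  ret <- sim$panel$retained
  expect_equal(length(ret) / 200, 0.15, tolerance = 0.02)
  expect_identical(sim$geno[sim$test_ids, ret],
                   sim$truth$geno[sim$test_ids, ret])
  off <- setdiff(seq_len(200), ret)
  expect_true(all(sim$geno[sim$test_ids, off] == 3L))
  expect_identical(sim$geno[sim$hd_ids, ], sim$truth$geno[sim$hd_ids, ])
  # HD animals are the parents; test animals their non-breeding descendants
  expect_true(all(classify_ancestry(sim$ped, sim$hd_ids, sim$test_ids) ==
                    "BothParents"))
})

test_that("the simulator is byte-identical under a fixed seed", {
  a <- simulate_dataset(sim_config(n_founders = 30, n_generations = 3,
                                   n_offspring = 30, n_sires = 4, n_dams = 10,
                                   n_snp = 60, n_test = 20, seed = 9))
  b <- simulate_dataset(sim_config(n_founders = 30, n_generations = 3,
                                   n_offspring = 30, n_sires = 4, n_dams = 10,
                                   n_snp = 60, n_test = 20, seed = 9))
  expect_identical(a$truth$pat, b$truth$pat)
  expect_identical(a$geno, b$geno)
  expect_identical(a$hd_ids, b$hd_ids)
})
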