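# Independent oracles used by the tests.

# Exhaustive-enumeration posterior for single-locus segregation analysis:
# sums the joint probability over all 4^n ordered-genotype configurations.
# Only feasible for tiny pedigrees; the reference the peeling engine is
# checked against.
brute_peel <- function(ped, obs, p) {
  n <- length(ped$id)
  states <- as.matrix(expand.grid(rep(list(0:3), n)))
  a <- states %/% 2
  b <- states %% 2
  penm <- rbind(c(1, 0, 0, 0), c(0, .5, .5, 0), c(0, 0, 0, 1),
                c(.25, .25, .25, .25))
  t1 <- c(0, .5, .5, 1)
  lp <- rep(1, nrow(states))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    pr_a <- if (s == 0) ifelse(a[, i] == 1, p, 1 - p) else
      ifelse(a[, i] == 1, t1[states[, s] + 1], 1 - t1[states[, s] + 1])
    pr_b <- if (d == 0) ifelse(b[, i] == 1, p, 1 - p) else
      ifelse(b[, i] == 1, t1[states[, d] + 1], 1 - t1[states[, d] + 1])
    lp <- lp * pr_a * pr_b * penm[cbind(obs[i] + 1, states[, i] + 1)]
  }
  out <- sapply(seq_len(n), function(i) tapply(lp, states[, i], sum))
  t(out) / sum(lp)
}

# Random loop-free pedigree: a reused parent is always mated to a fresh
# founder, so the undirected pedigree graph stays a tree.
rand_tree_pedigree <- function(n_target) {
  sire <- dam <- integer(0)
  k <- 0
  while (k < n_target) {
    if (k < 2 || stats::runif(1) < 0.4) {
      k <- k + 1; sire[k] <- 0; dam[k] <- 0
    } else {
      par <- sample(k, 1)
      k <- k + 1; sire[k] <- 0; dam[k] <- 0       # fresh founder mate
      fo <- k
      k <- k + 1; sire[k] <- par; dam[k] <- fo
    }
  }
  pedigree(as.character(seq_len(k)), as.character(sire), as.character(dam))
}

# Mendelian-consistent genotypes for a pedigree by direct allele dropping
# (single locus); returns observed codes after random masking.
drop_locus <- function(ped, p, mask = 0.5) {
  n <- length(ped$id)
  al <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    al[i, 1] <- if (ped$sire[i] == 0) stats::rbinom(1, 1, p) else
      al[ped$sire[i], sample(2, 1)]
    al[i, 2] <- if (ped$dam[i] == 0) stats::rbinom(1, 1, p) else
      al[ped$dam[i], sample(2, 1)]
  }
  obs <- rowSums(al)
  obs[stats::runif(n) < mask] <- 3L
  obs
}

entropy4 <- function(v) {
  v <- v[v > 0]
  -sum(v * log(v))
}
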