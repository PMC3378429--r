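#' Simulation configuration
#'
#' Settings for the gene-dropping simulator that generates pedigrees,
#' LD-structured founder haplotypes, Mendelian transmission with
#' recombination, and the masking scenarios used to test imputation.
#'
#' The defaults define the standard study fixture: 1000 SNP on a 1 Morgan
#' chromosome, a 6-generation pedigree of ~1500 animals (200 founders plus
#' five 260-offspring generations bred from 25 sires and 100 dams per
#' generation), every parent genotyped at high density, and the 500 youngest
#' non-parents as the low-density test set.
#'
#' @param n_founders number of base-generation animals.
#' @param n_generations total generations including founders.
#' @param n_offspring offspring born per non-founder generation.
#' @param n_sires,n_dams breeding males/females used per generation.
#' @param n_snp number of SNP on the chromosome.
#' @param morgans chromosome genetic length in Morgans (expected crossovers
#'   per transmitted gamete).
#' @param ld_decay correlation parameter in \[0, 1) of the latent first-order
#'   autoregressive process that generates founder haplotypes; higher values
#'   give longer haplotype blocks.
#' @param maf_range interval from which per-SNP allele-1 frequencies are
#'   drawn uniformly.
#' @param n_test number of low-density test animals.
#' @param mask_fraction proportion of SNP masked on test animals (e.g. 0.99,
#'   0.95, 0.90, 0.85).
#' @param hd_assignment which animals are genotyped at high density:
#'   `"parents"` (every animal with offspring), `"sires"` (male parents
#'   only), or `"random_parents"` (a random `hd_fraction` of parents).
#' @param hd_fraction fraction of parents kept high density under
#'   `"random_parents"`.
#' @param avoid_full_sibs avoid mating full sibs (default `TRUE`).
#' @param seed integer seed; the whole simulation is reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200L, n_generations = 6L,
                       n_offspring = 260L, n_sires = 25L, n_dams = 100L,
                       n_snp = 1000L, morgans = 1, ld_decay = 0.95,
                       maf_range = c(0.1, 0.5), n_test = 500L,
                       mask_fraction = 0.85, hd_assignment = "parents",
                       hd_fraction = 0.5, avoid_full_sibs = TRUE, seed = 1L) {
  stopifnot(n_founders > 0, n_generations >= 1, n_snp > 0, morgans >= 0,
            ld_decay >= 0, ld_decay < 1, length(maf_range) == 2,
            mask_fraction >= 0, mask_fraction < 1)
  hd_assignment <- match.arg(hd_assignment, c("parents", "sires", "random_parents"))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: founders first, then each generation's offspring
#' get a sire and dam sampled from the selected breeders of the previous
#' generation (dams nested within sires, litter-mates share both parents).
#' Sexes are assigned half and half. Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @return A [pedigree] object, with attribute `"sex"` (`"M"`/`"F"` per
#'   individual, pedigree order).
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  id <- paste0("F", seq_len(cfg$n_founders))
  sire <- dam <- rep("0", cfg$n_founders)
  sex <- rep(c("M", "F"), length.out = cfg$n_founders)
  prev_ids <- id
  prev_sex <- sex
  prev_sire_of <- stats::setNames(rep("0", length(id)), id)
  prev_dam_of <- stats::setNames(rep("0", length(id)), id)
  for (g in seq_len(cfg$n_generations - 1L)) {
    males <- prev_ids[prev_sex == "M"]
    females <- prev_ids[prev_sex == "F"]
    sires_g <- sample(males, min(cfg$n_sires, length(males)))
    dams_g <- sample(females, min(cfg$n_dams, length(females)))
    # nest dams within sires; optionally resample full-sib matings
    mate_sire <- sample(rep(sires_g, length.out = length(dams_g)))
    if (cfg$avoid_full_sibs) {
      for (k in seq_along(dams_g)) {
        full_sib <- function(s, d) {
          prev_sire_of[[s]] != "0" && prev_sire_of[[s]] == prev_sire_of[[d]] &&
            prev_dam_of[[s]] == prev_dam_of[[d]]
        }
        tries <- 0
        while (full_sib(mate_sire[k], dams_g[k]) && tries < 20) {
          mate_sire[k] <- sample(sires_g, 1)
          tries <- tries + 1
        }
      }
    }
    off_dam <- dams_g[(seq_len(cfg$n_offspring) - 1L) %% length(dams_g) + 1L]
    off_sire <- mate_sire[match(off_dam, dams_g)]
    off_id <- paste0("G", g, "_", seq_len(cfg$n_offspring))
    off_sex <- rep(c("M", "F"), length.out = cfg$n_offspring)
    id <- c(id, off_id); sire <- c(sire, off_sire); dam <- c(dam, off_dam)
    sex <- c(sex, off_sex)
    prev_sire_of <- stats::setNames(sire, id)[off_id]
    prev_dam_of <- stats::setNames(dam, id)[off_id]
    names(prev_sire_of) <- names(prev_dam_of) <- off_id
    prev_ids <- off_id
    prev_sex <- off_sex
  }
  ped <- pedigree(id, sire, dam)
  attr(ped, "sex") <- stats::setNames(sex, id)[ped$id]
  ped
}

#' Simulate founder haplotypes with linkage disequilibrium
#'
#' Per-SNP allele-1 frequencies are drawn uniformly from `maf_range`. Each
#' founder haplotype is generated through a Gaussian copula: a latent
#' first-order autoregressive chain with parameter `ld_decay` is thresholded
#' at each SNP's frequency, so marginal allele frequencies equal the drawn
#' frequencies exactly while neighbouring SNP are correlated, producing the
#' blocky LD that haplotype libraries exploit.
#'
#' @param cfg a [sim_config()].
#' @return `list(freq = <numeric L>, haps = <integer matrix 2*n_founders x L>)`.
#' @export
simulate_founder_haplotypes <- function(cfg) {
  set.seed(cfg$seed + 1L)
  L <- cfg$n_snp
  freq <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])
  H <- 2L * cfg$n_founders
  rho <- cfg$ld_decay
  z <- matrix(stats::rnorm(H * L), H, L)
  if (rho > 0) {
    for (j in 2:L) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  haps <- matrix(0L, H, L)
  haps[stats::pnorm(z) < rep(freq, each = H)] <- 1L
  list(freq = freq, haps = haps)
}

#' Gene-drop haplotypes through a pedigree
#'
#' Founders receive consecutive haplotype pairs; every transmitted gamete
#' recombines the parent's two haplotypes with a Poisson(`morgans`) number
#' of crossovers at uniform genetic positions. The true phase (paternal and
#' maternal gamete of every individual) and all crossover positions are
#' recorded.
#'
#' @param ped a [pedigree] (topological order).
#' @param founder_haps result of [simulate_founder_haplotypes()].
#' @param cfg a [sim_config()].
#' @return Object of class `truth_set`: list with `pat`, `mat` (integer
#'   allele matrices n x L), `geno` (their sum), `freq`, and `crossovers`
#'   (list per individual of the two crossover-position vectors).
#' @export
gene_drop <- function(ped, founder_haps, cfg) {
  set.seed(cfg$seed + 2L)
  n <- length(ped$id)
  L <- cfg$n_snp
  pos <- seq(0, cfg$morgans, length.out = L)   # genetic positions of SNP
  pat <- mat <- matrix(0L, n, L, dimnames = list(ped$id, NULL))
  xovers <- vector("list", n)
  founder_next <- 1L
  make_gamete <- function(h1, h2) {
    k <- stats::rpois(1, cfg$morgans)
    cuts <- sort(stats::runif(k, 0, cfg$morgans))
    strand <- (findInterval(pos, cuts) + stats::rbinom(1, 1, 0.5)) %% 2L
    list(g = ifelse(strand == 0L, h1, h2), cuts = cuts)
  }
  for (i in seq_len(n)) {
    cuts_i <- list(numeric(0), numeric(0))
    if (ped$sire[i] == 0L) {
      pat[i, ] <- founder_haps$haps[founder_next, ]
      founder_next <- founder_next + 1L
    } else {
      s <- ped$sire[i]
      gm <- make_gamete(pat[s, ], mat[s, ])
      pat[i, ] <- gm$g
      cuts_i[[1]] <- gm$cuts
    }
    if (ped$dam[i] == 0L) {
      mat[i, ] <- founder_haps$haps[founder_next, ]
      founder_next <- founder_next + 1L
    } else {
      d <- ped$dam[i]
      gm <- make_gamete(pat[d, ], mat[d, ])
      mat[i, ] <- gm$g
      cuts_i[[2]] <- gm$cuts
    }
    xovers[[i]] <- cuts_i
  }
  structure(list(pat = pat, mat = mat, geno = pat + mat,
                 freq = founder_haps$freq, crossovers = xovers),
            class = "truth_set")
}

#' Apply a genotyping scenario to a truth set
#'
#' Selects the high-density set according to `cfg$hd_assignment`, selects the
#' `cfg$n_test` youngest non-HD animals as the low-density test set, designs
#' the low-density panel from the HD animals' minor allele frequencies at
#' `cfg$mask_fraction`, and masks test animals down to the panel. Remaining
#' animals are ungenotyped.
#'
#' @param truth a `truth_set` from [gene_drop()].
#' @param ped the [pedigree] used to generate it.
#' @param cfg a [sim_config()].
#' @return List with `geno` (matrix of all pedigree individuals; ungenotyped
#'   rows all-missing), `hd_ids`, `test_ids`, `panel`, `categories` (ancestry
#'   category factor for test animals).
#' @export
apply_scenario <- function(truth, ped, cfg) {
  set.seed(cfg$seed + 3L)
  n <- length(ped$id)
  is_parent <- seq_len(n) %in% c(ped$sire, ped$dam)
  sex <- attr(ped, "sex")
  hd <- switch(cfg$hd_assignment,
    parents = is_parent,
    sires = is_parent & !is.null(sex) & sex == "M",
    random_parents = is_parent & stats::runif(n) < cfg$hd_fraction)
  hd_ids <- ped$id[hd]
  nonhd <- which(!hd)
  # youngest first: highest generation rank, then latest pedigree position
  ord <- nonhd[order(ped$rank[nonhd], seq_along(ped$id)[nonhd], decreasing = TRUE)]
  test_ids <- ped$id[sort(ord[seq_len(min(cfg$n_test, length(ord)))])]

  geno <- matrix(GENO_MISSING, n, cfg$n_snp, dimnames = list(ped$id, NULL))
  geno[hd_ids, ] <- truth$geno[hd_ids, ]
  panel <- design_low_density_panel(truth$geno, cfg$mask_fraction, rows = hd_ids)
  geno[test_ids, panel$retained] <- truth$geno[test_ids, panel$retained]
  list(geno = geno, hd_ids = hd_ids, test_ids = test_ids, panel = panel,
       categories = classify_ancestry(ped, hd_ids, test_ids))
}

#' Simulate a complete imputation test dataset
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_founder_haplotypes()], [gene_drop()] and [apply_scenario()].
#'
#' @param cfg a [sim_config()].
#' @return List with `ped`, `truth`, and the elements of [apply_scenario()].
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ped <- simulate_pedigree(cfg)
  fh <- simulate_founder_haplotypes(cfg)
  truth <- gene_drop(ped, fh, cfg)
  sc <- apply_scenario(truth, ped, cfg)
  c(list(ped = ped, truth = truth, cfg = cfg), sc)
}
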