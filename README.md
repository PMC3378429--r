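# pedimpute

Phasing and genotype imputation for pedigreed populations.

Genomic selection needs dense SNP genotypes on many animals, but genotyping
every animal at high density is expensive. In most livestock breeding
programs a minority of animals (sires, key dams) carry high-density (HD)
genotypes, candidates for selection carry a cheap low-density (LD) panel,
and the bulk of the pedigree is not genotyped at all. `pedimpute` imputes
phased alleles, per-gamete allele probabilities and real-valued dosages for
**every** animal in the pedigree — HD, LD or ungenotyped — so that all
pedigree, genomic and phenotypic information can be combined in a
single-stage genomic evaluation (the dosage matrix plugs directly into any
SNP-BLUP / Bayesian regression that accepts real-valued design entries).

## Method

The algorithm combines three sources of information, in three steps:

1. **Single-locus segregation analysis (iterative peeling).** For each SNP
   independently, ordered-genotype probabilities
   P(g_i = (a_pat, a_mat) | data) are computed for every individual *i* by
   message passing on the pedigree: founders carry a Hardy–Weinberg prior at
   the locus allele frequency *p*; anterior sweeps push Mendelian
   transmission probabilities down the pedigree and posterior sweeps push
   offspring likelihoods back up, iterated to a fixed point. The method is
   exact on loop-free pedigrees and a damped approximation on looped ones.
   Alleles with P(allele = 1) > 0.99 (or < 0.01) are imputed; the rest stay
   probabilistic.

2. **Long-range phasing and haplotype libraries.** HD animals are phased
   within *cores* (windows of ~100 SNP, re-tiled over several offset
   rounds). At a heterozygous locus the paternal allele is called when all
   informative *surrogate parents* — paternal-side relatives carrying no
   opposing homozygote over the core and its flanks — agree. Distinct
   resolved haplotypes per core form a library; partial gametes are
   completed against it, and base animals (unknown parents) are resolved
   into per-core haplotype pairs consistent with their genotype.

3. **Haplotype-matching imputation.** A fixed hierarchy of deterministic
   rules propagates phase through the whole pedigree: four cheap "minor"
   rules (parent-homozygous fill-in, genotype complement, parents from
   progeny, genotype from alleles) run after each of nine "major" steps —
   probability calls, base-animal strand assembly, candidate-library votes,
   parental- and own-phase votes, internally rebuilt libraries, and a
   bidirectional recombination scan that tracks which parental gamete each
   chromosome segment came from. The cycle repeats a configurable number of
   times; finally allele probabilities are recalculated by peeling on the
   updated genotypes and the dosage matrix (sum of the two gamete
   probabilities, in [0, 2]) is emitted.

Every fill is monotone (a resolved allele is never changed) and every run
is bit-reproducible given the same inputs and configuration.

## Worked example

Simulate the standard test design — a six-generation pedigree of ~1500
animals on a 1000-SNP chromosome, all parents HD-genotyped, and the 500
youngest animals carrying a 5% low-density panel — then impute and score:

```r
library(pedimpute)

cfg <- sim_config(seed = 42, mask_fraction = 0.95)   # 95% of SNP masked
sim <- simulate_dataset(cfg)
res <- impute_pedigree(sim$ped, sim$geno)
res
#> <impute_result> 1500 individuals x 1000 SNP
#>   alleles called without ambiguity: 90.4%
#>   conflicts: 8813

masked <- setdiff(seq_len(1000), sim$panel$retained)
acc <- imputation_accuracy(res, sim$truth, ids = sim$test_ids,
                           masked = masked, categories = sim$categories)
category_summary(acc)
#> # A tibble: 1 × 3
#>   category        n mean_r
#>   <fct>       <int>  <dbl>
#> 1 BothParents   500  0.982
```

`mean_r` is the mean per-animal Pearson correlation between true genotypes
and imputed dosages over the masked SNP: with both parents genotyped and
only 5% of SNP observed, the 500 test animals are imputed at *r* = 0.98
(per-animal median 0.99). `ambiguity_profile()` reports the percentage of
alleles hard-called per gamete — animals below ~90% tend to impute worse
and are flagged. `write_outputs()` writes the phased-allele,
allele-probability and dosage files; `plot_accuracy_histogram()`,
`plot_accuracy_vs_ambiguity()` and `plot_category_accuracy()` draw the
standard diagnostics.

A command-line wrapper is installed at `inst/cli/impute.R`:

```sh
Rscript inst/cli/impute.R --pedigree ped.txt --genotypes geno.txt \
    [--map map.txt] --out OUTDIR [--unmapped-only] [--core-length 100] \
    [--outer-iterations 3] [--seed 1] [--phased-input phased.txt]
```

SNP without map positions (chromosome `0` in the map file), or a run with
`--unmapped-only`, use the peeling-only path: single-locus probabilities
and phasing rules, no haplotype information.

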