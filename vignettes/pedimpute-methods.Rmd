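---
title: "Phasing and imputation in pedigreed populations: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing and imputation in pedigreed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pedimpute)
```

`pedimpute` imputes biallelic SNP alleles, allele probabilities and dosages
for every member of a pedigree from a mixture of high-density (HD),
low-density (LD) and absent genotypes. This vignette is the package's own
account of the underlying models, the reconstruction choices that had to be
made where the published algorithm family leaves details open, and what the
simulation-based tests do and do not demonstrate.

## 1. Single-locus segregation analysis

Each SNP is treated independently. The state of individual $i$ is its
*ordered* genotype $g_i = (a_i^{pat}, a_i^{mat}) \in \{0,1\}^2$. The joint
model over the pedigree is

$$P(\mathbf g \mid \text{data}) \propto \prod_{i \in \text{founders}}
\pi(g_i)\; \prod_{i \notin \text{founders}} T(g_i \mid g_{s(i)}, g_{d(i)})\;
\prod_i L(y_i \mid g_i),$$

where $\pi$ is Hardy–Weinberg at the locus allele-1 frequency $p$,
$T$ factorises into independent transmissions ($P(\text{transmit } 1 \mid g)
= 0, \tfrac12, \tfrac12, 1$ for the four states), and the penetrance $L$
maps an observed code 0/1/2 to its compatible states (missing = flat).

Marginals are computed by iterative peeling: an anterior sweep in pedigree
order (each individual receives the joint distribution of its parents,
*excluding its own descendants' evidence*, pushed through $T$) and a
posterior sweep in reverse order (each family sends its children's
likelihood back to the parents). On loop-free pedigrees this is belief
propagation on a tree: the fixed point is the exact posterior, which the
test suite verifies against exhaustive enumeration of all $4^n$
configurations on hundreds of random pedigrees. Pedigrees with loops
(inbreeding, cycles through common ancestors) make the iteration
approximate; a damping factor of 0.5 on the upward messages is switched on
when the sweep-to-sweep change grows, which stabilises oscillation.

Numerical choices: convergence is declared when no genotype probability
moves by more than `convergence_tol` ($10^{-4}$ by default) between sweeps,
with at most `max_iterations` (20) sweeps; allele frequencies are estimated
once from the HD animals (with a half-count shrinkage so monomorphic SNP
never produce a degenerate prior) and are not re-estimated during peeling,
which avoids feedback drift. An individual whose observation drives its
posterior mass to zero (an inconsistency that survived Mendelian cleaning)
has that observation reset to missing, with a warning.

Alleles are called from the marginal per-gamete probabilities
$P(a^{pat} = 1)$, $P(a^{mat} = 1)$ when they exceed the call threshold
(0.99) or fall below its complement. The threshold must exceed 0.5; values
near 1 trade yield for accuracy.

## 2. Long-range phasing and haplotype libraries

HD animals are phased within cores of `core_length` SNP (default 100), over
`n_rounds` (4) tilings whose boundaries shift by
$\lfloor r \cdot \text{core\_length} / \text{n\_rounds} \rfloor$. A
surrogate parent of $i$ on the paternal side is an HD animal $j$ with no
opposing homozygotes against $i$ in the region (up to `max_mismatch`,
default 0) whose pedigree connection to $i$ runs exclusively through $i$'s
sire. Side assignment is decided by an ancestor walk: $j$ is
paternal-side when $\{j\} \cup \text{anc}(j)$ intersects
$\{s\} \cup \text{anc}(s)$ but not the dam's counterpart, and $j$ does not
descend from $i$ (descendants carry $i$'s own recombined gametes and cannot
be assigned to one parental side). At a heterozygous locus the paternal
allele is called when every informative paternal surrogate — one that is
homozygous there — agrees and at least `min_agree` (1) are informative;
the maternal allele is the complement; any conflict, within a side or
between sides, leaves the locus unphased.

**Why surrogacy is declared beyond the core.** With ~100-SNP cores and
realistically blocky LD, two unrelated haplotypes are compatible by chance
often enough that one coincidental "surrogate" poisons the unanimity vote
(~0.7% wrong alleles in our simulations — an order of magnitude above the
package's own accuracy bar). True identity-by-descent segments in a
pedigree span tens of centimorgans, so the opposing-homozygote screen is
run over the core plus a flank of one core length on each side
(`surrogate_flank`). This restores the *long-range* character of the
original idea while phasing still happens per core; with the flank the
simulated phase error drops below 0.2%.

**Library construction and completion.** The distinct fully resolved
gamete-haplotypes per core form the library, with counts. Partial gametes
are completed jointly as pairs: a candidate pair $(h_1, h_2)$ from the
library must match both gametes' resolved alleles and satisfy
$h_1 + h_2 = $ genotype at every observed locus; loci where all surviving
pairs agree are filled. When no library pair fits but exactly one library
haplotype fits one gamete, the partner is taken as the genotype complement
— this is how novel haplotypes (present in only one founder) enter the
library. Per-gamete unique-match completion (`build_library(complete =
TRUE)`) is also available but is weaker, because it ignores the genotype
constraint that ties the two gametes together; `min_complete` (20 resolved
alleles) guards it against spurious matches on short edge cores.

**Base animals.** Founders have no parental side to orient against; they
are resolved into *unordered* per-core haplotype pairs: all
genotype-consistent library pairs are enumerated (anchored so the
haplotype carrying allele 0 at the first heterozygous locus is slot A) and
loci with unanimous agreement are filled. In simulation this fills ~87% of
founder alleles per core at ~99.99% accuracy; demanding a single unique
pair instead resolves only ~6% of founders, which is why the unanimity
vote is used. Chromosome-wide strands are assembled later
(`fill_base_animals()`): the central core of round 0 receives an arbitrary
paternal/maternal labelling and the labelling is extended junction by
junction using the overlapping cores of other rounds as bridges; a bridge
joins a strand only when it matches its resolved overlap with zero
mismatches and at least one distinguishing locus while the alternative
does not, and an ambiguous junction stops the extension (leaving alleles
unresolved rather than risking a strand swap).

Phase calls that disagree between rounds are treated as phasing errors and
removed (cross-round unanimity), which is the error-detection purpose of
running several offset rounds.

## 3. The imputation hierarchy

The working state holds phase, genotypes and a conflict ledger. All fills
are **monotone**: a resolved allele or genotype is never rewritten; later
contradictory evidence increments the conflict count and is dropped
(first-writer wins). Four *minor* rules run to a fixed point after every
major step: (1) a homozygous parent fills the corresponding offspring
gamete; (2) genotype plus one allele gives the other by complement; (3) a
parent with exactly one resolved allele receives the other from any
offspring whose transmitted allele does not match it; (4) two resolved
alleles make the genotype. The *major* steps per outer iteration:
probability calls (step 1 output); base-animal assembly; candidate-library
votes; parental-phase votes (HD parents' round haplotypes as the only
candidates); own-phase votes (assigning an HD animal's own two haplotypes
to gametes); the same two vote machines against libraries rebuilt
internally from the current state at several core lengths (50/100/200);
and the recombination scan.

**Votes.** For each gamete, core and round, candidate haplotypes with more
than `library_mismatch_threshold` (0) disagreements against the gamete's
resolved alleles are rejected; unresolved loci where all survivors agree
gain a vote, accumulated per chromosome locus across all cores, rounds and
core lengths. An allele is imputed when its votes reach `vote_accept`
while the opposite allele has at most `vote_reject` (0). The accept
threshold is 1 on the first outer iteration and 2 afterwards: the first
pass harvests the easy unanimous evidence, later passes demand
corroboration across independent tilings, which suppresses phasing-error
propagation.

**Recombination scan.** For each gamete, at loci where both the individual
and its parent are heterozygous and phased, the transmitted parental
gamete is identified. The origin is propagated forward and backward along
the chromosome; between two determinations of the same origin no double
crossover is assumed, and chromosome ends take the origin of the nearest
determination in the direction that reaches them. An allele is imputed
where the directions agree (or only one reaches) and the parent is phased,
unless the gamete's implied crossover count exceeds
`max_recombinations[k]` or any double-crossover interval is shorter than
`min_double_crossover_gap[k]` SNP; the schedule (10/20/40 crossovers,
100/50/25 SNP over three passes) relaxes the restriction as the phase
becomes more trustworthy.

Finally, allele probabilities are recalculated by peeling on the updated
genotypes; resolved alleles keep probability 0/1, unresolved alleles take
the recalculated probability, and the dosage matrix is their per-individual
sum. An ungenotyped animal unrelated to any genotyped one ends at dosage
$2p$ exactly.

**Unmapped SNP** (no map position) skip everything haplotypic: peeling,
probability calls and the minor rules only. This path is also exposed as a
whole-run mode (`unmapped_only = TRUE`).

## 4. The synthetic-data generator

The generator is the package's test bed and defines its study conditions.
The standard fixture is a 1000-SNP, 1-Morgan chromosome in a six-generation
pedigree of ~1500 animals (200 founders, then five generations of 260
offspring bred from 25 sires and 100 dams each, full-sib matings avoided);
every parent is HD-genotyped and the 500 youngest non-parents form the
test set, masked to a low-density panel — mirroring a breeding program
that genotypes ancestors at high density and selection candidates cheaply.
Panels retain 1/5/10/15% of SNP, chosen per the evenly spaced 5-SNP-window,
max-MAF rule of the panel-design module.

Founder haplotypes: per-SNP allele frequencies are drawn uniformly from
[0.1, 0.5]; each haplotype thresholds a latent AR(1) Gaussian chain
(parameter `ld_decay`, default 0.95) at the per-SNP frequency. This
Gaussian-copula construction was chosen over a literal copy-previous
Markov chain because it preserves the drawn allele frequencies *exactly*
while producing the blocky LD the haplotype library exploits; a coalescent
simulator would add realism (allele-frequency/LD coupling, rare variants)
but none of the structure the algorithm depends on. Gene dropping
transmits parental haplotypes with Poisson(`morgans`) crossovers at
uniform genetic positions, recording the true phase and crossover
positions.

What the simulation does *not* emulate: genotyping error (the pipeline
sees error only via Mendelian cleaning and vote thresholds), mutation,
selection, assortative mating, multi-breed structure, and real
marker-density/LD heterogeneity. Passing the simulation bars therefore
shows the algorithm's logic is sound under idealised inheritance, not that
the specific accuracy figures transfer to any real population.

## 5. Design choices in the open

- *Category precedence.* Test animals are categorised by their nearest HD
  ancestors with precedence BothParents > SireMGS > DamPGS > Sire > Dam >
  Other; an animal whose only HD ancestor is a grandsire without the
  corresponding parent falls to Other.
- *Vote accumulation* is per chromosome locus across cores and rounds (not
  per core), so independent tilings corroborate each other.
- *Conflict policy* is first-writer-wins with a logged ledger; arbitration
  by evidence weighting was rejected to keep runs deterministic and
  auditable.
- *Determinism.* Traversals follow pedigree topological order and SNP index
  order; the only arbitrary choice (a base animal's paternal label) is
  fixed by convention. Two runs with the same inputs, configuration and
  seed are byte-identical.
- *Problem sizes.* The shipped tests run the standard fixture (1000 SNP,
  ~1500 animals) across 20 seed-density combinations and complete in a few
  minutes; the C++ kernels scale linearly in individuals x SNP, and the
  surrogate search quadratically in HD animals within a region.

## 6. Known limitations

- Peeling is single-locus; linkage information enters only through the
  haplotype machinery, so unmapped-SNP accuracy is bounded by what
  parent-offspring genotype constraints can deliver.
- Looped pedigrees make peeling approximate; heavily inbred pedigrees may
  need more iterations or damping.
- The surrogate side assignment is pedigree-based; animals whose paternal
  and maternal families are genetically entangled (repeated ancestors on
  both sides) yield no usable surrogates and rely on the library instead.
- Library-based steps assume the population's haplotype diversity is
  bounded; in very diverse populations (large effective size, weak LD)
  libraries grow and the unanimity votes abstain more often.
- Genotyping error is only handled destructively (conflicting homozygote
  pairs are blanked); a probabilistic error model is out of scope.
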