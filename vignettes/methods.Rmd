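---
title: "Methods: diversity, differentiation, demography and prioritisation from SNP genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, differentiation, demography and prioritisation from SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelic)
```

`allelic` implements the analysis chain used in range-wide conservation
genomic studies of structured vertebrate populations: post-genotyping
quality control, per-population diversity, genetic distance and
differentiation, linkage-disequilibrium-based effective population size
(Ne) trajectories, and allele-based prioritisation of populations. This
vignette records the statistical models, the parameter choices and their
rationale, the numerical conventions, and the limits of what the test
suite can demonstrate.

## Data model

The central container is a biallelic locus × sample matrix of
alternate-allele dosages (0/1/2, `NA` missing), with locus records
(scaffold, 1-based position, ref/alt) and sample records (id, locality,
coordinates, optional `replicate_of`). Every downstream statistic is
symmetric in the allele labels, so which allele is counted is arbitrary
but fixed. All pairwise statistics use pairwise-complete observations;
nothing is imputed.

## Quality control

The cascade applies, in order: locus call rate (< 0.90 removed), minor
allele count (< 3 removed), observed heterozygosity (> 0.6 removed, a
guard against erroneously merged paralogues), kinship-based removal of
close relatives (> 0.25), LD pruning (|r| > 0.5 within 100-kb windows),
and sample missingness (> 25% removed). All boundaries are strict
removal conditions, so values sitting exactly on a threshold are kept.

Three conventions deserve justification:

* **Kinship** uses the allele-matching (Weir–Goudet) method-of-moments
  estimator: the pairwise matching proportion
  $M_{ij} = \overline{(x_i x_j + (2-x_i)(2-x_j))/4}$ over co-called loci,
  rescaled as $\hat\beta_{ij} = (M_{ij} - M_B)/(1 - M_B)$ with $M_B$ the
  mean matching over all distinct pairs. $\hat\beta$ is *relative to the
  average pair in the comparison set*, so the estimator is computed
  within each locality: with a range-wide reference set, shared local
  drift masquerades as relatedness and whole localities would flag each
  other. Expected values are ~0.25 for parent–offspring and ~0.5 for
  duplicates; of a flagged pair the member with more missing data is
  dropped (ties go to the later sample), maximising retained information.
  Technical replicates are exempt — they are handled by the concordance
  check instead.
* **LD pruning** sweeps loci in genomic order per scaffold and removes the
  *later* locus of any violating pair; removed loci take no further part.
  The threshold applies to |Pearson r| of dosages. Thresholding r² is
  available by passing `max_corr = sqrt(r2)`, since the sweep only
  compares |r| against a constant.
* **Fixpoint refinement.** Removing samples changes per-locus call rates
  and allele counts, so a single pass is not self-consistent. The cascade
  repeats the six-stage pass until nothing changes (all stages only ever
  remove, so this converges, nearly always in two passes), and again after
  replicate columns are dropped. The returned dataset therefore passes
  every filter: re-running the cascade is a no-op, and the filter report
  records each pass with monotonically non-increasing counts.

Replicate concordance is the fraction of co-called loci with equal dosage,
plus a dendrogram-style criterion: each replicate's nearest neighbour
under Prevosti distance must be its partner.

## Diversity

Per locus and population with alternate-allele frequency $\hat p$ over
$2n_c$ called copies: observed allele count $A$, effective alleles
$A_E = 1/(\hat p^2 + (1-\hat p)^2)$, observed heterozygosity $H_O$, and
unbiased expected heterozygosity
$H_E = \frac{2n_c}{2n_c-1}\,2\hat p(1-\hat p)$. The correction is Nei's
unbiased factor; other implementations' small-sample corrections are
undocumented, so the factor is isolated behind `correct = TRUE` and
table-level comparisons with published values are tolerance-based, not
bit-exact. $F_{IS} = 1 - H_O/H_E$ is averaged per-locus over polymorphic
loci (the ratio-of-means alternative is a one-line change via
`per_locus_diversity()` output). Table-level standard errors are standard
errors of the mean over loci.

SNP-panel heterozygosities are ascertainment-inflated, so
`autosomal_heterozygosity()` rescales to all callable sites: $H_O$ as het
calls over all called genotype-site observations, $H_E$ as the mean
unbiased $2\hat p(1-\hat p)$ with invariant sites contributing zero,
both reported ×1000. The callable-site total is an explicit input
(deriving it from raw reads is upstream of this package); the per-population
versus global denominator convention is the caller's choice via a named
vector.

## Structure

Prevosti distance between individuals is the mean over co-called loci of
$|x_i - x_j|/2$ — half the absolute difference of within-individual allele
frequencies — a [0, 1] dissimilarity requiring no allele-frequency model.
It feeds classical PCoA (double-centred $-D^2/2$, eigendecomposition,
coordinates scaled by $\sqrt\lambda$; percent variance is each positive
eigenvalue over the positive sum) and UPGMA dendrograms.

Pairwise differentiation is Weir–Cockerham $\theta$ computed from genotype
counts (including observed heterozygosity, so no Hardy–Weinberg assumption
enters the variance components), aggregated across loci as ratio of sums
— the standard multi-locus estimator, not a mean of per-locus ratios.
Negative estimates are reported as computed. Significance of
$\theta > 0$ uses a locus bootstrap (resample loci with replacement,
default 1000 replicates); the p-value is the fraction of replicates ≤ 0,
a one-sided convention chosen because the scientific question is whether
differentiation exceeds zero; a percentile-CI check is a one-liner on the
same replicates.

## Ne trajectories from LD

Under drift–recombination equilibrium, the expected squared correlation of
dosages at recombination fraction $c$ is approximately
$E[r^2] = 1/(\alpha + 4N_e c)$, and pairs at distance $c$ reflect an
effective size roughly $1/(2c)$ generations in the past. The module:

1. filters one population's loci to MAF ≥ 0.05 and call rate ≥ 0.5;
2. computes $r^2$ for every same-scaffold pair with
   $c = \mathrm{bp} \times$ `recomb_rate_per_bp` ≤ 0.25, applying the
   unphased sample-size correction $r^2_{adj} = r^2 - 1/n$;
3. bins pairs into 8 logarithmic bins over $c \in [5\times10^{-4}, 0.25]$
   (bins under 50 pairs merge leftwards) and inverts
   $N_e = (1/\bar r^2_{adj} - \alpha)/(4\bar c)$ per bin, with
   $t = 1/(2\bar c)$ generations, scaled to years by the generation
   interval (default 1.95 years, a typical large-rodent value).

Defaults: $\alpha = 2.2$ (the usual constant absorbing mutation and
sampling for unphased data), a uniform 1 cM/Mb map (no species map
exists; configurable), and a dropout bootstrap that removes 10% of
individuals (at least one) per replicate, 10 replicates, reporting the
min–median–max envelope per bin. Bins whose mean $r^2_{adj} \le 1/\alpha$
invert to non-positive Ne and are dropped with a warning. These are the
published relationships the common LD-Ne tools implement; each constant is
an isolated argument, and no byte-level agreement with any particular tool
is claimed. Loci are *not* LD-pruned for this module — pruning would
destroy the very signal being measured.

The estimator is accepted on two properties: feeding $r^2$ values lying
exactly on the drift expectation recovers $N_e$ to machine precision for
any $(\alpha, N, c)$; and on forward Wright–Fisher simulations at constant
$N_e = 100$ the median mid-range-bin estimate lands within a factor of two
of truth. The very shortest-distance bins look further back than the
simulated history and are biased, which is why recovery is judged on
mid-range bins.

## Prioritisation

Allelic richness is rarefied by hypergeometric expectation: with $N_a$
copies of allele $a$ among $N$ called copies,
$AR_g = \sum_a \left[1 - \binom{N-N_a}{g}\big/\binom{N}{g}\right]$, the
expected allele count in $g$ copies. "10 alleles" is interpreted as
$g = 10$ gene copies (5 diploids), the standard rarefaction unit. Loci
with fewer than $g$ copies in a population are excluded and counted.

The leave-one-out contribution pools all samples as one collection:
$AR(t)$ is the pooled rarefied richness, $AR(-i)$ the same without
population $i$, and the contribution is $(AR(t) - AR(-i))/(AR(t) - 1)$ —
the denominator subtracts the monomorphic floor of 1 allele per locus.
The classical Petit normalisation (divide by $AR(t)$) is available via
`normalisation = "petit"`. Contributions can be negative (removing a
population can raise pooled rarefied richness).

The reserve-selection analysis treats each allele as a feature and each
population as a unit of cost 1. Per iteration (default 100), four
individuals are drawn per population without replacement; an allele is
"in" a population iff observed among its drawn copies; the maximum-coverage
problem is solved *exactly* by enumerating all $\binom{k}{b}$ subsets per
budget $b$ (a greedy fallback with a logged notice covers $k > 20$; the
exhaustive optimum is provably ≥ greedy, which the tests assert). Tied
optima each add $1/\text{ties}$ to their subset's tally, so per-budget
tallies sum to the iteration count. The rarefied richness of the chosen
union is computed at $g_{\cup} = \min(g,\ 2 \cdot n_{draw} \cdot b)$,
because a one-population union of four diploids cannot supply ten copies —
this resolves the open choice of rarefaction size for solution unions in
favour of "as close to $g$ as the union can support".

## The synthetic generator

`sim_config()` describes a two-level hierarchy: per locus an ancestral
frequency $p$, per lineage a Balding–Nichols draw
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, per
locality another Balding–Nichols draw around its lineage, then
Hardy–Weinberg binomial genotypes. $F < 10^{-9}$ short-circuits to an
identity draw (the Beta becomes degenerate). Balding–Nichols was chosen
because it gives a closed-form acceptance test: pairwise $\theta$ between
two localities at drift $F$ concentrates near $F$, which the suite checks
at $F = 0.2$ over 20 seeds (5000 loci, 2 × 30 samples). Loci sit on
synthetic scaffolds at uniform 20-kb spacing (100 loci per scaffold) so
window-based operations and LD distance bins are exercised; monomorphic
realised loci are retained, and the diversity code must handle them.

The default topology mirrors a range-wide rodent design: an isolated
island lineage (melville, F ≈ 0.30) that split first, and a continental
lineage (shared F = 0.12) holding a strongly drifted peripheral locality
(weipa, local F = 0.46), and two weakly differentiated central localities
(cobourg 0.13, darwin 0.10), n = 5/14/8/14, 2.5% missingness, one
relative pair and two technical-replicate pairs. The branch F values were
calibrated once, before any testing, from the target pairwise-θ range
(≈ 0.11–0.40 with the island–peripheral pair highest and the central pair
lowest) by the approximation θ ≈ mean of the two branches' divergence
below the common ancestor.

`study_config()` additionally replaces the uniform ancestral frequency
draw with a rare-skewed spectrum (minor allele frequency log-uniform from
0.005 to 0.5, density ∝ 1/x, randomly folded), emulating the
rare-allele-heavy ascertainment of reduced-representation panels. This
matters scientifically: private alleles arise when rare variants are lost
along the shared continental branch while drifting upward on the island
branch, and only with a realistic rare-skewed spectrum does the fixture
reproduce the pattern these analyses exist to detect — the island
population contributing most to pooled richness despite a central
population being the best single reserve. With a uniform spectrum almost
no allele is rare enough to be lost anywhere, and leave-one-out
contributions degenerate toward a pure diversity ranking.

What the generator does *not* emulate: post-isolation mutation (drift only
redistributes ancestral variation), linked selection, isolation by
distance within localities, batch effects on missingness (missingness is
independent per genotype), and genotyping error outside replicate columns.
Passing tests therefore demonstrate estimator correctness under the stated
models, not robustness to artefacts the models exclude.

The Wright–Fisher simulator is the oracle for the Ne module:
non-overlapping generations, $2N_e$ haplotypes per chromosome, each gamete
from a random parent with a Poisson number of crossovers placed uniformly,
loci initialised i.i.d. at frequency 0.5, and a without-replacement
diploid sample at the end, returned unphased.

## Numerical conventions and degenerate inputs

* Rarefaction uses `lchoose` differences, so $\binom{n}{k} = 0$ for
  $k > n$ comes out as $e^{-\infty} = 0$ without overflow.
* Pairs or loci with no co-called observations yield `NA` plus a warning
  where a statistic is undefined (kinship, distances), or are excluded
  where a sum is taken (θ components, LD pairs).
* Monomorphic loci: $A = 1$, $A_E = 1$, $H = 0$, excluded from the
  $F_{IS}$ mean; rarefied $AR = 1$.
* Seeds: every stochastic function takes a seed; the pipeline derives
  per-stage seeds from one master seed (`seed * 131 + stage`, reduced
  mod $2^{31}-1$) so stages are independently reproducible; identical
  configuration and seed give byte-identical report files.
* Ties: relative removal prefers dropping the later sample; coverage ties
  are enumerated, all returned, and tallied fractionally.

## Problem sizes

The test-suite simulations are sized to be decisive yet quick: 5000-locus
fixtures for differentiation recovery (20 seeds), 2000-locus fixtures for
kinship and Hardy–Weinberg nulls (20 seeds each), Wright–Fisher runs of
100–500 diploids for 200–300 generations over 4–8 chromosomes, and
10-seed fixture replications for the end-to-end conservation pattern.
These sizes were chosen so that each band being asserted is several
standard errors wide at the simulated scale.

## Known limitations

* Heterozygosity corrections and $F_{IS}$ aggregation vary across
  published toolchains; comparisons with externally published tables
  should use tolerances, not exact equality.
* The LD-Ne inversion assumes drift–recombination equilibrium, a uniform
  recombination map, and unlinked sampling noise absorbed by $\alpha$ and
  the $1/n$ correction; trajectory *shapes* at the shortest distances are
  biased when history is shorter than $1/(2c)$ generations.
* The bootstrap p-values for θ are resampling-based and cannot go below
  $1/\text{reps}$.
* Exhaustive coverage enumeration is exact only up to 20 planning units;
  beyond that the greedy bound is reported as such.
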