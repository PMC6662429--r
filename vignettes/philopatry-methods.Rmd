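---
title: "Testing natal philopatry at three spatial scales: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing natal philopatry at three spatial scales: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestgen)
```

`nestgen` asks one biological question three ways: does natal philopatry —
females returning to nest where they hatched — shape where communally
nesting reptiles put their nests? The three ways are spatial (are nests
aggregated at all?), hierarchical-genetic (are nests in the same
aggregation more related than nests in different aggregations?), and
continuous (does genetic distance increase with geographic distance?).
This vignette explains the models behind each stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## Spatial stage: Ripley's K and CSR envelopes

For `n` nests in a rectangular window of area `A`, the package estimates

$$\hat K(r) = \frac{A}{n(n-1)} \sum_{i \ne j} w_{ij}\, 1[d_{ij} \le r],$$

where `w_ij` is an edge-correction weight, together with the
variance-stabilised `L(r) − r = sqrt(K̂/π) − r`. Under complete spatial
randomness (CSR, a homogeneous Poisson process) `K(r) = πr²` and
`L(r) − r = 0`; positive excursions indicate clustering, negative ones
overdispersion.

Choices:

* **Edge correction** (`correction`, default `"isotropic"`). Ripley's
  isotropic weight — the inverse of the fraction of the circle of radius
  `d_ij` centred on the focal point that lies inside the window — is the
  standard default for rectangular windows at these scales; `"translate"`
  and `"none"` are selectable. The uncorrected estimator is kept exactly
  equal to the brute-force double loop (the test suite asserts this), so
  it doubles as an oracle.
* **Distance grid** (`r`). 512 equal steps from 0 to a quarter of the
  shorter window side by default; the isotropic weight is valid to half
  the shorter side and larger `r` is refused with the bound named.
  Site-scale analyses conventionally cap at 250 m (two sites pooled),
  100 m and 40 m (single sites); `r_max` expresses these.
* **Envelope** (`csr_envelope()`). `nsim` patterns of the *observed* point
  count are placed uniformly in the same window (a binomial process — the
  count is conditioned on, which makes the test exact), K is computed for
  each, and the pointwise minimum and maximum form the rank-1 envelope.
  By exchangeability the attained two-sided significance at any fixed `r`
  is exactly `2/(nsim+1)` — 0.0208 at the conventional `nsim = 95`. The
  acceptance suite measures the exceedance rate over 2,000 CSR replicates
  and requires it within ±0.01 of 2/96. Global (simultaneous) envelopes
  are deliberately out of scope; the per-distance classification in
  `classify_dispersion()` is pointwise and should be read as descriptive
  of scale, not as a family-wise test.

## Cluster delimitation: edge thinning

`edge_thinning()` links nests at distance ≤ r and counts connected
components as r grows in steps (default 5 m, the conventional increment).
Because connectivity is single-linkage and transitive, the whole profile
is the single-linkage dendrogram read at the grid heights, which is how it
is computed (`stats::hclust`); a breadth-first-search oracle in the tests
confirms the equivalence. Ties at exactly `d = r` are linked (≤, not <).

Plateaus — maximal runs of constant component count — mark distances at
which the spatial structure is stable; the onset radius of a plateau is a
*threshold distance* (TD). A plateau must span at least `min_run = 2`
steps (10 m at the default step) to be reported: the notion of "little or
no change" is not otherwise quantified, 1-step runs are indistinguishable
from grid noise, and the all-singleton state at r = 0 is never a plateau.
`assign_clusters()` labels components at a chosen radius; the mean
nests-per-cluster reported alongside includes singleton nests.

## Hierarchical AMOVA

`hierarchical_amova()` partitions allele-identity variance over four
nested levels — clusters, nests within clusters, individuals within
nests, copies within individuals — using the classical nested
sums-of-squares decomposition on allele copies. For a set of copies with
allele counts `c_k` and total `m`, the within-set sum of squares under the
identity distance is `(m − Σc_k²/m)/2`; unequal-size coefficients are the
standard nested-ANOVA ones, computed per locus so that missing genotypes
are excluded pairwise. Components are summed over loci (ratio of sums,
never mean of ratios) and

$$F_{CT} = \frac{\sigma_1^2}{\sigma_T^2},\quad
  F_{SC} = \frac{\sigma_2^2}{\sigma_2^2+\sigma_3^2+\sigma_4^2},\quad
  F_{IS} = \frac{\sigma_3^2}{\sigma_3^2+\sigma_4^2},\quad
  F_{IT} = \frac{\sigma_1^2+\sigma_2^2+\sigma_3^2}{\sigma_T^2},$$

which satisfy `(1−F_IT) = (1−F_IS)(1−F_SC)(1−F_CT)` identically (asserted
to 1e−10). Negative components are retained — slightly negative `F_CT` is
a legitimate and common outcome — and a fully invariant panel is reported
as all-zero with a degenerate flag rather than NaN. A level with a single
unit leaves its statistic `NA` while the others are still computed.

Each statistic has its own permutation null, following the conventions of
hierarchical AMOVA software: whole nests permuted among clusters for
`F_CT`; individuals among nests within clusters for `F_SC`; allele copies
re-paired among individuals within nests for `F_IS`; and across the whole
sample for `F_IT`. One-sided p-values use `(exceedances+1)/(perms+1)`
everywhere in the package, so no p is ever exactly zero. Two-level
comparisons (`pairwise_fst()`) use the Weir–Cockerham theta estimator with
individuals permuted between the two groups.

One estimator property worth knowing: duplicating every individual leaves
`F_CT`, `F_IT` and theta essentially unchanged (< 0.005), but the
within-nest statistics shift by an `O(P/N)` amount (≈ 0.02 with a dozen
sibs per nest) because the unbiased degrees-of-freedom corrections change.
This is the mean-square algebra, not an implementation artefact — the
brute-force pairwise-distance oracle agrees to 1e−10 on both the original
and the doubled data.

## Isolation by distance

`nei_distance()` computes Nei's standard distance `D = −ln I` with the
identity aggregated over loci before normalising,
`I = Σ_l Σ_k x_k y_k / sqrt(Σ_l Σ_k x_k² · Σ_l Σ_k y_k²)`; pairs sharing no
alleles get `D = ∞` with a logged count, and such entries are excluded
pairwise from the Mantel correlation by default. The frequency unit is
open to debate when hatchlings are the sample: the package defaults to
**nests** (each nest's hatchlings pooled into a frequency vector, paired
with nest-coordinate distances) and offers an **individual** mode (each
individual a 2-copy frequency vector located at its natal nest) behind
`ibd_test(mode = )`. Neither mode is privileged; both are reported by the
pipeline and neither is claimed to reproduce any particular published
matrix, since the alignment of a population-level genetic distance with an
individual-level geographic matrix is ambiguous in the field literature.

`mantel_test()` correlates upper triangles, permutes rows and columns of
the second matrix simultaneously (so the null preserves the distance
structure), and is one-sided for positive association. Type-I error is
calibrated in the acceptance suite (0.05 ± 0.015 over 1,000 null
replicates) and the null p distribution is checked for uniformity.

## Marker QC and the classical estimators

* **Heterozygosity**: `H_E` uses Nei's unbiased factor `2n/(2n−1)`.
* **Exact HWE** (`hwe_exact()`): direct Monte Carlo sampling of genotype
  tables with the observed allele counts (random re-pairings of the
  copies), comparing conditional probabilities; the Monte Carlo standard
  error of the p-value is reported. Default 2,000 tables; a complete
  enumeration oracle pins the biallelic cases in the tests. Monomorphic
  loci have p = 1 by convention.
* **Null alleles** (`null_allele_estimate()`): Dempster EM for a single
  non-amplifying allele. Apparent homozygotes are a mixture of true
  homozygotes and visible/null heterozygotes; blank genotypes are treated
  as null homozygotes, which means unrelated amplification failures
  inflate the estimate slightly — acceptable at the few-percent
  missingness typical of microsatellite panels. Stopping rule: change
  < 1e−9 or 10,000 iterations (flagged if hit). Loci with estimates
  strictly above 0.20 are removed by `filter_loci()` (a locus at exactly
  the threshold is kept — the rule is a strict inequality).
* **Private-allele Nm** (`private_allele_nm()`): mean frequency of alleles
  seen in exactly one group, inverted through the published log–log
  regressions tabulated at per-deme sample sizes 10, 25 and 50, with
  linear interpolation at the harmonic-mean sample size. No private
  alleles means the regression is unbounded; `NA` with a message, read as
  gene flow too high to measure this way.
* **LD Ne** (`ne_ld()`): Burrows' composite Δ per allele pair (with the
  `S/(S−1)` factor), `r² = Δ²/(p(1−p)q(1−q))`, alleles below
  `pcrit = 0.05` dropped (one allele of a biallelic locus is dropped as
  perfectly redundant), the expected pure-sampling `r²` subtracted
  (`1/S + 3.19/S²` for `S ≥ 30`, the small-S variant otherwise), and the
  random-mating quadratic inversion. Mean `r²` at or below its sampling
  expectation gives `Ne = ∞`, the honest answer for uninformative data.
  The 95% CI uses a **leave-one-locus-out** jackknife rather than a
  locus-pair jackknife: locus pairs share loci, and in calibration runs
  the pairwise jackknife covered a known Ne = 50 only about half the
  time, while the locus jackknife achieves the intended coverage. The
  calibration itself defines "ideal population" as monoecious random
  mating with selfing at drift equilibrium (10 burn-in generations);
  without selfing the equilibrium composite `r²` for unlinked loci falls
  about 20% below `1/(3Ne)` and the published constants no longer apply.
* **Heterozygote-excess Nb** (`ne_het_excess()`): per-allele relative
  excess `D = (H_O − H_E)/H_E` averaged over alleles and loci, inverted
  as `Nb = 1/(2D̄) + 1/(2(D̄+1))`; non-positive excess gives `∞`, the
  expected outcome at realistic sample sizes unless the breeder pool is
  tiny.
* **Coancestry Nb** (`ne_coancestry()`): pairwise allele-sharing
  similarity corrected by the background match probability `Σp_k²` and
  inverted through `f̄ = 1/(2Nb)`. The reference frequencies are the
  crux: estimated from the sample itself they absorb the mean kinship,
  making the all-pairs mean ≈ 0 by construction, so the sample-referenced
  estimator averages the *positive* pairwise values — a convention that
  detects small breeder pools well (within a factor of 2 at four
  parents in the tests) but saturates, and can even invert, as the true
  breeder count grows. When the breeding pool's frequencies are known
  independently (`ref_freqs`; synthetic studies know their generating
  frequencies), the plain all-pairs mean is used and the breeder count is
  recovered monotonically. Field analyses should read the
  sample-referenced value as "small Nb detector", not a point estimate.

## The synthetic-data generator

`simulate_study()` builds the study the analyses expect, under conditions
chosen to emulate the target field system: two nesting sites with windows
of 454 × 695 m and 170 × 476 m about 1.5 km apart; a Thomas cluster
process per site (about 6 parent centres, mean 4 nests each, 15 m
Gaussian spread — roughly two dozen genotyped nests per site, aggregated
at the 30–60 m scale where threshold distances are conventionally found);
13 microsatellite loci with 8 alleles each (the observed panels run 4–16
alleles per locus); Balding–Nichols divergence `F = 0.02` between sites
(the magnitude of published between-site `F_ST` at this spatial scale);
clutches of full siblings with size Poisson(12.5) clipped to [2, 23] (the
field clutch law gives only the mean and range, and clipping honours the
range exactly); and 2% genotypes missing uniformly at random (the
missingness mechanism is never described in field panels; uniform is the
neutral choice).

Philopatry is modelled at the **matriline** level: each site has
`n_matrilines = 20` founder pairs whose daughters form the pool of
nesting females, and each nest's mother is drawn from the matriline
mapped to the nest's latent spatial cluster with probability φ, otherwise
from the site-wide pool. φ = 0 is the no-philopatry null; φ = 1 makes
cluster-mates full or half aunts/nieces and drives `F_CT` positive. A
single-generation pedigree is enough to create the testable signal;
multi-generation natal return, mutation, male territoriality, and
non-uniform missingness are intentionally not simulated. Consequently a
passing suite shows the *estimators* behave correctly under the stated
family and spatial structure — it cannot certify behaviour under real
complications such as genotyping error, linked loci, or nest failure
biased by location.

Determinism: every generator call is reproducible from one integer seed;
stage seeds are derived from the master seed via a stable tag hash, so
adding stages never shifts existing streams, and equal seeds give
byte-identical studies.

## Pipeline defaults and problem sizes

`pipeline_config()` defaults to the analysis settings conventional for
this design: 5 m thinning step, 95 envelope simulations, 16,000
permutations for `F_IS`/`F_ST`, 10,000 for the hierarchical AMOVA and
Mantel tests, null-allele threshold 0.20, `pcrit = 0.05`. All are
overridable, and the test and acceptance runs use smaller permutation
counts (49–999) and single-site configurations: the quantities being
checked there are estimates and calibration rates whose Monte Carlo error
at those sizes is already far below the tolerances asserted, and the
suite is meant to run comfortably on a laptop. The acceptance script uses
2,000 CSR replicates for envelope calibration, 1,000 null Mantel
replicates, 50 replicates each for divergence and Ne recovery, and 100
end-to-end studies per φ regime.

The repeated "one hatchling per nest" subsample is deterministic (first
id in sort order) or seeded (`one_per_nest(seed = )`), because published
analyses rarely state how theirs was drawn and reproducibility matters
more than matching an unknowable choice.

## Known limitations

* Windows are axis-aligned rectangles; irregular nesting grounds need
  pre-clipping. No inhomogeneous-K, pair correlation, or marked patterns.
* AMOVA distances are allele identity only (F-statistics); allele-size
  (stepwise-mutation) analogues are out of scope.
* The coancestry Nb saturation discussed above.
* Nm interpolation is clamped to the tabulated 10–50 sample-size range.
* The Mantel frequency-unit ambiguity is exposed, not resolved.
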