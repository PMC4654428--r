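---
title: "Statistical methods for replant-disease soil biotests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for replant-disease soil biotests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdsoil)
```

## The problem

Replant disease (RD) is a persistent growth depression of crops replanted on
soil previously used for the same or related species, attributed to biotic
soil factors. The standard way to quantify it is a greenhouse *biotest*: a
susceptible rootstock is grown in the suspect soil untreated (`Con`) and
after disinfection treatments — moderate heat (`H50`, 50 °C) and gamma
irradiation (`Gamma`) — and growth differences are read as RD severity. The
companion molecular question is how the treatments reshape the soil
bacterial community, assessed from 16S rRNA gene fragments by whole-lane
fingerprint comparison (DGGE) and by amplicon sequencing summarised into an
OTU table.

`rdsoil` implements the complete statistical path of such a study as
reusable, tested components, together with a synthetic-data generator that
stands in for the gels, sequence archives and greenhouse measurements.

## Models and procedures

### Fingerprint similarity and the permutation d-test

Each gel lane is a densitometric intensity vector. Lane similarity is the
Pearson correlation of the two raw curves (`pearson_similarity()`); UPGMA
(average linkage on `1 - S`) gives the dendrogram. Group structure is
quantified by

\[ d = 100\,(\bar S_{\text{within}} - \bar S_{\text{between}}) \]

over all unordered off-diagonal lane pairs, in percentage points
(`d_statistic()`). Significance comes from permuting group labels with
group sizes fixed (`permutation_test()`): exhaustive over all distinct
label arrangements (a multinomial coefficient) when that count is at most
20,000, otherwise Monte-Carlo with the identity arrangement added to both
numerator and denominator so that p > 0 always. The test is one-sided:
only large d indicates group structure.

Two numerical facts are worth spelling out. First, for the standard 4 vs 4
design the exhaustive scheme enumerates exactly `choose(8, 4) = 70`
arrangements, so `p >= 1/70`. Second, d is invariant to swapping the group
labels themselves, so with equally sized groups every sample *partition*
appears twice among the arrangements; the smallest p any data can realise
is therefore `2/70 ≈ 0.03` — which is why strongly separated 4 vs 4
comparisons all report the same p ≈ 0.03.

### Community matrices

From an OTU table (samples × OTUs with a six-rank lineage per OTU and
soil/treatment/replicate metadata):

* `relative_abundance()` divides counts `n` by sample totals `N`.
* `transform_abundance()` applies `log10(n/N · 100 + 1)` to the percent
  relative abundance — the variance-stabilising transform used before all
  per-taxon group testing. It maps zero counts to 0 and a pure sample to
  `log10(101) ≈ 2.004`. The base is not stated in the tradition this
  follows; base 10 is used here. The base only rescales the transformed
  values, so no rank-based or ANOVA inference changes with it.
* `aggregate_taxa()` sums counts over OTUs sharing the lineage prefix down
  to the requested rank; OTUs unclassified at that rank are pooled *per
  parent lineage*, not globally, because the grouping key is the full
  prefix.
* `dominant_taxa()` keeps taxa whose mean relative abundance is at least
  1 % (inclusive boundary; taxa below it are conventionally "rare"). The
  scope is global by default, per-soil optionally.

### Diversity

`rarefaction_curve()` computes the analytic (hypergeometric) expectation
of richness in a without-replacement subsample of size d,
\( E[S_d] = S_{obs} - \sum_i \binom{N-n_i}{d} / \binom{N}{d} \),
with log-gamma arithmetic; no resampling is involved. Whether the original
analyses rarefied analytically or by resampling is not documented; the
analytic curve is exact for the expectation and the test-suite cross-checks
it against 1,000-fold Monte-Carlo subsampling. `invsimpson()` uses the
unbiased finite-sample estimator \( D = \sum_i n_i(n_i-1) / (N(N-1)) \)
(the mothur convention, since diversity indices in this tradition come out
of that pipeline) rather than the plug-in \(1/\sum p_i^2\); the two agree
asymptotically and the suite checks that at large counts.

### Ordination and ANOSIM

`bray_curtis()` implements \( D_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k
(x_{ik} + x_{jk}) \). `pcoa()` is classical metric scaling: Gower
double-centering of `-D²/2`, symmetric eigendecomposition, coordinates
scaled by the square roots of positive eigenvalues; negative eigenvalues
(Bray–Curtis is non-Euclidean) are reported and their axes dropped, and
explained fractions are relative to the positive part.

`anosim()` uses Clarke's statistic on midranked off-diagonal distances,
\( R = (\bar r_B - \bar r_W) / (M/2) \) with `M = n(n-1)/2` pairs, i.e.
divisor `n(n-1)/4`. That divisor is what makes `R = 1` for perfect
separation, an identity the acceptance suite asserts. For the two-way
crossed design (treatment tested with soil held fixed) the package follows
Clarke's within-block scheme: R is computed within each block from the
block's own distance submatrix, the per-block values are averaged, and
permutations shuffle labels only within blocks. The literature the study
tradition cites does not pin down the two-way variant; crossed within-block
is the default and is flagged in the output.

The genus-level ordination input (`ordination_input()`) keeps only OTUs
from dominant phyla and only OTUs classified at genus level — unclassified
rows are dropped for this analysis only, matching the convention of
ordinating "identified at genus level" composition.

### The responder screen

`screen_responders()` works per soil and per taxon at a chosen rank:
transform, one-way ANOVA across treatments, Tukey HSD with the studentized
range on the pooled variance, and a compact letter display built with the
insert-and-absorb algorithm. A treatment is classified `increased` or
`decreased` versus the control only when it shares no letter with it;
otherwise `none`. No correction is applied across taxa — the familywise
control is within taxon, as in the study tradition — but a
Benjamini–Hochberg filter across taxa is available and off by default.
Taxa with all-zero counts in a soil are skipped and logged rather than
tested.

`dunnett_vs_control()` computes two-sided many-to-one comparisons. The
familywise adjustment integrates the equicoordinate multivariate-t
probability directly, factorising the statistics through the shared
control variate and the pooled scale:
\( P(\max_j |T_j| \le q) = \int_0^\infty f_S(s) \int \phi(z)\prod_j
[\Phi(\tfrac{qs + b_j z}{a_j}) - \Phi(\tfrac{-qs + b_j z}{a_j})]\,dz\,ds \).
Integration limits are finite (±12; the integrand is < 1e-30 beyond) at
tolerance 1e-10 — R's adaptive quadrature on doubly infinite ranges can
silently miss mass at looser settings. With one treatment the procedure
reduces exactly to the pooled two-sided t-test (checked to 1e-6), and a
Monte-Carlo null oracle validates the k = 2 case.

### Biotest statistics

`biotest_report()` summarises each soil × treatment group (mean, n−1 SD),
attaches Tukey letters per trait, and derives percent increase and fold
change of shoot dry mass versus the control and the root-to-shoot dry mass
ratio. Derived quantities use *group means* (matching how such tables are
printed), not per-plant ratios; report rounding is percent to integer,
fold and ratio to one decimal. Homogeneity of variance is checked with the
Brown–Forsythe (median-centred Levene) test and reported as a warning
only; the tradition does not state a remedial action, so none is gated.
`timecourse_flags()` applies the Dunnett test per week to shoot lengths on
the raw scale (weekly increments would be an alternative; raw is the
default) and reports each treatment's first significant week.

## The synthetic-data generator

The generator's defaults are the stated world of the design it emulates:
2 soils × 3 treatments × 4 replicates, per-sample depths uniform in
4,228–10,005, and (by default) 10⁴ OTUs with a geometric-series base
composition — a few dominant OTUs and a long rare tail.

* **Fingerprints** — Gaussian bands on a baseline; replicate noise scales
  band amplitudes and adds small pixel noise; group divergence deletes,
  inserts and jitters bands at a tunable rate. The per-group variance
  structure of real gels is not documented anywhere usable, so it is
  exposed as parameters rather than fixed. What the simulator reproduces
  is the Pearson-similarity structure whole-lane comparison operates on —
  not gel physics, lane warping or staining artefacts.
* **OTU tables** — per group, expected proportions are the base
  composition with multiplicative responder effects applied and
  renormalised; per sample, a Dirichlet draw at concentration
  `overdispersion` then a multinomial at the drawn depth. Overdispersion
  defaults to 200, giving replicate-level compositional noise of the
  magnitude biological replicates show; large values approach a pure
  multinomial. Taxonomy is synthetic (phyla/genera with a configurable
  unclassified fraction at genus).
* **Growth tables** — truncated-normal traits per plant around each
  group's mean ± SD (defaults: the reference biomass table's printed
  means/SDs; shoot lengths, absent from that table, were set from the
  reported relative gains: H50 ≈ +81 % and Gamma ≈ +131 % in Kle, Gamma ≈
  148 % of control in Alv, n = 10 plants).
* **qPCR tables** — lognormal copy numbers around 10⁹ copies g⁻¹ soil.

Every generator is a pure function of `(params, seed)`; each group draws
from its own substream derived from the master seed, so adding a group
does not shift other groups' draws.

What a green test on synthetic data establishes is that the statistical
machinery is correct and calibrated *for data of the assumed structure*
(independent replicates, Dirichlet-multinomial compositional noise,
truncated-normal traits). It does not establish robustness to gel
digitisation artefacts, sequencing error and chimera structure, spatial
correlation among field replicates, or compositional effects stronger than
the Dirichlet allows.

## Numerical choices and degenerate inputs

* Constant fingerprint lanes make Pearson correlation undefined: error,
  naming the lane.
* All-zero samples are rejected by the OTU container; all-zero taxa within
  a soil are skipped by the screen with a note.
* ANOVA with zero variance everywhere and equal means returns F = 0,
  p = 1, flagged `degenerate_no_variance`; zero within-variance with
  unequal means returns p = 0.
* Permutation p-values compare with a 1e-9 tie tolerance so that exact
  ties (symmetric similarity matrices) count as `>=`.
* Exhaustive enumeration caps at 20,000 arrangements; beyond that,
  Monte-Carlo with at least 100 draws and a mandatory seed.
* PCoA eigenvalues below `max(eigenvalue) * 1e-10` are treated as zero;
  asking for more axes than are positive truncates with a warning.

## Design choices that were genuinely open

* **ANOSIM divisor.** Stated divisors in secondary descriptions vary; the
  package uses Clarke's `n(n-1)/4`, the only choice for which R = 1 at
  perfect separation and R ∈ [−1, 1] hold — both asserted in tests.
* **Log base** of the abundance transform: base 10 (see above).
* **Dominance scope**: global mean by default, per-soil available.
* **Raw vs preprocessed lanes**: Pearson runs on raw supplied profiles; a
  `preprocess` hook exists for background subtraction, which is declared
  upstream and out of scope.
* **Across-taxa correction**: off by default to match the within-taxon
  testing tradition; BH option provided.

## Limitations

The package starts from processed inputs: no read trimming, alignment,
chimera removal or OTU clustering. The permutation machinery assumes
exchangeable replicates under the null; field pseudo-replication would
invalidate that silently. The Dunnett integration assumes a common
within-group variance (as the classical procedure does). Reported
real-data values from the study this design emulates (specific d-values,
ANOSIM R, diversity ranges) depend on deposited raw reads and gel images
and are treated as reference shapes, not reproduction targets; every
number asserted by the test suite is computed by the package itself.
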