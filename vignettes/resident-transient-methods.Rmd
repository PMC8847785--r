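---
title: "Classifying resident and transient microbiome members: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying resident and transient microbiome members}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restrans)
```

# The question and the design

A host reared alongside hosts from other populations in one shared
environment (a common garden) keeps only the part of its microbiome that is
genuinely attached to it.  `restrans` asks, for a set of host populations
sampled in the field and then resampled repeatedly in a common garden,
(1) whether community composition is structured by population in the field,
(2) whether that structure survives the shared environment, (3) whether
garden communities drift away from their field baseline over time, and
(4) which individual ASVs behave as population-restricted *residents*
versus environmentally exchanged *transients*.

All community-level analyses run on binary Sorensen-Dice dissimilarities:
for samples $i, j$ with $a$ ASVs present in both and $b, c$ unique to each,
$D(i,j) = 1 - 2a/(2a+b+c)$.  Presence means count $> 0$; the index
deliberately ignores abundance, so the pipeline rejects non-integer count
tables rather than silently binarising relative abundances.  A quantitative
variant is exposed (`binary = FALSE`) but is not used by the chain.

# Filtering rules

Two thresholds gate the analysis, both exposed as parameters:

* **Sample depth** (`min_reads = 1000`): samples with *fewer than* 1,000
  reads are excluded; a sample with exactly 1,000 stays.
* **Prevalence** (`min_prevalence = 0.01`): an ASV must be present in
  *strictly more than* 1% of samples.  An ASV in exactly 1% of samples is
  removed.  The word "more" is read strictly; the boundary cases are
  pinned by tests.

Prevalence is computed after depth filtering (the pipeline's fixed order).
By default the prevalence filter applies only to the flexibility-score
stage; the beta-diversity tests use every ASV that survives depth
filtering.  Nothing in the chain requires the opposite choice — the filter
is per-stage and callers can filter earlier if they prefer.

# Distance-matrix tests

**PERMANOVA.** With $N$ samples in $g$ groups,
$SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2$,
$SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$, and
pseudo-$F = \frac{SS_{among}/(g-1)}{SS_{within}/(N-g)}$.  The p-value
permutes sample labels with the add-one convention
$p = (1 + \#\{F^\pi \ge F\})/(1 + n_{perm})$, so $p$ is never 0 and has
resolution $1/(n_{perm}+1)$; 999 permutations give the conventional
$p \ge 0.001$.  An exhaustive mode enumerates all distinct label
arrangements for small designs; the suite checks the sampled p against it.
Only the one-factor design is implemented: the field and garden strata are
always tested separately, never pooled, and tank is not modelled (tank
pseudo-replication is recorded in metadata and flagged here rather than
corrected — the design question is population structure, and the tests on
synthetic data generate no tank effect by default).

**Dispersion homogeneity.** Samples are embedded by principal-coordinates
decomposition of the double-centred $-\tfrac12 d^2$ matrix.  Distances in
`[0,1]` are generally non-Euclidean, so negative eigenvalues appear; their
axes are kept separately and a sample's squared distance to its group
centroid is the real-axis part minus the imaginary-axis part, floored at
zero before the square root (the standard correction).  The statistic is
the one-way ANOVA F over these distances; the permutation p-value permutes
the computed distances' group labels without refitting centroids, matching
common practice.  Centroids (not spatial medians) are used; with
dissimilarities in a bounded range and balanced groups the two differ
little, and the choice is pinned in tests against an independent
implementation.

**Rank-sum contrast.** The within- versus between-population comparison of
garden-vs-field dissimilarities uses the Mann-Whitney U from midranks.
With no ties and $n_a n_b \le 400$ the p-value is exact, from the full
null distribution of U obtained by Gaussian-binomial partition counting
(exact in double precision up to that size); otherwise a normal
approximation with tie correction and continuity correction is used.  The
two branches agree to well under 0.01 absolute p at $n_a = n_b = 10$.

**Divergence regression.** Each garden-vs-field within-population pair is
one observation of dissimilarity against the garden member's timepoint in
days (1, 2, 7, 14, 21, 28, 35, 42 in the emulated design); ordinary least
squares gives slope, intercept, $r^2$ and a two-sided slope t-test.  Pairs
sharing a sample are not independent; the fit is reported as a descriptive
trend, deliberately uncorrected, and both pooled and per-population fits
are returned.

# The flexibility score

For one ASV, every unordered sample pair in which the ASV is present in at
least one member scores 1 (present in both) or 0 (present in exactly one);
pairs where both members lack the ASV are excluded, because a
presence-based sharing index is undefined on double absences.  With
$s_{within}$ the mean score over same-population pairs and $s_{between}$
over different-population pairs,

$$FS = \frac{s_{within} + \epsilon}{s_{between} + \epsilon},$$

with smoothing $\epsilon = 0$ by default.  $FS > 1$ means the ASV is
shared within populations more than between them — a resident;
$FS < 1$ a transient; $FS = 1$ indifference.

Two orientation details deserve emphasis:

* The score is a ratio of *sharing* (similarity), not of dissimilarity.
  A population-restricted ASV has **high** within-population sharing, so
  only the similarity ratio satisfies the stated interpretation that
  values above 1 mark population-restricted ASVs.  The literal
  dissimilarity ratio $(1-s_{within})/(1-s_{between})$ is available as
  `fs_mode = "dissimilarity"`; its values are reciprocally oriented and
  the residency call flips accordingly, so both modes classify
  identically.
* With $\epsilon = 0$, an ASV shared within but never between populations
  gets $FS = +\infty$ and still classifies as resident;
  an ASV with no eligible pair in a class, or zero sharing in both
  classes, has undefined FS and is excluded from the distribution with a
  logged count.

**Tails.** The top/bottom tail of the FS distribution holds
$\lceil f \cdot n \rceil$ ASVs per side ($f = 0.01$ default); for
$n = 1375$ scored ASVs that is 14 per tail, 28 across both.  $+\infty$
ranks above all finite values; boundary ties break by higher prevalence,
then lexicographic ASV ID (an arbitrary but fixed rule).

**Dip test.** Whether the FS distribution is unimodal is tested with
Hartigan's dip: the smallest sup-norm distance between the empirical CDF
and any unimodal CDF (convex to the mode, concave after, an atom at the
mode allowed).  The implementation derives, for every candidate mode, the
minimal feasible distance from greatest-convex-minorant /
least-concave-majorant band conditions (a C++ kernel; modes between data
points are located by monotone-crossing search).  It is validated in the
suite against a brute-force oracle — exhaustive chord-evaluated hulls with
per-gap bisection — to $10^{-9}$ on random small samples, and against the
analytic anchors $dip = 1/(2n)$ for $n$ equally spaced points and
$dip = 0.25$ for two point masses.  The dip depends on the spacing of the
values, not only their ranks (two tight, well-separated clusters have
$dip \approx 0.25$; the same ranks equally spaced give $1/(2n)$), so the
suite asserts affine rather than general monotone invariance.  The p-value
bootstraps the dip of uniform samples of the same size — the standard
least-favourable unimodal calibration — with 2,000 replicates by default
(the replicate count is a package choice) and the add-one convention, so
the smallest attainable p is $1/2001$.  Infinite FS values are excluded
from the dip by default; a cap option (`1.01 ×` the largest finite value)
supports density visualisation.

# The synthetic common-garden generator

No deposited sequencing data are required anywhere: the generator produces
an ASV table, metadata, taxonomy, and per-ASV ground truth emulating the
study design — 6 populations, 5 field samples each, and 4 garden samples
per population at each of 8 timepoints (222 samples).  Presence is
Bernoulli per sample × ASV; present ASVs draw negative-binomial counts
(size 0.5, a typically overdispersed setting) scaled so totals fluctuate
log-normally (sdlog 0.35) around 20,000 reads, with 1% of samples drawn
shallow (< 1000 reads) so the depth filter has work to do.

Three planted classes:

* **Residents** (30 per population): presence 0.9 in the home population,
  0.02 elsewhere, in field and garden alike (residents persist through
  the transplant).
* **Core** (120): presence 0.8 everywhere — population-indifferent
  filler whose FS concentrates near 1.
* **Transients** (200): exchanged with the shared water.  Each transient
  pulses through the garden at 2 of the 8 timepoints (drawn per ASV);
  availability is shared across populations because the garden has a
  single water supply.  During a pulse at day $t$ a sample of population
  $P$ is colonised with probability
  $0.95 \cdot [0.7 + 0.3(1 - e^{-\lambda_P t})]$, where the exchange rate
  $\lambda_P$ is 0.1/day for half the populations and 0.3/day for the
  other half (two rate levels emulating a geographic split; a rate of
  exactly 0 disables uptake entirely).  Outside pulses a transient is
  absent from the garden; field samples carry an ambient baseline of
  0.05.

The pulse mechanism is the substantive modelling choice.  A transient
whose occurrences are scattered independently and identically over all
samples is *exchangeable*: its expected within- and between-population
sharing coincide and its FS straddles 1, carrying no signal.  What makes
real transients detectable is temporal synchrony: taxa arriving through
the shared water appear in many populations at the same sampling time,
while two samples from the same population are usually drawn at different
times.  In this design 12.5% of between-population garden pairs share a
timepoint versus 9.7% of within-population garden pairs, so synchronised
occurrences are relatively more visible between populations and pulsed
transients land reliably below FS = 1.  The pulse count (2), hit
probability (0.95) and uptake floor (0.7) were fixed at values giving that
separation a comfortable margin before the validation thresholds were
frozen; they are ordinary config fields and can be varied for sensitivity
work.  In the degenerate configuration (leak 0, resident presence 1, hit
probability 1, uptake floor 1, baseline 0) the direction is deterministic:
every resident has FS > 1 and every transient FS < 1.

A null generator keeps the sample layout but gives every ASV one presence
probability shared by all samples (drawn uniformly in 0.05–0.6 per ASV);
population labels are then labels only.  It calibrates the PERMANOVA
type-I error (nominal within binomial tolerance in the suite) and yields
an FS distribution that the dip test does not reject.

**What the generator does not emulate:** taxonomic realism, phylogenetic
structure, abundance correlations between ASVs, tank effects (recorded in
metadata but generating nothing by default), compositionality artifacts,
or sequencing error.  Passing the suite therefore shows the chain recovers
planted presence/absence structure of this kind — not that it is robust to
every failure mode of real amplicon data.

# Numerical and interface choices

* Counts must be integers; duplicate IDs, negative or non-numeric cells
  are format errors.  Field samples carry `NA` timepoint/tank sentinels
  (day 0 does not exist in the design; the first garden timepoint is
  24 h).
* A fully zero sample has no defined Sorensen-Dice distance and raises an
  error naming the sample, rather than being assigned distance 1.
* Every permutation or bootstrap consumer takes an explicit `seed` and
  restores the caller's RNG state; the pipeline derives per-stage seeds
  from its single seed, so one config + seed reproduces `report.json`
  byte for byte.
* Permutation p-values use the add-one convention throughout.
* `pseudo_F = +Inf` is the sentinel when $SS_{within} = 0$; the
  permutation p remains well defined.
* No multiple-testing correction is applied anywhere, and the report
  labels its p-values uncorrected.

# Problem sizes used by the validation suite

The suite and the acceptance script run the full chain at the default
design size (222 samples × 500 ASVs, 999 permutations, 2,000 dip
bootstraps), the type-I study at 200 replicates × 199 permutations on a
32-sample null design, and oracle comparisons at $n \le 20$ where the
brute-force references are exact.  These sizes make the whole suite run in
well under a minute while leaving every statistical conclusion
Monte-Carlo-stable; they are package choices, not statements about the
method's limits.

# Known limitations

* One-factor PERMANOVA only; no nested or multi-factor designs, no
  post-hoc pairwise PERMANOVA.
* The dispersion test's permutation scheme holds distances fixed; for
  strongly unbalanced designs a centroid-refitting scheme can differ.
* FS treats every pair equally regardless of sampling time, so it cannot
  distinguish a transient that is synchronised for environmental reasons
  from one synchronised by, e.g., seasonal host physiology.
* Divergence regressions ignore pair non-independence by design
  (descriptive trend, matching the pair-level reading of the data).
* The dip test's uniform calibration is conservative for some unimodal
  nulls with heavy ties; FS distributions with many exactly equal values
  reduce its resolution.
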