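---
title: "fosmap: models, calibration, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fosmap: models, calibration, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fosmap)
```

This vignette is the package's own account of its statistics: the models and
procedures, the parameters that matter and why they default as they do, what
the synthetic generator does and does not emulate, and the places where the
design was genuinely open and we had to choose. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis problem

Serial coronal sections of mouse brains carry two fluorescent signals: a
membrane-targeted axon label expressed from a unilateral amygdalar injection
(so its fluorescence outside the injection site traces long-range axonal
projections), and c-Fos immunoreactivity, an immediate-early-gene proxy for
recent neuronal activity. Four experimental groups arise from crossing
genotype (wild type vs. a haploinsufficient mutant) with optogenetic
theta-burst stimulation of the injected amygdala (sham vs. TBS). After
registration to a labeled atlas (out of scope here; we consume label masks),
the questions are:

1. which regions receive different axonal innervation between genotypes
   (structure-wise comparison along the anterior–posterior axis);
2. whether rewired innervation predicts altered stimulation-evoked activity
   (the rewiring–activity correlation classifier);
3. how pairwise co-fluctuation of regional c-Fos density — functional
   connectivity — differs between groups (correlation networks, centrality,
   communities);
4. whether stimulation changes behavior (paired nonparametric tests).

## 2. Segmentation

**Axon binarization.** The image is multiplied by a pixel-probability map (a
stand-in slot for an external pixel classifier; the default is min–max
normalized intensity, and a constant map of ones gives the identity
behavior). Edges are enhanced by subtracting a Gaussian-blurred copy
(`gaussian_sigma_px`, default 5), and pixels above `sd_multiplier` (default
6) times the standard deviation of the whole processed stack are kept. The
SD is computed over the full multi-slice stack, not per slice, so one global
criterion applies to a brain series. A constant stack yields an empty mask
with a warning, never an error. Because the threshold is SD-relative, the
mask is invariant under intensity rescaling; with a constant probability map
it is invariant under any affine map of intensities.

**Background subtraction.** Rolling-ball background estimation is
implemented as grayscale opening with a ball (hemisphere) structuring
element of the stated radius (default 50 px), computed in C++. Opening is
anti-extensive, so the residual is nonnegative by construction; a pure
linear ramp is reproduced exactly by the opening in the interior (the ball
slides under a plane), so ramps are removed while features narrower than the
ball survive.

**Spot detection.** Cells of stated diameter $d$ (default 10 µm) are found
by a scale-matched Laplacian of Gaussian, $\sigma = d/(2\sqrt{2})$. Local
maxima of the scale-normalized response above `sd_multiplier` (default 2)
times the SD of the background-subtracted stack become candidates; centers
are refined by center of mass of the positive response in a diameter-sized
window, and a greedy pass (ties broken by response, then lowest row/column)
enforces a minimum separation of one diameter within each slice. Detection
is per slice; no across-slice merging (the upstream workflow detects per
section image).

The synthetic fixtures render spots as Gaussian blobs with
$\sigma_{\text{blob}} = d/(2\sqrt 2)$ and axon ridges as curves with a flat
core at the stated amplitude and Gaussian falloff outside the truth width.
The flat core matters: the acceptance criterion counts truth-mask pixels,
and a profile that decays inside the truth mask would render "ridge pixels
at SNR 20" that are not actually at SNR 20.

## 3. Quantification and filters

Events (positive pixels, cell centers) are assigned to the region labeling
their coordinate; background (label 0) events are counted and reported, and
totals are conserved exactly — a property tested on random fixtures. The AP
coordinate of a slice is its anterior face; bins are half-open
$[s, s+100)$ µm. These conventions are configurable; the generator emits
bin-aligned grids but `bin_trace()` handles arbitrary origins and slice
spacings.

Three filters reproduce the study's region selection:

* **Axon floor:** total pixels (both genotypes) must exceed 13 × SD, where
  the SD is over the pooled per-bin axon pixel counts of all contralateral
  regions, and the same SD is reused for the ipsilateral side. We
  deliberately do *not* take the SD over per-region totals: a region holding
  essentially all of the signal contributes $T/\sqrt{n}$ to a totals-SD, so
  $13\,\mathrm{SD} > T$ whenever fewer than $13^2 = 169$ regions exist, and
  the filter would reject everything at toy scale — including the very
  dominant region it is meant to keep. Reading the SD as the distribution of
  the quantification unit (binned counts) makes the criterion a low-signal
  floor at any scale. Additionally, the mutant-group total must strictly
  exceed the 20th percentile (linear interpolation) of mutant per-region
  totals on that side.
* **c-Fos floor:** summed cells over all four groups strictly greater
  than 100.
* **Density exclusion:** c-Fos density is total cells divided by region
  volume in mm³; regions whose density summed over all samples is below
  800 cells/mm³ are dropped (raw density — whether the study used raw or
  relative density is unstated; raw is the only reading available before
  normalization exists). Relative density divides by the WT-control group
  mean, so that group averages exactly 1 per region; a zero WT-control mean
  drops the region with a warning rather than producing infinities. The
  study's manually curated artifact exclusions (injection-site regions and
  related tracts) are a configuration list, not hard-coded.

## 4. Structure-wise statistics

The Friedman repeated-measures test needs one observation per block ×
condition, but group sizes differ. We use AP bins as blocks, groups as
conditions, and the group-mean count per bin as the cell value. This is a
documented resolution of an under-specified design, flagged prominently:
bin-blocked designs reuse the same animals in every block, so any
animal-level variance component (labeling efficiency, global activity
level) correlates blocks and makes the test anti-conservative — see §8.
Ranks use midranks; the statistic carries the standard tie correction
(dividing by $1 - \sum(t^3-t)/(nk(k^2-1))$), matching the Python
implementation lineage the study used; base R's `friedman.test` omits the
correction, and the two agree on tie-free data (tested).

Post hocs are two-sided Wilcoxon signed-rank tests on the bin-matched group
means with one-step Bonferroni over all pairs, run only when Friedman
p < 0.05. An identical pair (all differences zero) is reported as adjusted
p = 1 — no evidence — rather than "untestable", since a multiplicity-
corrected family should not lose members to degeneracy.

The effect metric averages all $|A|\times|B|$ per-bin sample-pair
differences and sums over bins. Algebraically this equals
$\sum_b (\bar A_b - \bar B_b)$; both routes are computed and cross-checked
at every call, so the identity is enforced, not assumed.

## 5. The rewiring–activity classifier

Per region: all pairwise mutant-minus-WT axon difference traces
(ΔoChIEF), the per-genotype TBS-minus-control c-Fos difference traces
(ΔC-FOS), and all pairwise differences of those (ΔΔC-FOS). The Pearson
correlation $r$ between the mean ΔoChIEF and mean ΔΔC-FOS trace is
classified by three criteria: (1) $r$ beyond the one-sided 95% band of the
reshuffled null, (2) $|r| > 0.1$, (3) the product of the two trace
tendencies has the matching sign.

**The null.** Each of the (default 1,000) shuffles reshuffles the AP order
of the three trace families independently of each other and recomputes
$r$. Within a family we apply one common bin permutation to all its traces
(equivalently, to its mean trace). We deviate here from an alternative that
permutes every pair trace independently, for a calibration reason: count
signals have bin-dependent variance (variance tracks the mean along the AP
profile), and averaging independently permuted rows shrinks the shuffled
means toward zero, producing a null far narrower than the sampling
distribution of the observed mean traces. Measured on no-effect cohorts,
the per-trace variant calls 37% of regions correlated; the family-common
permutation — a standard permutation-of-alignment null that conditions on
the observed mean-trace values — is near-nominal (§8). The per-trace
variant remains available as `mode = "per_trace"`.

**Tendencies.** The tendency threshold of a family is defined as the mean
over shuffles of the 99th percentile of the absolute scaled shuffled mean
trace, where scaling divides by the maximum absolute value of the observed
mean trace. Under the family-common permutation the per-shuffle percentile
is permutation-invariant, so the threshold equals the observed trace's own
99th percentile and is computed directly. The tendency is the signed sum of
scaled values exceeding the threshold (zero if none exceed), which for
~20-bin traces amounts to the sign of the most extreme bins — random under
the null, locked to the planted direction under coupling.

**Gate.** Only regions with axon-label Friedman p < 0.05 *and* an adjusted
post hoc p < 0.05 in either TBS-vs-control c-Fos comparison enter
classification, mirroring the study's selection.

## 6. Correlation networks and communities

Functional connectivity is Kendall's τ-b between relative c-Fos densities
of region pairs across the samples of one group. For n < 10 without ties
the two-sided p-value is exact, from the inversion-count null distribution
(the polynomial-product recursion; identical to enumerating all $n!$
permutations, which the test suite does independently); with ties or larger
n, the standard tie-corrected normal approximation on $S$ is used. Entries
with p ≥ 0.05 are set to exactly 0 ("no correlation"), the diagonal is
zero, and no multiple-testing correction is applied across edges (a BH
option exists, off by default). Note the exact test is discrete: at n = 7
the achievable size at the 0.05 level is $2 \cdot 76/5040 \approx 0.030$,
so edge rates *should* sit below 5% — relevant to calibration (§8).

Graphs take nodes from the matrix and edges where $|r|$ and p pass the
thresholds, with weight r. Degree centrality is degree/(N−1). The
participation coefficient is $1 - \sum_m (k_{im}/k_i)^2$ with binary
degrees over the communities of a supplied partition — the weighted variant
was rejected because the upstream definition gives no formula and binary
degrees keep the quantity deterministic under weight perturbations.
Stability sweeps rebuild the graph over an $(|r|, p)$ grid from the
*ungated* τ values (so `p_max = 1` recovers the fully ungated graph) and
track mean DC. Area summaries average gated entries (zeros included — they
are asserted "no correlation", and averaging only survivors would bias
means upward; a significant-only flag exists).

Louvain community detection runs on the positive-weight subgraph (Newman
modularity assumes nonnegative weights; negative edges are < 2.4% of edges
in the study's groups and are retained in the correlation summaries).
Detection is best-of-10 restarts under a fixed seed, reporting weighted
modularity Q at the stated resolution R. The resolution is tuned over
0.4–0.9 (step 0.1) by the maximal mean $Q - Q_{\text{shuffled}}$ against
endpoint-shuffled nulls: each edge keeps its weight but lands on a uniform
random node pair, collisions summing weights — total weight is conserved,
the degree sequence is not. Ties in the tuning argmax go to the smallest R.
An edgeless positive subgraph yields the all-singletons partition with
Q defined as 0.

## 7. Behavior and injection QC

Frame labels aggregate to seconds at 30 fps (18,000 frames per 10-minute
session; a length mismatch warns). The paired test enumerates the exact
signed-rank distribution (subset-sum counts over ranks) for up to 25
untied pairs; W is the smaller signed-rank sum and the two-tailed p is
$P(W^+ \le W) + P(W^+ \ge S - W)$. Zero differences are dropped before
ranking (classical convention); tied absolute differences switch to
midranks with a tie-corrected normal approximation, and every result
carries an `exact` flag and method string. At n = 7 the attainable
two-tailed p-values are the multiples of $1/64$ printed in the study's
behavior figure, which the acceptance suite reproduces for every printed W.

Injection-site separability runs KNN (Euclidean, majority vote, nearest-
neighbor tie-break) with stratified 5-fold cross-validation over a k grid
(odd 1–15, capped below the smallest class), selecting the best-k accuracy.
The null repeats the *entire* procedure, including best-k selection, on
1,000 label permutations, so the selection optimism cancels;
p = (# null ≥ observed)/n_shuffles, with the observed value included in
the comparison convention.

## 8. The synthetic world and what a green test establishes

`simulate_cohort()` draws, per region, a focal AP profile for the axon
label and an independent broad profile for c-Fos; counts are negative
binomial with Var = φ·mean (φ = 2 by default — overdispersion chosen to
stress the rank-based tests; the parameterization Var = µ + µ²/size was
rejected as ambiguous at small means). Genotype effects multiply the mutant
axon mean (defaults: 0.1 contralateral — near-complete loss — and 2
ipsilateral — gain/mistargeting, the study's qualitative finding); c-Fos
group effects add on log-density. Sample-level latent factors (one per
planted community) load on log-density with the stated loading; factor
scores are orthogonalized across samples so planted communities are
*exactly* independent — without this, chance inter-factor correlations of
order $1/\sqrt{n}$ merge planted communities at Louvain and the ground
truth would be wrong, not the method. Coupled regions for the classifier
deposit their extra mutant-TBS activation along the *axon* profile: the
shared AP shape is the planted signal the classifier is meant to detect.

Two generator choices were forced by calibration logic rather than realism:

* **Independent signal profiles.** With one shared profile per region, even
  the "no effects" configuration couples the two signals' magnitude
  patterns (their difference traces share a variance profile), and no AP-
  reshuffling null can represent that dependence — the null world must
  plant none.
* **Pure count-noise null for Friedman calibration.** With animal-level
  variance (lognormal labeling efficiency, per-sample log-density noise),
  the bin-blocked Friedman design rejects almost always under no group
  effect, because blocks reuse the same animals. This is a genuine property
  of the method, not of the implementation; the calibration suite therefore
  uses a null with those components at zero, and users should read
  small Friedman p-values on real data as "consistent group ordering
  across bins", not as animal-level evidence.

What the generator does **not** emulate: real atlas geometry and region
ontology (a rectangular mirrored toy suffices), registration error, optical
artifacts, spatial autocorrelation of c-Fos within regions, and
animal-level covariance between the axon and c-Fos signals. A green suite
therefore establishes correctness of the statistics and plumbing under a
known model — not biological validity of any particular threshold.

Calibration facts the acceptance suite computes (500 no-effect cohorts,
n = 7/group): Friedman region-level rejection and the Kendall significant-
edge rate fall inside the binomial 99% CI of 0.05 computed at n = 500
replicates (half-width ≈ 0.025 — wide enough to admit the exact Kendall
test's discrete size of ≈ 0.030, which a CI at per-pair resolution would
wrongly reject); the classifier's positive+negative rate stays ≤ 0.10.
Recovery facts (100 seeds each): four planted 6-region communities at
loading 0.9 are recovered with adjusted Rand ≥ 0.9 (pooled 32-sample
matrices — per-group n = 8 exact-Kendall gating at |τ| ≥ 0.64 cannot
support full recovery, and the per-group requirement is the separate
within-greater-than-between-τ invariant); planted coupled regions classify
positive in ≥ 90% of seeds.

## 9. Numerical and interface choices

* Exact distributions (signed-rank subset sums, inversion counts) are
  integer-valued double vectors built by convolution and cached; p-values
  are exact rationals up to double rounding.
* All seeded functions save and restore the caller's RNG state; pipeline
  stages derive per-stage seeds from one root seed (kept below $2^{31}$).
* Atlas masks and section images travel as uncompressed little-endian
  grayscale TIFF through a minimal built-in codec (uint8/uint16/float32,
  multi-page) because the target environment provides no TIFF library;
  writes are byte-deterministic. Catalogs, truth, manifests and the QC
  report are JSON; tables are CSV.
* The pipeline configuration is JSON validated against the in-package
  schema (`default_config()`): unknown keys and non-numeric parameters are
  rejected by name. YAML was not used because no parser is available in
  the target environment.
* `sum_of_delta()` cross-checks its two algebraic routes at runtime;
  `detect_spots()` breaks response ties by lowest (row, column) so results
  are order-independent; the shuffle collision policy (sum weights) is
  fixed, with reject-resample intentionally not offered to keep total
  weight conserved exactly.

## 10. Known limitations

Bin-blocked Friedman anti-conservativeness under animal-level variance
(§8); discreteness of exact tests at n ≤ 8 making edge rates conservative;
the 13 × SD axon floor depends on the pooled-count reading (§3) —
totals-based readings do not scale below ~170 regions; Louvain is a local
optimizer, and although we fix seeds and take the best of restarts, global
optimality is not guaranteed; the probability-map stand-in for pixel
classification is intensity-based and will not separate autofluorescence
from label the way a trained classifier can; and the paper-scale headline
counts (numbers of differentially innervated regions, community counts,
negative-edge percentages) depend on the real imaging cohort and are out of
reach of any desk-scale reproduction — the package reproduces the methods
and their analytic/calibration properties instead.
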