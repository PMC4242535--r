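---
title: "Thresholding hemispherical canopy photographs and assessing binarization accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thresholding hemispherical canopy photographs and assessing binarization accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemibin)
```

## The problem

A hemispherical photograph of a forest canopy is interpreted by classifying
every pixel as vegetation or sky. The package fixes the field's standard
convention throughout: a global threshold $t \in [0, 255]$ is chosen on the
blue color plane and pixels with gray value $\le t$ are vegetation, the
rest sky. The blue plane is used because leaves scatter little blue light,
so the vegetation/sky contrast is maximal there. Everything downstream —
gap fraction, and from it leaf area index or site factors — inherits the
threshold choice, so the package pairs the thresholding algorithms with an
estimator of how accurate a given binarization actually is.

## The seven threshold criteria

All histogram-based criteria operate on the 256-bin gray-value histogram of
the mask-true pixels (pixels outside the circular fisheye area never enter
any statistic). Writing $\omega_0(t), \omega_1(t)$ for the class weights,
$\mu_i(t)$ for the class means and $\sigma_i^2(t)$ for the class variances
induced by a candidate threshold $t$ (class 0 = values $\le t$):

* **Otsu** maximizes the between-class variance
  $\omega_0\omega_1(\mu_0-\mu_1)^2$.
* **IsoData** scans upward from the smallest occupied gray value and stops
  at the first $t \ge (\mu_0(t)+\mu_1(t))/2$ — the intersection form of the
  Ridler–Calvard fixed point. If no candidate qualifies before the last
  occupied gray value the last candidate is returned with
  `converged = FALSE`.
* **Maximum entropy** maximizes $H_0(t) + H_1(t)$, the Shannon entropies of
  the two class-conditional distributions; empty bins contribute nothing.
* **Minimum error** minimizes the Kittler–Illingworth criterion
  $J(t) = 1 + 2[\omega_0\ln\sigma_0 + \omega_1\ln\sigma_1]
  - 2[\omega_0\ln\omega_0 + \omega_1\ln\omega_1]$ by exhaustive scan. The
  iterative variant was deliberately not used: its result depends on the
  starting point, which an audit trail cannot defend. A split that leaves a
  class with less than 1% of the pixels is flagged `converged = FALSE` —
  on effectively unimodal histograms this criterion is known to run to an
  extreme, which is exactly the instability users should be warned about.
* **Minimum** smooths the histogram with a three-point moving average until
  exactly two local maxima remain and returns the valley between them.
* **Minimum histogram** rebins at widths $w = 1, 2, \dots$ (first bin
  anchored at gray 0) and stops at the first width showing two modes with a
  single minimum bin between them; the threshold is the middle of that bin.
* **Edge detection** is the one image-based criterion: for each $t$ the
  Edge Value is the mean absolute gray difference over all 4-neighbour
  pixel pairs that straddle the vegetation/sky boundary, and the maximizing
  $t$ is returned. A pair with values $a < b$ straddles the boundary
  exactly for $a \le t < b$, which lets the whole trace be accumulated in
  one pass instead of re-binarizing 256 times.

### Numerical conventions

These choices make the criteria deterministic and testable against
independent exhaustive scans:

* **Ties** break to the smallest optimizing $t$, everywhere. Plateau
  objectives (e.g. any split between two isolated spikes) therefore return
  the plateau's left edge.
* **Plateaus in mode counting** count as a single extremum: a run of equal
  counts is compared against its nearest differing neighbours on each side.
  Without this rule "two modes" is ill-defined on discrete histograms.
* **Valley plateaus** return the floor of the plateau's middle gray value,
  consistent with the minimum-histogram rule "middle of the minimum bin"
  (floor for even widths, since the binarization rule needs an integer).
* **Smoothing** uses edge-replicated boundaries and float accumulation,
  with a cap of 10000 passes; unimodal histograms can never become bimodal
  and error out there. Bin widths above 128 cannot contain two modes plus a
  valley, so the minimum-histogram scan stops at 128.
* **Variance admissibility** in the minimum-error criterion requires both
  class variances above $10^{-7}$. A class concentrated on one gray value
  has true variance 0, but the cumulative-moment computation can leave
  $\sim 10^{-9}$ of floating-point cancellation there; any genuine
  two-valued class of an 8-bit histogram has variance $\ge 1/n$, so the cut
  separates the two cleanly.
* **Edge Value** uses 4-connectivity and the mean (not the sum) of absolute
  differences, so thresholds that merely produce many low-contrast edges
  are not rewarded. An optional stride subsamples the image grid for very
  large rasters; the default of 1 computes the exact objective.

## The accuracy assessment protocol

Accuracy is estimated against reference pixels labeled by an operator on a
per-pixel basis, a design borrowed from the accuracy assessment of remote
sensing map products. The image is stratified into 16 contiguous strata of
16 gray values, and 24 pixels per stratum are drawn by simple random
sampling without replacement (384 in total when all strata are populated).
Stratification forces reference pixels into the sparse mid-gray region
around any plausible threshold — exactly where classifications disagree —
which a uniform random sample would almost never hit.

Within stratum $h$ the sampled confusion matrix (rows = operator, columns =
algorithm) is bias-corrected with the *image marginal proportions*
$W_V, W_S$: the fractions of the stratum's entire pixel population the
algorithm assigned to each class. The corrected cell proportions are
$\hat p_{jk} = W_k\, n_{jk}/n_{\cdot k}$, giving

$$PC_h = W_V\frac{n_{VV}}{n_{\cdot V}} + W_S\frac{n_{SS}}{n_{\cdot S}},
\qquad
\kappa_h = \frac{p_o - p_e}{1 - p_e},$$

with $p_o = \hat p_{VV} + \hat p_{SS}$ and $p_e$ the chance agreement from
the corrected marginals. The per-stratum variance of $PC_h$ is the
stratified binomial form
$\sum_k W_k^2\, q_k(1-q_k)/\max(n_{\cdot k}-1,1)$, $q_k = n_{kk}/n_{\cdot k}$;
the variance of $\kappa_h$ is the standard delta-method (Fleiss–Cohen–
Everitt) large-sample expression evaluated on the corrected proportions and
divided by $n_h$. Overall estimates are weighted by stratum population
shares $N_h/N$, with variance $\sum (N_h/N)^2 \mathrm{var}_h$ and symmetric
normal 95% intervals. A 0/0 column ($W_k = 0$ and $n_{\cdot k} = 0$)
contributes nothing — the stratum genuinely holds no such pixels — and
empty strata carry weight 0.

### The degenerate-kappa convention

Under a global threshold, every stratum whose gray range does not contain
$t$ is single-class for the algorithm ($W_V \in \{0,1\}$). Algebra on the
corrected cells shows that $p_e = 1$ can occur only when such a stratum
also agrees perfectly with the operator ($p_o = 1$); the chance correction
is then undefined (0/0) and the package reports $\kappa_h = 1$ with a
`degenerate` flag. This is the only convention consistent with
"$\kappa = 1$ iff zero off-diagonal cells in every weighted stratum": the
alternative of scoring such strata 0 would drag the overall kappa of a
*perfect* binarization toward 0, since 15 of 16 strata are single-class by
construction. Conversely a single-class stratum with any disagreement
yields $p_o = p_e < 1$ and hence $\kappa_h = 0$ automatically — a constant
classifier earns no chance-corrected credit, which is also why grossly
misplaced thresholds (the minimum-error pathology) produce overall kappas
near 0 without any special handling.

### Gap fraction

$GF_{pic}$ is the sky share of the analyzed pixels of the binarized image,
computed over the whole photograph with no zenith-angle weighting (the
mask defaults to the full frame; a circular fisheye mask is available and
configurable). $GF_{ref} = \sum_h (N_h/N)(s_h/n_h)$ is the design-unbiased
stratified estimate from the operator labels. Their ratio is reported as
misestimation; it deliberately separates classification errors that cancel
(which leave gap fraction untouched) from those that bias it.

## The synthetic scene generator

`scene_params()` fixes the study conditions of the simulator; its defaults
describe a moderately closed, foliated canopy on the blue plane:

| parameter | default | meaning |
|---|---|---|
| `width`, `height` | 512 px | scene size |
| `canopy_cover` | 0.7 | vegetation share of the procedural truth |
| `structure_scale` | 8 px | smoothing length of the random field (clump/gap size) |
| `mixed_fraction_target` | 0.03 | share of pixels rendered as boundary mixtures |
| `mu_veg`, `sigma_veg` | 40, 15 gray | vegetation gray distribution |
| `mu_sky`, `sigma_sky` | 200, 20 gray | sky gray distribution (approx. normal) |
| `zenith_gradient` | 30 gray | peak-to-edge brightness difference, zenith brightest |
| `exposure` | histogram | histogram: max rendered value scaled to exactly 255, nothing clips; auto: `clip_excess` added, clamped |
| `clip_excess` | 60 gray | brightness excess under auto-exposure |
| `blooming_radius` | 2 px | reach of saturation blooming into vegetation |
| `seed` | — | drives the whole generate/render/bloom chain |

The class means put the bimodal valley near gray 110–130 with strong
blue-plane contrast; the sigmas overlap the tails slightly so thresholds
matter; the 3% mixed-pixel share mimics a foliated canopy at typical
camera resolutions (the defoliated, fine-structure case the protocol
cannot assess reliably corresponds to much higher values, which the user
can set). Under auto-exposure the 60-gray excess saturates essentially all
sky, producing the characteristic spike at 255, and blooming then raises
nearby vegetation values (truth labels are never changed — blooming
corrupts gray values, not classes). Under histogram-exposure at most the
single brightest pixel touches 255, so blooming is inert by construction.
Mixed pixels render as $\alpha V + (1-\alpha) S$ with $\alpha$ uniform on
$(0,1)$; the census rule assigns them to vegetation at $\alpha \ge 0.5$
(`alpha_rule = "half"`), or drops them (`"exclude"`), mirroring how an
operator forced to a binary label behaves. Truth is a thresholded smoothed
random field — deliberately procedural, not a radiative canopy model: it
reproduces the features the estimators respond to (bimodality, mixed
boundary pixels, gradient, clipping, blooming) and nothing else.

What passing tests on these scenes do **not** show: robustness to JPEG
compression artifacts, camera gamma curves, sun glare, understory
reflections, or the heavily mixed defoliated canopies that defeat
per-pixel reference labeling altogether. Those remain the user's
responsibility on real photographs.

## Validation design and problem sizes

The test suite validates each criterion against an independently coded
exhaustive scan of its stated objective on seeded bimodal mixture
histograms (bit-exact integer agreement; 100 histograms in the acceptance
run), plus hand-derivable micro-cases (two-triangle histogram, two-spike
histogram, a 3-pixel edge-detection toy).

Estimator calibration is checked on a 512×512 default scene with 500
independent stratified resamples: the mean PC must sit within 0.5
percentage points of the census PC, the normal 95% intervals must cover
the census value at a near-nominal rate, and the mean reference gap
fraction must recover the census sky share. The assessed binarization is
the maximum-entropy one (census PC ≈ 0.977 on the default scene) rather
than a nearly perfect classifier: at 2–3% error — the accuracy regime the
protocol is designed for — every informative stratum shows sampled errors
and the variance estimator is well behaved, whereas a classifier at 99.8%
census accuracy concentrates its errors in near-empty cells where any
binomial variance estimate collapses and normal-interval coverage is known
to fall below nominal. The exposure-effect experiment compares
misestimation of Otsu/IsoData/MaxEntropy between histogram- and
auto-exposed renderings of the same 20 seeded truths at 256×256; these
sizes keep the full validation run within a couple of minutes on one core
while leaving Monte-Carlo noise far below the tested margins.

## Known limitations

* JPEG input is accepted as-is; no attempt is made to undo compression
  artifacts or camera gamma, both of which are known to influence derived
  parameters.
* The kappa variance uses the standard delta-method expression; an exact
  design-based variance for the bias-corrected stratified kappa is not
  implemented.
* Gap fraction is the unweighted whole-photo sky share; no lens-projection
  model or zenith-ring weighting is applied.
* Local (sector-wise) thresholding, sub-pixel three-class methods and
  above/below-canopy ratio methods are out of scope.
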