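---
title: "Models and methods behind airspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind airspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, the numerical choices, and the
limitations of the `airspace` package: a pipeline for quantifying alveolar
airspace enlargement (emphysema) in lung histology sections, together with
the statistical machinery used around it — group comparisons of morphometric
indices, a synthetic clinical cohort with a planted COPD model, and
relative-quantification qPCR arithmetic.

## The scientific problem

Emphysema destroys alveolar walls, so airspaces become fewer and larger.
Given a grayscale section image, the pipeline must (1) separate airspace
from tissue despite staining noise and uneven illumination, (2) measure the
resulting airspace compartments in physical units, and (3) summarise each
image by an index sensitive to the enlarged tail of the size distribution,
so that genotype or treatment groups can be compared with rank tests.

## Segmentation model

### Fuzzy c-means with a multiplicative bias field

Pixel intensities $x_p$ are clustered into two fuzzy classes (tissue,
airspace) while jointly estimating a smooth multiplicative illumination
field $b_p$. The objective is

$$J = \sum_p \sum_{k \in \{1,2\}} u_{pk}^m \,(x_p - b_p v_k)^2,$$

minimised by alternating the standard fuzzy-membership and centroid
updates with a bias re-estimate: the ratio of observed to reconstructed
intensity, Gaussian-smoothed and clamped.

Parameter choices (all in `fcm_params()`):

* `m = 2` — the conventional fuzzifier; larger values blur the class
  boundary without benefit for a two-class problem.
* `tol = 1e-4` on the maximum per-pixel membership change — memberships
  live in $[0,1]$, so this is a 0.01 % stability criterion; the loop
  typically converges in under ten iterations.
* `bias_smooth_sigma = min(H, W) / 4` pixels — illumination varies on the
  scale of the whole slide, not of an alveolus; a quarter-image kernel
  cannot absorb real structure.
* `bias_clamp = c(0.5, 2)` — a slide never physically doubles or halves its
  illumination locally; the clamp prevents the field from explaining away
  true class contrast.

Initialisation is deterministic (centroids at the 25th/75th intensity
percentiles, bias at 1), so segmentation never depends on a random seed.
The Gaussian smoothing of the bias field downsamples by `floor(sigma/4)`,
smooths with a separable kernel, and upsamples bilinearly — an
$O(HW)$ approximation that makes the quarter-image kernel affordable.

### Graph-cut refinement

The fuzzy memberships give per-pixel label costs; spatial coherence is
imposed by exactly minimising the two-label Potts energy

$$E(L) = \sum_p -\log \max(u_{p,L(p)}, \epsilon)
  + \lambda \sum_{(p,q) \in N_4} [L(p) \ne L(q)]\,
    e^{-(x_p-x_q)^2 / 2\sigma_i^2}$$

with Boykov–Kolmogorov max-flow on the standard $s$–$t$ construction. The
pairwise term is submodular, so the returned labeling is the exact global
minimum — `graph_cut_refine()` also reports the energy of the plain
argmax-membership labeling, which it can never exceed. The test suite
verifies exactness against brute-force enumeration on small grids.

* `lambda = 0.5` — enough smoothing to remove isolated noise pixels
  without erasing thin tissue septa; `lambda = 0` reduces to per-pixel
  argmax.
* `sigma_i` defaults to the mean absolute 4-neighbour intensity
  difference, a scale-free contrast normalisation.
* `epsilon = 1e-6` floors memberships before the log so single pixels can
  never carry infinite cost.

A pure R max-flow was too slow at image scale, so the Boykov–Kolmogorov
algorithm is implemented in C++ (via Rcpp); it solves a 512×512 image in
tens of milliseconds.

## Morphometry

Connected airspace components are labeled (4-connectivity by default —
conservative against one-pixel bridges merging distinct alveoli) and each
compartment of $A$ µm² gets the equivalent diameter $d = 2\sqrt{A/\pi}$.
The image is summarised by the moment-ratio index

$$D_k = \frac{\sum_i d_i^{k+1}}{\sum_i d_i^k},$$

with `k = 2` as default: $D_0$ is the arithmetic mean, and $D_k$ increases
with $k$ towards $\max d$, so $D_2$ up-weights the enlarged airspaces that
mark early emphysema while staying bounded by the largest observed
compartment.

Two filters are applied before the index:

* compartments touching the image border are excluded (default) because
  their truncated areas bias the diameters unpredictably;
* compartments below `min_diameter_um = 138` µm are disregarded, so the
  index targets abnormally enlarged airspaces rather than the bulk of
  normal alveoli.

Both choices interact with field size: in a small field most large
compartments touch the border, which truncates exactly the tail $D_2$ is
designed to see. This drove the simulation sizes below.

## Synthetic data generators

### Histology (`generate_alveolar_image()`)

A Boolean disc model: disc centers are uniform, the count is Poisson with
intensity chosen so the expected union covers `target_area_fraction`
(using $E[\text{covered}] = 1 - e^{-\text{total disc area}/\text{image
area}}$), and equivalent diameters are lognormal (median 60 µm,
`sdlog = 0.5` at severity 0 — the scale of normal-to-mildly-enlarged mouse
alveolar airspaces). A `severity` in $[0,1]$ multiplies diameters by
$3^{\text{severity}}$ while the disc density is scaled down to hold the
expected area fraction, emulating progressive enlargement at constant
airspace content. On top of the exact rasterised union the generator adds
the two class intensities (0.45 tissue / 0.85 airspace), Gaussian noise
(SD 0.05), and a planar multiplicative illumination ramp whose extreme
corners are exactly $1 \pm$ `bias_amplitude`.

The generator emulates: bimodal intensities, acquisition noise, smooth
illumination inhomogeneity, and a diameter distribution under analytic
control (the ground truth ties directly to what $D_2$ measures). It does
**not** emulate: tissue texture, staining variability within a class,
non-circular airspace shapes, septal wall thinning, or imaging artifacts
such as tears and folds. Conclusions about absolute segmentation accuracy
therefore transfer to real slides only qualitatively.

### Clinical cohort (`generate_cohort()`)

One row per patient in a two-group vascular-surgery cohort (aortic
aneurysm, AA, versus arterial occlusive disease, AOD; default split
614/1393). Binary baseline covariates are Bernoulli at per-group
prevalences typical of such cohorts (current smoking is drawn within
ever-smokers so the flags are consistent); COPD comes from an explicit
logistic model with default intercept $\mathrm{logit}(0.26)$ and group
log-odds $\log 2.08$, so association analyses can be validated against
planted coefficients; COPD severity (GOLD class) and spirometry values are
drawn so that `classify_gold()` maps each record back to its assigned
class. The generator does not model covariate–covariate correlation
(beyond smoking), confounding between covariates and COPD (unless planted
via `beta_covariates`), or informative missingness of spirometry.

### qPCR panel (`generate_qpcr_panel()`)

Under perfect amplification efficiency each halving of expression raises
the target Ct by one cycle: $Ct = \text{base} - \log_2(\text{ratio}) +
\text{noise}$, housekeeping ratio fixed at 1. Defaults plant 2-fold and
4-fold downregulation (ratios 0.5 and 0.25), measured in triplicate over
four samples per genotype. Efficiency below 2 per cycle, plate effects,
and outlier replicates are not modeled.

## Statistics

Group comparisons use rank tests, reported with raw p-values and no
multiplicity correction (the report labels every test so a caller can
correct as desired):

* **Mann–Whitney U** (`mann_whitney()`): $U = \min(U_1, U_2)$; for
  $n_1+n_2 \le 16$ the two-sided p-value is exact by enumeration of all
  $\binom{n_1+n_2}{n_1}$ rank assignments; above that, a normal
  approximation with tie-corrected variance and a 0.5 continuity
  correction. The continuity correction was adopted because without it the
  exact and asymptotic p-values disagree by up to 0.046 at the enumeration
  boundary; with it the worst disagreement over every attainable U at
  $n_1 = n_2 = 8$ (untied) is 0.011.
* **Kruskal–Wallis** (`kruskal_wallis()`): H with tie correction, p from
  $\chi^2_{g-1}$.
* **Kolmogorov–Smirnov** (`ks_two_sample()`): exact by enumeration up to
  combined size 12, else the asymptotic Kolmogorov distribution.

The enumeration cutoffs (16 for MW, 12 for KS) keep exact computation
under a second; both tests fall back to their asymptotics transparently
(`exact` is reported in every result).

Cohort analyses: Pearson chi-square without continuity correction for
prevalence contrasts; logistic regression via iteratively reweighted least
squares (`stats::glm`) with Wald 95 % intervals $\exp(\hat\beta \pm
1.96\,SE)$. Separation is detected when a coefficient's magnitude times
the observed range of its predictor exceeds 15 log-odds — the range
scaling avoids false alarms on legitimately steep slopes over
near-constant covariates, such as a propensity score.
`propensity_covariate_fit()` models spirometry availability on covariates
and adds the fitted probability as an adjustment covariate; a constant
availability indicator degrades gracefully to the unadjusted fit with a
warning.

## Problem sizes

All simulation sizes in this package are its own choices, made for
tractability on a single CPU:

* The generator default is a 1024² image at 2 µm/px (a 2048 µm field), a
  plausible 10×-objective tile.
* The pipeline demo config uses 256² at 16 µm/px (a 4096 µm field) so a
  full simulate–segment–quantify–compare run takes about a second.
* The power property (severity 0.2 vs 0.8, ten images per group, detected
  by Mann–Whitney at $\alpha = 0.05$) is verified on 256² images at
  32 µm/px — an 8192 µm field. The field must be large relative to the
  enlarged compartments: in a 2048 µm field, border exclusion removes most
  of the large-compartment tail at high severity and the group contrast
  nearly vanishes; at 8192 µm the contrast is detected in effectively
  every repetition. Coarse resolution costs little here because the
  filtered compartments (≥ 138 µm) remain many pixels wide.

## Limitations and open questions

* The Boolean disc model has no spatial regularity; real alveoli tile the
  tissue. Absolute $D_2$ values from the generator are not calibrated to
  any particular organism or stain.
* Border exclusion makes $D_2$ downward-biased in small fields; choose
  fields several times larger than the largest expected compartment, or
  expect the bias to be shared across comparison groups at equal field
  size.
* The 138 µm filter is a fixed default, not estimated from data; indices
  across studies are comparable only at the same threshold.
* The exact Mann–Whitney p is defined as $P(\min(U_1,U_2) \le
  u_{\text{obs}})$, which matches the classic two-sided doubling rule on
  continuous data but is a deliberate single convention under heavy ties.
* The logistic Wald intervals are asymptotic; no profile-likelihood or
  exact intervals are provided.
* The propensity adjustment uses the score as a covariate — the simplest
  of several possible uses (matching, weighting, stratification), chosen
  because it preserves the full sample.
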