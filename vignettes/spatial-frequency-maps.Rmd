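---
title: "Modeling spatial-frequency maps in visual cortex with sfmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spatial-frequency maps in visual cortex with sfmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfmaps)
```

## The problem

fMRI measures the pooled response of tens of thousands of neurons per
cortical vertex. In early visual cortex those populations are tuned to
spatial frequency, and the tuning varies lawfully across the retinotopic
map: populations representing the fovea prefer high spatial frequencies,
peripheral ones prefer low frequencies, and preferences are further
modulated by stimulus orientation. `sfmaps` provides a complete, testable
implementation of a compact modeling approach to this structure: scaled
grating stimuli, a one-dimensional tuning-curve analysis, a nine-parameter
model of an entire visual-field map, and cohort-level aggregation — plus a
synthetic-data generator so that every stage can be validated against known
ground truth without any imaging data.

## Scaled gratings and their local structure

A scaled grating is the log-polar pattern
$$I(r, \theta) = \cos(\omega_r \ln r + \omega_a \theta + \phi),$$
with radial frequency $\omega_r$ (radians per unit of $\ln r$) and angular
frequency $\omega_a$ (cycles per revolution, integer-valued to avoid edge
artifacts). Its local spatial frequency depends only on eccentricity,
$$\omega_l(r) = \frac{\sqrt{\omega_r^2 + \omega_a^2}}{r}
\quad \text{radians/deg},$$
and its local orientation only on polar angle,
$\theta_l = \theta + \arctan(\omega_a/\omega_r)$. Because the phase in the
image equation is in radians, $\omega_l$ is a radian frequency; the package
reports cycles/degree by dividing by $2\pi$. This convention is not taken
on faith: `measure_local_frequency()` recovers the phase field of a
rendered image in quadrature (two renders a quarter cycle apart) and
finite-differences it, and the test suite requires the measured field to
match the analytic one within 2% in frequency and 2 degrees in orientation
across the whole catalog. The same oracle pins the orientation convention:
$\theta_l$ is the direction of the local phase gradient, so an annulus on
the right horizontal meridian has $\theta_l = 0$ and vertically oriented
contours — which is what makes $\cos 2\theta_l = +1$ select "vertical" in
the 2D model below.

The built-in `make_catalog()` reproduces the 28-class NSD design: six
pinwheels ($\omega_r = 0$), six annuli ($\omega_a = 0$), six forward and
six reverse spirals ($|\omega_r| = |\omega_a|$), four mixtures, each at
four phases. Forward spirals are assigned $(\omega_r, \omega_a) = (k, -k)$;
only the magnitudes are pinned by the design, and the choice is immaterial
to the model terms, which are even in orientation. The integer constraint
on $\omega_a$ means the spiral base frequencies $k\sqrt{2}$ only
approximately match the annulus/pinwheel ones (discrepancies up to ~11%).

Near the image center the local frequency diverges; a circular
anti-aliasing mask replaces the region above a cutoff frequency with mean
luminance. The renderer defaults the cutoff to the pixel-grid Nyquist
frequency (`ppd/2`), which also absorbs the $r = 0$ singularity of
$\ln r$. The display cutoff that produced the published 0.02–0.5 degree
mask radii is not recoverable from the stimulus parameters alone, so exact
reproduction of those radii is out of scope; the mask-radius *ordering*
across the catalog, which is what the vertex exclusion rule depends on, is
cutoff-independent.

```{r catalog}
cat28 <- make_catalog()
table(cat28$shape)
local_stimulus(2, pi / 4, omega_r = 6, omega_a = 0)
```

## The 1D pathway: binned tuning curves

Vertices are binned by pRF eccentricity (0.5° steps from 0.5° to 4° for the
NSD-like range; bins are half-open on the right, last bin closed, a
convention the data source leaves open). Within each bin, responses are
averaged over trials, vertices, and the four primary shapes at each of the
six base-frequency levels — under the 1D model the response depends only on
local spatial frequency, not orientation — and mixtures are excluded (24 of
the 28 classes). Each bin's six points are fit with a log-Gaussian in
period,
$$\hat\beta_b(p_l) = A_b \exp\!\left(-\frac{(\log_2 p_l - \log_2 p_b)^2}
{2\sigma_b^2}\right),$$
by least squares with $p_b, \sigma_b$ kept positive via log-coordinates
(BFGS). Because the four shapes' base frequencies match only approximately,
the period attributed to a (bin, level) cell is evaluated at the bin center
using the geometric mean of the four base frequencies — the natural choice
for a model that lives on a log-period axis. A line fit of $p_b$ against
bin center (OLS) summarizes the growth of preferred period with
eccentricity.

## The 2D model: nine parameters for a whole map

The map-level model predicts every vertex's response to every stimulus
class from nine numbers:
$$\hat\beta_v(p_l, \theta_l) = A_v \exp\!\left(-\frac{(\log_2 p_l -
\log_2 p_v)^2}{2\sigma^2}\right),$$
$$p_v = (a r_v + b)\,(1 + p_1\cos 2\theta_l + p_2\cos 4\theta_l +
p_3\cos 2(\theta_l - \theta_v) + p_4\cos 4(\theta_l - \theta_v)),$$
$$A_v = 1 + A_1\cos 2\theta_l + A_2\cos 4\theta_l.$$

$\sigma$ (octaves) is shared across the map. $a$ and $b$ are the affine
eccentricity dependence of preferred period. $p_1, p_2$ ($A_1, A_2$)
capture absolute-orientation effects on period (gain): positive $p_1$
means vertical > horizontal, positive $p_2$ cardinal > oblique. $p_3, p_4$
capture orientation relative to the pRF's polar angle: positive $p_3$
means annuli (radial orientation) > pinwheels, positive $p_4$ non-spirals
> spirals. Gain is deliberately not allowed to depend on relative
orientation. All local stimulus values are evaluated at the vertex's pRF
center.

### Loss and optimizer

Each vertex contributes the precision-weighted, L2-normalized mean squared
error between its observed trial-mean betas and the model prediction across
the 28 classes:
$$L_v = \frac{1}{\sigma_v^2} \frac{1}{n} \sum_{i=1}^{n}
\left(\frac{\beta_{iv}}{\lVert\beta_v\rVert_2} -
\frac{\hat\beta_{iv}}{\lVert\hat\beta_v\rVert_2}\right)^2,$$
where $\sigma_v^2$ is the vertex's trial variance averaged over classes
(sample variance, $n-1$ denominator — the convention is not dictated by the
definition and is fixed here once). Normalizing both vectors makes the fit
sensitive to the response *pattern* only, and precision weighting
discounts noisy vertices without discarding them. The map loss is the
*mean* of $L_v$ over vertices (sum vs mean is left open by the
definition; the mean keeps the loss scale independent of map size, and the
two differ only by a constant factor that no parameter depends on).

Minimization uses Adam (learning rate $10^{-3}$, at most 20,000
iterations, stopping when the relative loss change over 100 iterations
falls below $10^{-7}$ — all configurable) on analytically differentiated
internal coordinates. Positivity is enforced by reparameterization rather
than clipping: $\sigma$, $a$, $b$ pass through a softplus (a nonnegative
slope plus positive intercept guarantees $a r + b > 0$ at every
eccentricity), and the modulation vectors through
$q \mapsto q / (1 + \sum_j |q_j|)$, which keeps
$|p_1| + |p_2| + |p_3| + |p_4| < 1$ and $|A_1| + |A_2| < 1$ and hence
period and gain positive at every orientation. Published modulation
estimates are below 0.2 in magnitude, far from the bound, and the map is
the identity to first order near zero, so the constraint is inert in
practice while guaranteeing a well-defined model during optimization. The
analytic gradient is verified against central finite differences to 1e-5
in the test suite, and the vectorized loss against a scalar loop-based
re-implementation to 1e-10.

Initialization is $\sigma = 2$, $a = 0.1$, $b = 0.3$, all modulations 0 —
near published group values and inside the constraint region. The fit is
deterministic given data, initialization and configuration; the recorded
seed is provenance only.

```{r fit-example, eval = FALSE}
cfg <- sim_config(n_vertices = 1000, seed = 0)
subj <- simulate_subject(cfg, 1)
kept <- filter_vertices(subj$vertices, subj$betas, mode = "2d")$kept
fit_2d_model(kept, subj$betas)
```

### Vertex exclusion rules

Before fitting, three rules drop vertices whose data cannot constrain the
model: negative mean response across the relevant class set (24 classes
for the 1D pathway, 28 for the 2D), pRF centers inside the largest
anti-aliasing mask (eccentricity < 0.5°), and — 2D only — pRF centers more
than one pRF size outside the 4.2° stimulus extent. Exact-boundary cases
keep the vertex (the data source does not specify edge handling; one
inclusive convention is applied everywhere and tested). The exclusion log
reports one count per rule, attributing each dropped vertex to the first
rule it violates.

## Aggregation across subjects

Each subject gets a single precision, $\sigma_s^2$: the mean of its
vertices' $\sigma_v^2$ over the fitted map. Cohort estimates are
inverse-variance weighted means,
$$\bar{x} = \frac{\sum_s x_s / \sigma_s^2}{\sum_s 1/\sigma_s^2},$$
with the same weight for every eccentricity bin and every parameter of a
given subject. Uncertainty comes from a subject-level percentile bootstrap:
resample subjects with replacement (each keeping its own weight), recompute
the weighted mean, report the 16th–84th percentiles (10,000 replicates by
default). Resampling parameter *values* rather than refitting per replicate
is the implemented choice: refitting inside the bootstrap is
computationally implied nowhere in the procedure being emulated, and the
values-only bootstrap is the standard reading of "bootstrapped across
subjects". Within-subject ROI contrasts (e.g. V2−V1 bandwidth) difference
the two fits per subject and weight by the *sum* of the two ROI variances,
the variance of a difference of independent estimates.

## The synthetic-data generator

The generator exists to make every stage falsifiable: it produces data with
exactly the statistical structure the analysis assumes, from known truth.

- pRF layouts: log-uniform eccentricity over 0.5–4.2° (NSD-like; 1–12° for
  a Broderick-like variant), uniform polar angle, pRF size
  $0.1 + 0.2 \cdot$ eccentricity (coefficients configurable; they only
  feed the extent filter).
- Responses: noiseless betas from the 2D model at each pRF center; 8
  trials per class with independent Gaussian noise. The per-vertex trial
  SD is `noise_sd_scale` (default 0.5) × the vertex's mean absolute
  response, multiplied by a log-normal factor with log-SD
  `noise_heterogeneity` (default 0.5) so that vertex and subject
  precisions genuinely vary — without heterogeneity, precision weighting
  would be untestable. Defaults emulate realistic single-trial fMRI SNR:
  trial-mean SEM ≈ 18% of the mean response at 8 trials.
- 2% of vertices are generated with sign-flipped mean response to exercise
  the negative-mean exclusion rule.
- 8 subjects per cohort by default; optional between-subject jitter of the
  generating parameters. All draws derive deterministically from one seed,
  and a subject regenerates bit-identically from (config, index).

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: GLM-induced noise correlations across
classes, spatial correlation along the cortical surface, pRF estimation
error, hemodynamic nonlinearity, and between-subject differences beyond
parameter jitter. Recovery results on synthetic cohorts validate the
estimation machinery, not the model's adequacy for cortex.

## Numerical choices and problem sizes

- Octaves are $\log_2$ throughout; natural-log variants are deliberately
  absent. `fwhm_octaves()` converts an SD to full width at half maximum
  ($2\sqrt{2\ln 2}\,\sigma$): SDs of 2.2 and 4.5 octaves correspond to
  FWHMs of 5.2 and 10.6.
- The quadrature phase-gradient validator samples between 2× the mask
  radius and 0.9× the image half-width, where discretization error of the
  centered difference is below the 2% band.
- Noiseless maps have $\sigma_v^2 = 0$; the fitter floors the variance at
  $10^{-12}$, which (Adam being invariant to the overall loss scale)
  reduces to uniform weighting for an all-noiseless map.
- Degenerate 1D bins (empty, or fewer than 3 distinct frequencies) are
  reported and skipped, not silently interpolated; constant-response bins
  are flagged.
- Test and validation problem sizes are chosen to exercise each property at
  the smallest scale where it is decisive: single-map unit tests use
  150–600 vertices (per-subject estimates are unbiased already at 150
  vertices — checked directly), end-to-end recovery uses the full
  8 × 1000-vertex cohort, and the bootstrap-calibration study uses 20
  cohorts of 8 × 150 vertices. At 8 subjects the percentile bootstrap is
  expected to undercover mildly (true coverage near 0.6 for a nominal
  0.68 interval); calibration is therefore assessed as the
  parameter-pooled coverage rate across 9 parameters × 20 cohorts, since a
  single parameter's empirical rate at 20 cohorts carries ±10 pp binomial
  noise.

## Known limitations

- The affine period–eccentricity law and the single map-wide bandwidth are
  assumptions inherited from the model being implemented, not findings of
  this package; alternative forms (difference-of-Gaussians tuning,
  non-affine eccentricity dependence) are out of scope.
- The forward-spiral sign assignment and the screen-coordinate sense of
  the pRF polar angle are conventions; the model's even orientation terms
  make the results invariant to a joint reflection, but single-vertex
  orientation values should not be compared across packages without
  checking conventions.
- The fitter consumes trial-level betas in the documented CSV schema;
  estimating betas from time series (GLM fitting) is explicitly outside
  the package.
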