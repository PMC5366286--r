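---
title: "Non-Gaussian diffusion modelling in cardiac diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-Gaussian diffusion modelling in cardiac diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiffusion)
```

## The problem

Diffusion tensor imaging summarises water displacement in tissue by a
single Gaussian profile per voxel. In myocardium, membranes, organelles
and the laminar sheetlet architecture hinder and restrict diffusion, so
the signal measured at strong diffusion weighting (high b-value) departs
from the monoexponential decay the tensor model predicts. This package
implements a family of one-dimensional diffusion models fit along the
eigenvectors of the diffusion tensor, ranks them with the corrected
Akaike information criterion (AICc), and provides the surrounding
pipeline: phase-based noise handling, cardiac angle maps, a synthetic
phantom generator, and group statistics for comparing healthy, sham and
pressure-overload (TAC, transverse aortic constriction) hearts.

## The model family

Under the assumption that each voxel contains a spectrum of Gaussian
diffusion environments with density $P(D)$, the normalised signal is the
Laplace transform

$$\frac{S(b)}{S(0)} = \int P(D)\, e^{-bD}\, dD .$$

The implemented attenuations $f(b)$ are:

| model | $f(b)$ | diffusivity spectrum |
|---|---|---|
| monoexponential / tensor | $e^{-bD}$ | point mass |
| stretched exponential | $e^{-b^{a} D_s}$ | no analytic form |
| diffusion kurtosis (DK) | $e^{-bD + K b^2 D^2/6}$ | Gaussian, variance $D^2K/3$ |
| biexponential | $v e^{-bD_f} + (1-v) e^{-bD_s}$ | two point masses |
| truncated Gaussian | error-function ratio $\times$ Gaussian-in-$b$ | normal truncated at 0 |
| gamma | $(1 + b\theta)^{-k}$ | gamma |
| beta | $M(\alpha, \alpha{+}\beta, -bD_{max})$ | beta on $(0, D_{max})$ |

$M$ is the Kummer confluent hypergeometric function. Throughout,
**kurtosis** is the normalised variance of the diffusivity spectrum,
$K = 3\,\mathrm{Var}[D]/E[D]^2$, zero for a single Gaussian environment;
this convention is verified against the closed forms $K=3/k$ (gamma) and
$K = 3\beta/(\alpha(\alpha+\beta+1))$ (beta). Skewness is reported for
the gamma ($2/\sqrt{k}$) and beta families only; the stretched
exponential supports neither a mean diffusivity nor a kurtosis because
$b^a$ has no Taylor expansion in $b$ for non-integer $a$, and the
package refuses those queries rather than inventing values.

Three-dimensional data are handled by the factorisation
$S/S_0 = \prod_{i=1}^3 f(b_i)$, where $b_i = b\,(g \cdot v_i)^2$
projects the diffusion weighting onto the tensor eigenvectors; the
projections sum exactly to $b$. This assumes non-Gaussian diffusion
shares the tensor's principal frame — a necessary assumption for using
one-dimensional statistical models, at the cost of not supporting a full
kurtosis tensor.

### Numerical choices in the model zoo

* The truncated-Gaussian attenuation multiplies a tiny error-function
  ratio by a potentially enormous $e^{b^2\sigma^2/2}$; it is evaluated
  in log space via `pnorm(..., log.p = TRUE)`, accurate far into the
  tails.
* The truncated-Gaussian normalising coefficient is
  $A = 2 / (\sigma\sqrt{2\pi}\,(1 + \mathrm{erf}(D_m/\sigma\sqrt{2})))$,
  i.e. the reciprocal of the upper-tail normal mass.
* $M(\alpha, c, -x)$ is computed through the Kummer transformation
  $e^{-x} M(c-\alpha, c, x)$, whose series has all-positive terms, so no
  cancellation occurs even at $x = b_{max} D_{max} \approx 50$. No
  installed special-function library provides ${}_1F_1$, so the series
  is implemented here and verified against adaptive quadrature of the
  beta density (agreement $\sim 10^{-13}$) and against the defining
  series.
* Quadrature oracles for the beta family substitute $u = t^\alpha$ /
  $u = (1-t)^\beta$ at the endpoints, because shape parameters well
  below 1 (which Table-level myocardial fits do produce along the
  primary eigenvector) make the raw density too singular for generic
  adaptive quadrature.
* The stretched exponential is exposed in two parameterisations,
  $e^{-b^a D_s}$ (default, `stretched_form = "separate"`) and
  $e^{-(bD_s)^a}$ (`"compound"`); both occur in the literature and the
  printed form of the model is typographically ambiguous about the
  exponent's reach.
* The DK spectrum is a Gaussian that is **not** truncated at zero, so it
  alone may be evaluated on diffusivity grids extending below zero, and
  its attenuation is non-monotone beyond $b = 3/(DK)$.

## Fitting

Each model is fit voxelwise by bounded nonlinear least squares on the
signal (not its logarithm), using Levenberg–Marquardt with box
constraints (minpack.lm) — the bounded-NLS engine available in this
stack; positivity and physical ceilings are enforced through the box.
By default the six symmetric tensor elements defining the eigenframe are
re-optimised jointly with the shape parameters (`fit_frame = "joint"`);
only their eigenvectors enter the forward model. A `"frozen"` mode
keeps the frame of the initial linear tensor fit, at roughly half the
cost — useful when the frame is known to be well determined. The AICc
parameter count is fixed per model (8 for the tensor; 14 for stretched,
DK, truncated Gaussian and gamma; 15 for biexponential and beta,
including the residual variance) regardless of frame mode.

The initialisation cascade:

1. tensor and DK models: linear least squares on the log-signal (the DK
   design regresses on the frame projections and their squares);
2. stretched exponential: tensor eigenvalues as scales; the stretching
   index starts at 0.99 rather than exactly 1 because a parameter
   initialised exactly on a box bound cannot move when the local
   gradient points outward under projected Levenberg–Marquardt;
3. biexponential: monoexponential fits to b < 1000 and b > 6000 s/mm²
   give fast and slow rates, the volume fraction comes from the two
   intercepts; a noise-dominated high-b segment (slope below
   1e-5 mm²/s) is discarded in favour of eigenvalue-based fallbacks. A
   second deterministic start (fast component at the free-water
   diffusivity 2.3e-3 mm²/s, even split) guards against the model's
   label-switching multimodality; the better sum of squares wins;
4. truncated Gaussian, gamma and beta: moment inversion of the DK fit's
   per-axis mean and kurtosis ($k = 3/K$, $\theta = \bar D K/3$;
   $D_m = \bar D$, $\sigma^2 = \bar D^2 K/3$; beta matched at
   $D_{max} = 2.3\times10^{-3}$ mm²/s, the room-temperature diffusivity
   of free water). Non-positive kurtosis at initialisation falls back
   to $K = 0.01$ with a warning.

Defaults: function/step tolerance $10^{-10}$, 500 iterations, bounds
$D$-like $\in [0, 5\times10^{-3}]$ mm²/s, $a \in (0,1]$, $v \in [0,1]$,
$K \in [0,10]$, shape parameters in $(10^{-6}, 10^{3}]$, $D_{max} \in
[0.5, 5]\times 10^{-3}$ mm²/s. Noiseless single-voxel recovery is exact
to better than $10^{-3}$ relative for every model (most are recovered to
machine precision). The DK model's input data are capped at
b ≤ 5000 s/mm² so the neglected cubic term stays small; for model
comparison its residuals are evaluated on the full common measurement
set, keeping $n$ identical across models — the comparability requirement
of AICc.

## Model selection

$\mathrm{AICc} = n \log \varepsilon^2 + 2P + 2P(P{+}1)/(n{-}P{-}1)$
with the natural logarithm (the standard information-theoretic
convention), and relative likelihood
$p_i = \exp((\mathrm{AICc_{min}} - \mathrm{AICc}_i)/2)$. The b-ceiling
sweep refits every model from scratch at each ceiling (no warm start,
for determinism) and averages RMSE and relative likelihood over ROI
voxels. Best-model maps break AICc ties toward the smaller parameter
count, then lexicographically. Per-voxel (not ROI-pooled) residuals are
used, the only reading consistent with producing maps.

## Noise handling

Magnitude MR data with complex Gaussian noise are Rician-distributed,
and the positive noise floor biases high-b fits. The package removes
the phase of the voxelwise mean of the complex non-diffusion-weighted
images from all measurements and keeps the real channel, restoring
zero-mean Gaussian noise; no spatial smoothing of the reference phase is
applied by default (an optional design extension). Monte-Carlo checks
in the test suite show the resulting monoexponential estimates at SNR 5
and b = 10000 s/mm² carry an order of magnitude less bias than
magnitude-domain fits. The noise level is estimated as the standard
deviation of phase-corrected real values in a signal-free background
(Rayleigh-corrected by $1/\sqrt{2-\pi/2}$ for magnitude backgrounds, or
a Rayleigh-consistent MAD for robustness); the cited original
estimation procedure is not described in the source literature, so this
background estimator is a documented substitute, not a reproduction.

## The phantom generator

`make_phantom()` emulates the study conditions the analysis assumes
rather than any real anatomy: an annular short-axis wall (default
20×20×5 voxels) with a cylindrical local frame, a linear transmural
helix ramp from −60° to +60°, regions of interest of ~247 voxels away
from wall boundaries, per-channel noise SD 243 against a mean non-DW
signal of 2.36×10⁴ (SNR ≈ 97), and q-space schemes on Cartesian
lattices: the half-ball of lattice radius 5 has exactly 257 points and
the symmetric full ball exactly 514 — precisely the two emulated
protocols (δ = 5 ms, Δ = 9 ms, b up to 10,000 s/mm²).

Group-level generating parameters (healthy, sham, TAC) are drawn per
heart from the emulated cohort summaries: biexponential
$D_{fast}, D_{slow}, v$ determine the per-axis mean diffusivity
$\bar D = vD_f + (1-v)D_s$, and the beta-model kurtosis/skewness
triplets supply the shape targets. Per-axis $(\alpha, \beta)$ are
solved exactly from (mean, kurtosis) — feasible iff
$D_{max} > \bar D (3+K)/3$ — while the single shared $D_{max}$ is chosen
to minimise the summed squared skewness mismatch: three moments per
axis are generally unattainable for a two-shape family with one global
ceiling, and the residual is reported. Alternative generating models
(`gaussian`, `gamma`, `biexp`, and a `two_pop` tissue-plus-free-water
partial-volume analogue with the free compartment at 2.3×10⁻³ mm²/s)
exist to probe model selection under misspecification.

What the phantom does **not** emulate: realistic ventricular anatomy,
compartment-specific T2/T1 contrast between tissue and gel, temperature
drift, perfusion, or spatially correlated noise. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative assumptions, not performance on real scans. One concrete
consequence observed in the acceptance suite: on equal-fraction
two-population voxels the beta model (whose bounded support covers the
free-water peak) reaches the noise floor and wins the AICc comparison,
whereas interface voxels in real scans have been reported to prefer the
biexponential; compartment contrast absent from the phantom is the
plausible difference.

## Group statistics

Per-heart ROI means are compared with a two-tailed Mann–Whitney U test,
exact by full enumeration of all $\binom{n_1+n_2}{n_1}$ labelings
(mid-ranks under ties; the two-tailed p doubles the smaller tail,
capped at 1), switching to a tie-corrected normal approximation only
above 24 combined observations. Percent differences are reported under
two conventions — signed $(\bar x_a - \bar x_b)/\bar x_b$ and
magnitude-based — because reported comparisons of negative-valued
skewness are ambiguous between them; no multiple-testing correction is
applied in the primary columns (matching the field's small-cohort
reporting), with a clearly-labelled Holm-adjusted column alongside.

## Problem sizes and reproducibility

The test suite and the acceptance script run phantom analyses at
deliberately modest sizes chosen as this package's own defaults for
desk-scale validation: single-heart ROIs of 12–100 voxels for model
selection and recovery studies, cohorts of 4 hearts × 16 voxels across
5 seeded replicates for group discrimination, 1000 Monte-Carlo
repetitions for the noise-bias comparison. Because significance at
4-vs-4 with the exact Mann–Whitney test requires complete group
separation, single cohort draws fail to separate even the true
sheetlet-normal kurtosis targets in ~15% of replicates; directional
patterns are therefore judged across replicates, not per draw.

A practical subtlety that matters for any per-axis ROI statistic: the
secondary and tertiary eigenvalues of myocardium are nearly equal, so
descending-eigenvalue sorting assigns the sheetlet and sheetlet-normal
axes essentially at random under noise, silently mixing their
parameters in ROI summaries. [relabel_axes_by_frame()] resolves the
identity of axes 2 and 3 against the local radial direction — an exact
symmetry of the factorised forward model, so fits and residuals are
unchanged — and cohort analyses in this package apply it before
averaging. All randomness flows from explicit integer seeds;
`make_phantom()` and `simulate_signals()` are bitwise reproducible for
a fixed spec and seed. `scripts/acceptance.R --seed N --out f.json`
re-derives every reported quantity from scratch.

## Known limitations

* The eigenframe factorisation cannot express orientation-dependent
  mixing (crossing populations); the biexponential product form is not
  an additive two-compartment model.
* The cylindrical wall frame is a stand-in for mesh-based local
  coordinates; near insertion points its circumferential direction is
  a poor guide.
* Joint frame re-optimisation makes the objective non-smooth at
  eigenvalue crossings; ties are resolved by the deterministic
  descending-eigenvalue order.
* The stretched-exponential diffusivity spectrum is not computed (no
  analytic form; numeric inversion is out of scope).

## A worked example

```{r example, eval = FALSE}
scheme <- make_scheme(257)                      # 257 DW + 4 non-DW
spec <- phantom_spec("sham", n_hearts = 1, roi_n = 50)
gt <- make_phantom(spec, seed = 1)
sim <- simulate_signals(gt, scheme, heart = 1, seed = 2)
sig <- corrected_signals(sim)                   # phase-corrected real data

fits <- fit_volume(sig, as.vector(sim$roi_mask), scheme,
                   models = c("dt", "beta"), fit_config(b_max = 10000))
mom <- fit_moments(fits, "beta")
aggregate(mom["kurtosis"], by = list(axis = mom$axis), FUN = median)
```
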