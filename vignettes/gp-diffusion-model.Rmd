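---
title: "A Gaussian-process model of the diffusion MRI signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Gaussian-process model of the diffusion MRI signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwigp)
```

## The model

A diffusion-weighted acquisition measures, per voxel, the MR signal after
diffusion sensitisation of strength $b$ (s/mm$^2$) along a unit direction
$\mathbf{g}$. Viewed as a function of $\mathbf{g}$, the signal lives on the
sphere, varies smoothly, and is *axially symmetric*: the signal along
$\mathbf{g}$ equals the signal along $-\mathbf{g}$. `dwigp` models this
function non-parametrically as a Gaussian process

$$f(\mathbf{x}) \sim \mathcal{GP}\!\left(m(\mathbf{x}),\, k(\mathbf{x}, \mathbf{x}')\right),$$

used purely predictively: conditioned on a voxel's measurements, the GP
yields the expected signal (and its uncertainty) at any (direction, b-value)
point. This is the engine behind model-free motion/distortion correction and
outlier replacement: a predicted volume is a registration or replacement
target that does not depend on any biophysical model of the tissue.

### Covariance on the sphere

Distance between measurement directions is the angle between *axes*, not
vectors:

$$\theta(\mathbf{g}, \mathbf{g}') = \arccos\lvert\mathbf{g}\cdot\mathbf{g}'\rvert \in [0, \pi/2],$$

which bakes the axial symmetry into the kernel (and hence into every
prediction — it holds to machine precision, not approximately). Two
geostatistical ("Kriging") covariance models are provided:

* exponential: $C(\theta) = e^{-\theta/a}$;
* spherical: $C(\theta) = 1 - \frac{3\theta}{2a} + \frac{\theta^3}{2a^3}$
  for $\theta \le a$, and exactly $0$ for $\theta > a$.

Both are valid (positive-definite) covariances on the sphere for any scale
$a > 0$; we deliberately do not clamp $a$ at $\pi/2$. The angular scale $a$
(radians) sets how fast covariance decays with angle; the signal-variance
scale $\lambda$ sets how much the signal varies at all. The spherical model
has compact support — beyond $a$ the covariance is identically zero — and on
real diffusion data it is overwhelmingly preferred by the evidence
comparison below; Bayes-factor model selection between the two is built in.

### Multiple shells

Multi-shell protocols acquire several non-zero b-values. Signal shapes on
nearby shells are similar, so the kernel is extended as a product:

$$k(\mathbf{x}, \mathbf{x}') = \lambda\, C_\theta(\theta; a)\,
C_b(b, b'; \ell), \qquad
C_b = \exp\!\left(-\frac{(\log b - \log b')^2}{2\ell^2}\right),$$

with one extra length scale $\ell$ on the log-b axis and one noise variance
$\sigma_s^2$ per shell ($3 + N$ hyperparameters for $N$ shells; a
single-shell model has exactly 3). Log-b distance makes the coupling scale
free. Within a shell $C_b \equiv 1$, so a one-shell "multi-shell" model
reduces bitwise to the single-shell model. Data on one shell thereby informs
predictions on another — strongly for neighbouring b-values, weakly for
distant ones — which `shell_subsample_experiment()` quantifies.

### Prediction

With training kernel matrix $K$, noise $\Sigma$ (per-shell $\sigma_s^2$ on
the diagonal) and observations $\mathbf{f}$,

$$\hat f(\mathbf{x}_*) = \mathbf{k}_*^\top (K + \Sigma)^{-1}
(\mathbf{f} - \bar{\mathbf{f}}) + \bar f_{s(\mathbf{x}_*)}, \qquad
\mathrm{Var}[\hat f(\mathbf{x}_*)] = k_{**} - \mathbf{k}_*^\top
(K + \Sigma)^{-1} \mathbf{k}_*.$$

The mean is removed per shell and the queried shell's mean restored
(shells differ grossly in mean attenuation; a pooled mean would bias
cross-shell prediction — for queries at b-values away from every training
shell the restored mean is interpolated linearly in log-b and the output
flagged). The weights do not depend on the observed values, so one Cholesky
factorisation of $K + \Sigma$ is shared across all voxels and per-voxel
work is a single triangular solve — prediction is a fast linear operation.
With $\sigma^2 = 0$ the GP interpolates the training points exactly.
`predict_volume()` predicts a whole volume either with the observed volume
in the training set (*smoothing*) or without it (*interpolation*); the
excluded-volume mode rebuilds the reduced system rather than down-dating
the factorisation — simplicity wins at these problem sizes.

## Hyperparameter estimation

One hyperparameter vector $\beta = (\lambda, a, [\ell], \sigma_1^2, \dots)$
is shared by all voxels. It maximises the summed log marginal likelihood
(type-II maximum likelihood)

$$\log p(\mathbf{y} \mid \beta, M) =
-\tfrac12 \mathbf{y}^\top K_y^{-1} \mathbf{y}
-\tfrac12 \log\lvert K_y\rvert - \tfrac n2 \log 2\pi,
\qquad K_y = K + \Sigma,$$

summed over voxels (by default a seeded random subset of 1000 voxels —
hyperparameters are global, a sizeable subset suffices). The additive
constant is fixed at $-\frac n2 \log 2\pi$ so values are genuine Gaussian
log densities, comparable across $n$. Leave-one-out alternatives are
available: CV (mean squared LOO residual) and GPP (mean LOO log predictive
density), both computed with the closed-form LOO identities from the
inverse-kernel diagonal — residual $\alpha_i / [K_y^{-1}]_{ii}$, variance
$1/[K_y^{-1}]_{ii}$ — and verified in the test suite against literal
refit-without-point-$i$ oracles. A third LOO criterion sometimes seen in
this literature (predictive mean squared error, GPE) is intentionally not
implemented.

Positive parameters are optimised as exponentials of unconstrained
coordinates ($\lambda = e^u$, etc.), which rules out negative scales or
variances. The optimiser is the Nelder–Mead simplex — on the multi-shell
surface it avoids local maxima better than gradient methods — run from an
automatic start ($a = 1$ rad, $\lambda$ = pooled demeaned-signal variance,
$\sigma^2 = 0.1\lambda$, $\ell = 1$), optionally with seeded log-normal
restarts. Convergence uses a relative objective tolerance of $10^{-8}$
(about $10^{-4}$ nats at typical objective magnitudes) with at most $200d$
iterations.

### Numerical choices

* $K_y$ is factorised once per (scheme, hyperparameters) and reused; no
  explicit inverses anywhere on the main path.
* If the factorisation fails (e.g. duplicated directions with near-zero
  noise), a jitter of $10^{-10}\overline{\mathrm{diag}(K_y)}$ is added and
  the factorisation retried once with a warning; a second failure is an
  error reporting the smallest eigenvalue.
* Dot products are clipped to $[-1, 1]$ before $\arccos$; the self-angle is
  set to exactly zero so $\mathrm{diag}(K) = \lambda$ holds exactly.
* Predictive variances negative by less than $10^{-9}\lambda$
  (floating-point cancellation) are clamped to zero with a warning; larger
  negativity is an error.
* Prior-shape sampling factorises $K$ (which carries no noise term) with a
  relative jitter of $10^{-12}\lambda$.

## Model comparison

The evidence $p(\mathbf{y} \mid M) = \int p(\mathbf{y} \mid \beta, M)\,
p(\beta \mid M)\, d\beta$ is approximated by Laplace's method around the
type-II ML point $\hat\beta$ (in unconstrained coordinates):

$$\log p(\mathbf{y} \mid M) \approx L(\hat\beta) + \tfrac d2 \log 2\pi
- \tfrac12 \log\lvert -H \rvert,$$

with $H$ the Hessian of the summed log marginal likelihood at $\hat\beta$,
estimated by central finite differences (relative step $10^{-3}$,
symmetrised — a balance of truncation against cancellation when each
objective call costs one factorisation). A flat improper prior over the
unconstrained log-parameters is assumed, the only construction consistent
with centring the Gaussian approximation on the likelihood maximum without
further prior information; evidences are therefore comparable between
models with equal $d$, and Bayes factors between the spherical and
exponential models (same $d$) are well defined. A Hessian that is not
negative definite flags the result invalid rather than silently producing a
number. The approximation is exact for quadratic log-objectives and, in the
tests, agrees with brute-force quadrature within 0.5 nats on a
1-hyperparameter problem.

## The synthetic data generator

No scanner data ships with the package; every claim is validated on
synthetic signals whose ground truth is known.

* `make_scheme()` builds acquisitions with directions drawn uniformly or
  spread by electrostatic repulsion of antipodally symmetrised points (the
  layout of real protocols). Repulsion uses capped-step tangent descent so
  near-coincident pairs cannot overshoot.
* `simulate_voxel()` implements the multi-tensor compartment model
  $S(\mathbf{g}, b) = S_0 [\sum_i f_i e^{-b\,\mathbf{g}^\top D_i \mathbf{g}}
  + f_{\mathrm{iso}} e^{-b\,d_{\mathrm{iso}}}]$ with axially symmetric
  tensors — axially symmetric and monotonically decaying in $b$ by
  construction. Default diffusivities are textbook human-brain magnitudes:
  axial $1.7\times10^{-3}$, radial $0.2\times10^{-3}$, grey matter
  $0.8\times10^{-3}$, CSF $3.0\times10^{-3}$ mm$^2$/s; $S_0 = 1000$.
* `make_phantom()` assembles voxel populations (single fibre, two- and
  three-way orthogonal crossings at volume fractions 0.8, 0.45+0.45 and
  0.3×3, grey matter, CSF) with per-voxel orientation jitter (sd 0.1 rad)
  and Gaussian or Rician noise. Rician is the magnitude-MR default;
  Gaussian is used in parameter-recovery tests because it is the GP's own
  error model.

What the generator does *not* emulate: eddy-current and susceptibility
distortions, motion, signal dropout, spatially correlated noise, or any
pulse-sequence physics. Passing tests therefore demonstrate correctness of
the GP machinery under its own assumptions plus robustness to multi-tensor
(non-GP) signal structure — not performance on artefact-laden scanner data.

### Problem sizes used in the validation suite

The test suite validates exact identities on small instances (explicit
MVN conditioning at $n \le 10$; naive LOO refits at $n \le 8$) and
statistical behaviour at realistic scale: parameter recovery uses 120
directions × 500 voxels; model recovery 20 replicates × 2 generating models
at 60 directions × 500 voxels; the cross-shell borrowing experiment two
300-direction shells (b = 3000/5000); prior-shape statistics 50,000 draws.
These sizes were chosen to make Monte-Carlo margins comfortable while a
full run stays interactive on one core.

## Known limitations

* Type-II ML on *misspecified* voxels (sharply structured multi-tensor
  signal, sparse angular sampling) can drive $\sigma^2$ toward zero,
  absorbing noise into $\lambda$: the rough (non-differentiable at zero)
  angular kernels can mimic white noise at coarse sampling. With dense
  protocols (~300 directions) the fitted GP's leave-one-out RMSE approaches
  the injected noise level (within ~15% in the suite); at 40–60 directions
  it does not, and the leave-one-out criteria (CV/GPP) are the safer choice
  there.
* Hyperparameters are global per data set; per-voxel or spatially varying
  hyperparameters are out of scope, as are inter-voxel (spatial)
  covariances.
* Gradient directions are taken in the image frame as stored; no
  reorientation by the NIfTI affine is attempted. Sign flips are harmless
  under axial symmetry; axis permutations are the caller's responsibility.
* Evidence values rest on the flat-prior Laplace construction above;
  their absolute magnitudes are not comparable across data sets, only
  between models fitted to the same voxels.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
scheme <- make_scheme(c(64, 64), c(1500, 3000), n_b0 = 2, seed = 1,
                      method = "repulsion")
phantom <- make_phantom(25, c("wm1", "wm2_crossing", "gm"), scheme,
                        noise = noise_spec("gaussian", 15), seed = 2)

Y <- t(matrix(phantom$volumes, prod(dim(phantom$volumes)[1:3]),
              length(scheme$bvalues))[which(phantom$mask),
                                      scheme$dwi_index])
spec <- objective_spec(Y, scheme, model = "spherical", criterion = "ml")
fit <- fit_hyperparameters(spec, seed = 3)
fit$hyper

pred <- predict_volume(phantom$volumes, scheme, fit$hyper,
                       target_index = 10, mode = "interpolation",
                       mask = phantom$mask)
```
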