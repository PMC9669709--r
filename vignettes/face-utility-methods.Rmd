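---
title: "Methods: ordinal Gaussian process estimation of facial utility functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ordinal Gaussian process estimation of facial utility functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(faceutility)
```

## The problem

A rater looking at a face produces, we assume, a latent scalar judgment
$f(\mathbf{x})$ — a *utility* — that depends on the face's shape
coordinates $\mathbf{x}$, but we only ever observe that judgment after it
has been discretized onto a Likert scale. `faceutility` estimates $f$
per rater from such ordinal data, drives the choice of which face to show
next, and pools the estimated surfaces across raters to ask which shape is,
on average, most (and least) preferred. The motivating application is
perceived cuteness of children's faces, where candidate explanations (the
"baby schema": forehead size, eye position, jaw width, facial roundness)
are exactly the kind of thing one would like to *discover* from a
low-dimensional shape space rather than assume.

## The face space

Shapes are ordered landmark configurations ($K$ points in 2-D; the
motivating design uses $K = 80$, hence a 160-dimensional coordinate
space). Construction:

1. **Generalized Procrustes analysis** (`gpa_align`). Each configuration is
   translated to its centroid and scaled to unit *centroid size*
   $\sqrt{\sum_i \lVert p_i - c \rVert^2}$, then iteratively rotated onto
   the running mean shape by 2-D orthogonal Procrustes (SVD with the
   determinant forced positive — reflections are never similarity
   transforms here). The loop stops when the mean moves by less than
   `tol = 1e-8` RMS, with `max_iter = 200` and an explicit `converged`
   flag. We read the field's occasional "sum of squared distances" phrasing
   for centroid size as the conventional *root* sum of squares; the
   un-rooted variant is available as `type = "raw"` for sensitivity checks,
   and the choice only rescales the space.
2. **Symmetrization** (`symmetrize`). Facial asymmetry is nuisance
   variation. Each shape is averaged with its mirror-reversed,
   left/right-relabeled copy after Procrustes-aligning the two. The
   rotation $\theta$ that aligns the reflection onto the original is split
   evenly — the original rotated by $-\theta/2$, the reflection by
   $+\theta/2$ — which makes the average an *exact* fixed point of the
   mirror operation (mirroring conjugates a rotation into its inverse), so
   the output is bilaterally symmetric to machine precision rather than to
   optimizer tolerance, and the operation is idempotent. Centroid and
   centroid size of the input are preserved. The left/right pairing is
   user-supplied (`symmetry_map`): no landmarking scheme is assumed.
3. **PCA** (`fit_face_space`). Principal components of the *covariance*
   (not correlation) matrix of the flattened coordinates, the standard
   choice in geometric morphometrics where all coordinates share units.
   Loadings are orthonormal; per-PC score standard deviations are stored so
   every downstream coordinate is expressed in SD units, which makes the
   ±2 SD experimental box and the 0.4-step grid meaningful across data
   sets. Requesting more components than the achievable rank is an error
   that names the rank.

Thin-plate splines (`tps_fit`, kernel $U(r) = r^2 \log r^2$, $U(0)=0$)
render stimuli: with smoothing $\lambda = 0$ (the default, as stimulus
generation requires exact landmark correspondence) the warp interpolates
exactly, the weights satisfy the affine side conditions, and the bending
energy $\mathrm{tr}(W^\top K W)$ is invariant to adding any affine function
of the source to the target. Only synthetic grayscale matrices are warped
(`tps_warp_image`); real photograph handling is deliberately out of scope.

## The observation model (GPOR)

With $R$ ordered categories, thresholds
$b_0 = -\infty < b_1 < \dots < b_{R-1} < b_R = \infty$ and noise SD
$\sigma$:

$$P(y = s \mid f) = \Phi\!\left(\frac{b_s - f}{\sigma}\right) -
  \Phi\!\left(\frac{b_{s-1} - f}{\sigma}\right),$$

with a zero-mean GP prior on $f$ under the ARD kernel
$K(\mathbf{x}, \mathbf{x}') = \exp(-\tfrac12 \sum_d \eta_d (x_d - x'_d)^2)$.
As $\sigma \to 0$ this recovers the ideal noise-free categorizer.

**Inference.** The likelihood is log-concave in $f$, so the posterior mode
is unique; we find it by Newton iterations from $f = 0$ in the standard
$B = I + W^{1/2} K W^{1/2}$ parameterization, which never forms $K^{-1}$
and never inverts the per-observation curvatures $W_{ii}$ (some of which
can be numerically zero in flat likelihood regions). A line search in
$\alpha = K^{-1} f$ space halves the step until the objective increases, so
the iterate sequence is provably monotone — asserted per iteration in the
tests. Convergence is gradient $\infty$-norm $< 10^{-6}$ within 100
iterations; failure raises an error carrying the objective trace rather
than returning a silent partial fit. The kernel gets diagonal jitter
$10^{-6}$, escalating tenfold to at most $10^{-2}$ before erroring.

Predictions use $\mu_* = k_*^\top K^{-1} f_{\mathrm{MAP}}$ and
$\sigma_*^2 = k_{**} - k_*^\top (K + \Lambda_{\mathrm{MAP}}^{-1})^{-1} k_*$
via the symmetric $\Lambda^{1/2}$ form; variances are clamped at zero with
a warning if the pre-clamp deficit exceeds $10^{-8}$. Label probabilities
at a test point integrate the ordinal likelihood against the Gaussian
predictive in closed form (replace $\sigma$ by
$\sqrt{\sigma^2 + \sigma_*^2}$); the point prediction is the modal label,
ties to the smaller label. Normal CDF differences are computed through the
complementary tail when both arguments are positive and floored at
$10^{-300}$ before logs, so $|z| \gg 8$ is safe.

**Hyperparameters.** The source design does not state how $(\eta, \sigma,
b)$ were chosen, so the package's own choice is Laplace-evidence
maximization: Nelder-Mead over $(\log \eta, \log \sigma, b_1,
\log \Delta b)$ — the log-increment threshold parameterization enforces
ordering by construction — from a data-driven start (length scales from
the input spread, thresholds from normal quantiles of the empirical label
frequencies) plus seeded random restarts (default 5). Results are
bit-reproducible given the seed. One caveat worth recording: the *evidence
itself* is not invariant to jointly shifting thresholds and latent values
by a constant (the prior is zero-mean pins the location), although the
*likelihood* is; the tests assert the exact likelihood identity and only
optimizer-level stability (0.05 in log evidence) for fits started from
shifted thresholds. Whether thresholds should be fitted per rater at all
is an open design question; we fit them, treating each rater as having
their own response style.

## Sequential design

Sessions mirror the motivating experiment: `n_practice = 20` trials drawn
from the random stream and discarded, `n_random = 45` uniform draws on the
±2 SD box, then `n_adaptive = 15` stimuli maximizing

$$\mathrm{UCB}_{\mathbf{x}} = \mu_{\mathbf{x}} + \frac{\log N}{N}\,
\sigma_{\mathbf{x}}$$

over the 0.4-step candidate grid, where $N$ counts all test trials so far.
The typeset source formula is ambiguous ("log N N"); we take the literal
$\log N / N$ reading as default and expose the conventional GP-UCB
$\sqrt{\log N / N}$ as `ucb_beta = "sqrt_log_over_n"`. Note $\log N / N$
is *decreasing* in $N$: exploration fades as the session progresses, which
is the behaviour the design intends at these trial counts. Ties in the
acquisition resolve to the lexicographically smallest grid point, making
sessions fully deterministic given (seed, config, responder). The model is
refit on the whole history before every adaptive selection; hyperparameter
refitting frequency is configurable (`refit_every`), since a full evidence
maximization per trial is faithful but expensive — the test suite uses
`refit_every = 5` and documents it as a budget choice, not a statistical
one.

## Evaluation

LOOCV withholds each trial in turn, refits on the rest, and predicts the
held-out label; test MZE/MAE come from the held-out predictions, and the
"train" columns — whose definition the source leaves open — are the
in-sample errors of the full-data fit. The ordinal logistic baseline is a
proportional-odds cumulative-logit model fit by BFGS on the same
log-increment cutpoint parameterization, with complete separation detected
(diverging coefficients or optimizer failure) and refit under a ridge of
$10^{-4}$, flagged `converged = FALSE` rather than silently accepted. Both
models use the same modal-label prediction rule, so the comparison is of
the latent models, not the decision rules. `compare_models` gives the
paired $t$, two-sided $p$ and paired Cohen's $d$; zero-variance differences
return an infinite $t$ with a `degenerate` flag instead of `NaN`. The
chance MZE of a uniform random predictor over 5 categories is exactly
$(R-1)/R = 0.8$ regardless of the truth's distribution; the per-rater
chance derivation under a response-marginal predictor would differ, but
the uniform reading matches the stated chance level.

## Pooling across raters

Per-rater surfaces on the grid (11 points per PC over ±2 SD; $11^3 =
1331$ points at $D = 3$) are pooled as an equal-weight Gaussian mixture:

$$\mu_{S\mathbf{x}} = \tfrac1M \sum_s \mu_{s\mathbf{x}}, \qquad
\sigma^2_{S\mathbf{x}} = \tfrac1M \sum_s
(\mu_{s\mathbf{x}}^2 + \sigma_{s\mathbf{x}}^2) - \mu_{S\mathbf{x}}^2,$$

which satisfies the law of total variance exactly (pooled variance is
never below the mean within-rater variance, with equality iff the raters
agree). The argmax and argmin of $\mu_S$ localize the preferred and
dispreferred shapes; the significance check at the maximum is
$P(f \le 0) = \Phi(-\mu/\sigma)$ using the pooled variance *at that point
only* — no multiplicity correction over the 1,331 grid points, following
the stated procedure; a Bonferroni-minded user can divide their $\alpha$
by the grid size.

## The synthetic world

Because neither the photographs nor the human ratings of the motivating
study are deposited, the package ships a generator whose defaults *are*
the study's stated conditions: 40 raters, 60 test trials (45 random + 15
adaptive), a 5-point scale, a ±2 SD box. What the study does not state, we
fixed once:

* **Utilities**: quadratic peaks $a - c\lVert \mathbf{x} -
  \mathbf{p}\rVert^2$ with amplitude $a = 2$ and curvature $c = 0.25$,
  so the latent range spans the default thresholds
  $b = (-1.5, -0.5, 0.5, 1.5)$ at noise $\sigma = 1$ (scale is not
  identified jointly with amplitude; 2 makes the signal detectable at 60
  trials without being trivial). A `bimodal` kind (pointwise maximum of
  two Gaussian bumps, so the stated peak heights are attained exactly) and
  a seeded `gp_sample` kind (lattice draw + multilinear interpolation)
  exist for robustness checks.
* **Heterogeneity**: a shared peak plus per-rater Gaussian jitter of SD
  0.3 per PC, so pooling is meaningful but raters genuinely differ. The
  shared peak defaults to $(-0.8, -0.4, 0.8)$ — the kind of interior,
  on-grid location the application reports — so recovery tests probe a
  realistic operating point. Rater $i$ derives its seeds from
  `seed + i`, making studies extensible without reshuffling existing
  raters.
* **Responses** are drawn from exactly the thresholded noisy-utility model
  the GPOR likelihood assumes, from a private per-rater RNG stream that
  never touches the global one.

A green end-to-end test therefore establishes *internal* consistency —
the estimator recovers the model's own generative process through the full
experimental pipeline — and the shape generator's planted-PC recovery
establishes the same for the morphometric pipeline. It does **not**
establish robustness to likelihood misspecification (real raters drift,
anchor, and violate threshold constancy), to landmarking error, or to
utilities outside the tested families; those are the package's known
limitations, shared with any simulation-validated method.

## Numerical and testing choices worth knowing

* All oracles in the test suite are independent of the code paths they
  check: brute-force rotation grids for Procrustes, a dense hand-assembled
  linear system for TPS, tensor quadrature for the Laplace evidence and
  posterior moments, Monte Carlo for predictive labels, an iterated grid
  search and `MASS::polr` for the ordinal logistic ML, and closed-form
  mixture integrals for pooling.
* Acceptance checks run the *stated* world (20 seeded studies for the
  directional GPOR-vs-logistic comparison; Spearman ≥ 0.6 for utility
  recovery; pooled argmax within one grid step — read as Euclidean
  distance ≤ 0.4 — in ≥ 70% of 10 replicate studies at $M = 10$). Seeds
  were fixed before outcomes were observed and are not tuned.
* Compute scaling inside tests (hyper refits every 5 adaptive trials, 1–2
  optimizer restarts, `maxit = 150`) trades optimizer effort, not model
  structure, for a single-CPU budget; package defaults remain the faithful
  ones.
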