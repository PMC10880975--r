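---
title: "Dynamic predictive coding with dpcnet: model, inference, and experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic predictive coding with dpcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dpcnet)
```

## The generative model

`dpcnet` implements a two-level (optionally three-level) hierarchical
generative model of grayscale image sequences. At the bottom, each frame
`I_t` (a vectorized `H x W` image, `M = H * W` pixels) is a noisy linear
image of a sparse latent state:

    I_t | r_t  ~  N(U r_t, sigma2 I),          r_t in R^N

with spatial filters in the columns of `U` (unit L2 norm, as in sparse
coding). The temporal dynamics of `r_t` are a *mixture of K learned linear
transition matrices* passed through a rectifier:

    w    = H_theta(r_h)                (hypernetwork, w in R^K)
    V    = sum_k w_k V_k
    r_t | r_{t-1}, r_h  ~  N(ReLU(V r_{t-1}), sigma_r2 I)

The higher-level state `r_h ~ N(0, I)` does not generate single frames; it
generates *the dynamics of the whole sequence* via the modulation weights
`w`. This is the model's central hypothesis: top-down feedback acts as
gain modulation on the lower level's recurrent connectivity, so a slow,
sequence-level variable (e.g. "rightward drift") controls a fast,
frame-level code. The hypernetwork `H_theta` is a two-layer perceptron
(one tanh hidden layer, linear K-dimensional output); this is the smallest
architecture that is a genuine hypernetwork, and its width is
configurable (`dpc_shape(hidden = ...)`).

Latent states are unconstrained reals; the rectifier appears only inside
the transition mean. The ReLU subgradient at 0 is taken to be 0
everywhere.

## MAP inference as prediction-error minimization

Perception in the model is per-step MAP estimation (Bayesian filtering
with the previous posterior collapsed to a point mass). At step `t` the
network minimizes

    L_t = 1/(2 sigma2)   ||I_t - U r_t||^2
        + 1/(2 sigma_r2) ||r_t - r_bar_t||^2
        + lambda ||r_t||_1 + lambda_h ||r_h||^2,

where `r_bar_t = ReLU(V(r_h) r_hat_{t-1})` is the top-down temporal
prediction. `infer_step()` descends this loss jointly in `r_t`
(warm-started at `r_bar_t`, proximal soft-thresholding for the L1 term)
and `r_h` (warm-started at its carried estimate), re-evaluating
`r_bar_t` at the current `r_h` so that prediction errors flow upward. The
first step of a sequence uses the reduced loss without temporal or prior
terms (`infer_first_step()`, descent from the zero vector). An
alternating update schedule (`joint = FALSE`) is available; we found no
qualitative difference and default to simultaneous steps.

Step sizes default to `lr_r = 0.05`, `lr_rh = 0.01`, with an iteration
cap of 300 and an max-abs-change tolerance of `1e-5` per inner loop;
user-facing calls backtrack (halve both step sizes when a step would
increase the loss), which guarantees a non-increasing recorded loss.
Batched filtering (`filter_dataset()`), used inside training and the
large experiments, advances all sequences in lock-step with fixed step
sizes — the per-sequence and batched paths are verified against each
other in the test suite.

## Learning

`train_two_level()` alternates batched MAP filtering of a minibatch with
one Adam update of `U`, `{V_k}` and `theta` on the gradient of the summed
per-step losses at the MAP latents, then renormalizes the columns of `U`
to unit norm (removing the usual sparse-coding scale degeneracy; the
transition matrices and hypernetwork are unconstrained).

Two numerical choices matter and were made once, during the
teacher–student calibration of the package:

* **Hypernetwork initialization.** The output bias starts at `1/K`
  (weights small), so the initial mixed dynamics are the mean of the
  transition matrices. Initializing the output at zero is a saddle point:
  the gradient of each `V_k` is proportional to `w_k`, and the gradient
  of the hypernetwork input weights is proportional to the (initially
  zero) higher-level state, so nothing moves.
* **Noise-variance ratio.** The observation and transition variances are
  free hyperparameters (we treat pixel scales of order 1). Defaults are
  `sigma2 = 0.1`, `sigma_r2 = 1`, `lambda = 0.01`, `lambda_h = 0.001`.
  If the temporal term is weighted much more strongly than the
  reconstruction term, early in training inference is dragged toward the
  (still meaningless) top-down prediction, the latents stop explaining
  the input, and learning converges to a degenerate solution; with the
  reconstruction term dominant, the teacher–student protocol reaches
  held-out one-step prediction R² close to the teacher's own.

Held-out prediction quality is scored by `prediction_r2()` from step 3
onward: the filter needs the first two frames to identify a sequence's
dynamics (the model's own prediction errors are largest there), so
earlier steps measure adaptation, not the learned model.

## Synthetic stimuli

All experiments run on generated data; every generator is a pure function
of its spec and seed.

* `make_moving_sprites()` — one of eight drawn glyphs (bars, cross,
  diagonal cross, ring, blob, L, T) translating in a bounded 18 x 18
  arena, 10 frames, one of four cardinal directions, fixed speed
  2 px/frame, reflecting at boundaries (straight rule: left/right and
  up/down invert). The glyph bank stands in for handwritten digits so the
  package ships no external data; speed 2 makes a 10-frame sequence
  typically contain 1–2 bounces, matching the intended regime of
  occasional dynamic changes. Direction changes on the frame where the
  next step would cross the boundary (reflect-before-exit), so sprite
  mass is conserved in every frame.
* `make_bouncing_dataset()` — 20-frame sequences guaranteed to contain at
  least two bounces, under the straight or the clockwise rule (left→up,
  up→right, right→down, down→left; when the rotated direction would
  leave the arena — a corner — the rotation cascades once more).
* `make_white_noise()` — i.i.d. `N(0, 0.0075)` pixels, the stimulus used
  to probe response timescales independently of stimulus correlations.
* `make_drifting_surrogate()` — band-pass noise textures drifting with
  per-sequence constant velocity (continuous direction, exact Fourier
  shifts), then whitened. These emulate the statistics of short natural
  movie patches (stable dynamics within a sequence) for users without
  access to natural video; they do not contain occlusions, contrast
  nonstationarity, or the heavy-tailed structure of real movies, so
  results on them demonstrate mechanism, not natural-scene performance.

`whiten_sequences()` implements the retina/LGN-style preprocessing used
for natural input: per-frame frequency-domain filtering with the
amplitude profile `|f| exp(-(f/f0)^4)` (`f0 = 0.8` Nyquist by default),
followed by a first-order temporal decorrelation filter
(`y_t = x_t - 0.8 x_{t-1}`). The ramp removes DC, so whitened sequences
are approximately zero-mean, and the whole operation is linear. Note the
filter *flattens 1/f-amplitude input*; feeding it already-white input
produces a ramp-shaped spectrum by construction.

## Response analyses

* `compute_strf()` implements reverse correlation: the response-weighted
  average of the preceding `tau = 7` stimulus frames, averaged over time
  and sequences; it equals the naive triple loop exactly (tested). The
  response used is the post-correction MAP estimate. Desk-scale defaults
  probe fewer and shorter noise sequences than a full physiology-style
  mapping; both are configurable. `collapse_strf_xt()` produces space–time
  maps by summing over the spatial axis whose marginal profile varies
  least across lags (ties prefer collapsing Y).
* `response_autocorrelation()` normalizes each neuron/trial series by its
  own variance so that `rho(0) = 1` before averaging. The normalization
  uses the standard deviation (the square root of the mean squared
  deviation); normalizing by the raw mean-square-deviation would not give
  `rho(0) = 1` for unit-free curves. Zero-variance series are excluded
  with a reported count. `fit_exponential_decay()` fits
  `a exp(-k/tau) + b` by separable least squares over a `tau` grid
  (seeded at 0.5, 1, 2, 5, 10) with a Levenberg–Marquardt polish; a flat
  curve returns `a = 0` with `tau` flagged unreliable rather than an
  error.
* `crossval_decode()` is a stratified k-fold RBF-kernel SVM with default
  regularization; chance is the majority-class count in each test fold
  divided by the fold size.

## The experiments

**Temporal hierarchy.** After training on 2,000 sprite sequences
(N = 64, N_h = 16, K = 5, hidden width 32; 6 epochs of Adam at 5e-3,
minibatch 200, 25 inner iterations per step), the fitted autocorrelation
timescale of the higher level exceeds the lower level's both on held-out
sprites and on white noise (J = 100 sequences of 50 steps — a desk-scale
reduction of the reference protocol of 500 trials).

**Factorization.** Decoding features are the time-averaged lower-level
response (content lives in every frame) and the final higher-level
estimate (dynamics are a sequence-level quantity). Motion direction
decodes better from `r_h`, sprite identity better from `r` — the
inequality structure, not the absolute accuracies, is the claim.

**Flash-lag.** Five-frame windows of consistent horizontal motion are
extracted; the higher-level state is either inferred from the first three
frames or zeroed; the probe frame at the fourth step either continues,
stops, reverses, or disappears. The percept is the corrected top-down
prediction `U ReLU(V(r_h) r_hat_2)` and its location the positive-rectified
center of mass (percepts may contain negative pixels; rectification keeps
the location well defined; an all-nonpositive percept is flagged rather
than located). The displacement sign convention follows the moving
object's original trajectory. The latency sweep probes the *optimization
trajectory* of the higher-level correction on reversed trials: it uses a
deliberately fine probe (lr_rh = 5e-4, 1000 iterations, no early stop) so
that "10% of iterations" resolves the early, prediction-dominated phase;
with a coarse probe the correction converges before the first probe point
and the early percept is already postdictive. Fraction 0 is the pure
extrapolation; fraction 1 equals running the step to its cap.

**Episodic memory.** The memory matrix `G` ((N + N_h) x P, P = N + N_h)
binds `s = [r_0; r_h]` through a ridge-regularized predictive-coding
objective (`lambda_m = 0.1`). Conditioning performs 5 repetitions of
inference-plus-Hebbian update with the DPC network frozen; the update
step defaults to the exact minimizing step for the quadratic storage
objective (`eta_G = NULL`), a Newton-style choice that removes a scale
hyperparameter; a fixed small rate (0.01) is available. Recall from a cue
masks the dynamics block (prediction errors on the missing observation
are ignored — robust predictive coding) and reads `r_h` out of the
top-down prediction. Before conditioning, `G` has entries of scale 1e-3
so recall is near-null. The cross-correlation analysis relates pairwise
response peak lags to RF distances projected on the motion direction; the
reported signature is that the peak-lag-versus-distance slope increases
from before to after conditioning (the per-pair slope is more stable at
T = 5 rollouts than re-peaking the binned difference correlogram, which
is also returned).

**Three-level extension.** The second level gains K2 = 2 transition
matrices and a second hypernetwork driven by `r^(3)`; a second-level
transition is *gated*: it happens only at steps whose first-level
prediction error exceeds a threshold `rho` (the terminal-state analogy —
the lower level "completing" a subsequence). `rho` is the 0.75 quantile
of training-set errors. Gating uses the *relative* error
`||I - U r_bar|| / max(||I||, 1)`: one absolute threshold cannot work
across sprites of different contrast and size. When the gate is off, the
second-level prediction target is an identity hold (`r_bar2 = r2_{t-1}`),
the minimal reading of transitions-only-at-flagged-steps; with the gate
forced off and the Gaussian penalty reinstated on `r^(2)`, the
three-level filter reproduces the two-level filter exactly (tested).
`r^(3)` starts at zero, persists across the sequence, and is corrected
only through gated second-level errors; the Gaussian prior penalty is
applied to `r^(3)` only. The two `V^(2)` matrices are pretrained per
bounce type on gated transitions of the two-level filter's second-level
estimates, then the second hypernetwork is trained on the mixed corpus.
Decoding features for the hierarchy comparison are the *final-step*
modulation weights: whole `w^(1)` time courses would reveal the bounce
type through the direction sequence itself and blur the level separation
the comparison is meant to expose.

## Problem sizes and runtime

All experiment scales in the tests and in `scripts/acceptance.R` were
chosen as desk scale: sprite studies use 2,000 training sequences
(N = 64), the bouncing corpus 1,200 sequences of 20 frames, the
teacher–student corpus 1,000 sequences (generalization of the learned
dynamics keeps improving well past a few hundred sequences), held-out
sets of 100–300 sequences, 5 seeded repetitions for the stochastic
properties, and reverse-correlation/autocorrelation probes of 100 noise
sequences. These reproduce the structural signatures (orderings,
inequalities, sign flips) rather than any printed accuracy of a
full-scale run on natural video or handwritten digits, which would
require the external media the package deliberately does not ship.

## Known limitations

* Mixture-of-linear-maps dynamics with a rectifier can become unstable if
  training drives the mixed spectral radius above 1; the Adam learning
  rate and the near-identity transition initialization were chosen to
  stay in the stable regime, and divergence raises an explicit error
  naming the learning rate.
* The generative `r_0` prior (standard normal) is a modeling convenience;
  inference regularizes `r_0` only through the L1 penalty.
* Checkpoints and datasets persist via an R-native serialization with an
  explicit schema-version string (`save_dpc()`/`load_dpc()`); arrays
  round-trip bit-exactly, and mismatched schema versions raise a typed
  error.
* The CLI (`run_cli()`, with a thin Rscript wrapper in
  `inst/scripts/dpcnet-cli.R`) writes CSV tables and RDS artifacts plus a
  JSON manifest per run; figures are left to the user's plotting
  environment.
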