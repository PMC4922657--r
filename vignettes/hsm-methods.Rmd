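---
title: "Methods: population receptive-field estimation with hierarchical structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population receptive-field estimation with hierarchical structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model and its assumptions

`hsmrf` estimates the stimulus–response mapping of a local population of
V1 neurons under a structural assumption taken from the anatomy of the
early visual pathway: all `s3` recorded neurons are driven, directly or
through one intermediate stage, by a *small shared pool* of `s1`
thalamic-like inputs. Each LGN unit is a difference-of-Gaussians (DoG)
kernel with six parameters — center `(mu_x, mu_y)` in continuous pixel
coordinates, center and surround widths `sigma_c`, `sigma_s` in pixels,
and center/surround weights `alpha`, `beta`. The two cortical stages are
fully connected linear integrators with a softplus transfer
`f(x) = log(1 + exp(x - t))`, one threshold `t` per unit. The transfer is
smooth, strictly positive, approximately exponential far below threshold
and linear with unit slope far above it, which makes it a convenient
differentiable stand-in for a rectified firing-rate nonlinearity while
keeping the Poisson likelihood finite everywhere.

Key assumptions, and what they buy:

* **Shared inputs.** The population shares one LGN pool and one hidden
  layer, so parameters grow as `6 s1 + s2 + s3 + s1 s2 + s2 s3` rather
  than per-neuron; for 103 neurons on a 31×31 grid that is 2417
  parameters for the whole population versus 961 per neuron for a
  pixel-space linear kernel. The per-neuron ablation (`fit_per_neuron`)
  quantifies what sharing contributes.
* **Poisson emission.** The likelihood `sum(y log M - M)` omits the
  `log y!` term, which is constant in the parameters, so non-integer
  responses (deconvolved, sliding-averaged spike estimates) are accepted
  as-is.
* **No temporal structure.** The model maps one static image to one
  scalar response per neuron; presentation protocols that suppress
  temporal RF structure are assumed upstream.

# Fitting

The log-likelihood is maximized by `optim`'s bound-constrained L-BFGS-B
with analytic gradients (hand-derived backpropagation through the two
softplus layers and through the six DoG parameters of each LGN unit; the
test suite checks the gradient against central finite differences at
relative tolerance 1e-4). A bound-constrained truncated-Newton method
would serve equally; L-BFGS-B is the bounded quasi-Newton optimizer
available in base R and reaches the same contract: box constraints keep
DoG centers inside the image (`[0, p-1]`) and both Gaussian widths in
`(0, p]` (numerically `[1e-3, p]`); all other parameters are unbounded.
The convergence control is a relative-reduction tolerance of about 1e-8
(`factr = 4.5e7`) with a cap of 2000 iterations; there is no early
stopping.

Because the objective is non-convex, each fit is restarted from many
random initializations (default 50; 20 is conventional for
meta-parameter sweeps) and the restart with the best *training-set*
performance is kept. Performance for this selection is the mean
per-neuron Pearson correlation between predictions and single-trial
training responses — the quantity in which results are reported — with
the log-likelihood recorded alongside and used as a tie-break.
Initialization ranges: centers uniform over the image; `sigma_c` ~
U(0.5, p/8), `sigma_s` ~ U(0.5, p/2); `alpha`, `beta` ~ U(0, 1); weights
~ U(-0.1, 0.1); thresholds ~ U(0, 1). These start the network in a
small-signal regime well inside the bounds and are stored in the
configuration so sweeps can vary them.

Two genuinely open choices were resolved as follows. First, `alpha` and
`beta` are *not* sign-constrained: OFF-center LGN units are real, and the
weight polarity is anyway redundant with the sign of the next layer's
weights, so constraining signs would only carve the search space without
restricting the function class. Second, the per-neuron ablation keeps the
hidden-layer size of the population model (`s2` relative to the
population, not to the single neuron); this isolates the effect of
*sharing* inputs from the effect of shrinking the architecture.

# The rLN baseline

The regularized linear-nonlinear baseline estimates a pixel-space kernel
per neuron by penalized least squares, `k = pinv(S'S + alpha L) S' r`,
where `L = D'D` and `D` is the 5-point discrete Laplacian with reduced
stencils at the borders (no wraparound; constants lie in the null space,
and the quadratic form is the summed squared Laplacian — the positive
semidefinite realization of "biasing kernels to be locally smooth").
`alpha` is selected per neuron on a 10% holdout of the training stimuli
by linear-stage prediction correlation; one split (one seed) is shared by
all neurons of a population so that selections are comparable. The
candidate grid spans seven orders of magnitude (1e-2 to 1e5) relative to
the design scale `trace(S'S)/p^2`, ten log-spaced values.

The linear stage has no intercept and images are used exactly as stored.
With zero-mean stimuli this makes the raw response mean unrepresentable:
its least-squares image is a large, meaningless pseudo-DC kernel
component that can swamp the estimate. The pipeline therefore centers the
response vector for the *filter* stage only; the histogram point
nonlinearity — 20 equal bins over the range of training filter outputs,
each bin valued at the mean response within it, empty bins filled by
linear interpolation, predictions linearly interpolated between bin
centers and clamped outside the range — is fitted on the raw responses
and restores the operating level. (`fit_rln_filter` itself takes `r`
literally, and the algebraic identities — exact least squares at
`alpha = 0`, penalty monotone in `alpha` — are tested on it directly.)

# Evaluation statistics

All performance numbers are computed on a held-out validation set with
repeated trials (v stimuli × m neurons × r trials).

* **Correlation** — Pearson r between prediction and the trial-averaged
  response, per neuron; significance by a percentile bootstrap over
  stimuli (95% CI excluding zero; 1000 replicates by default).
* **Power decomposition** — with `Var_s` the variance across stimuli:
  total power is the trial-average of `Var_s(single trial)`; signal power
  the unbiased `(r Var_s(trial mean) - total)/(r - 1)`; noise their
  difference. Normalized noise power `noise/total` is clipped to [0, 1]
  with a flag; a negative *signal* estimate (possible at small r) marks
  the neuron undefined rather than being clipped.
* **FEV** — `(signal - (MSE(pred, trial mean) - noise/r))/signal`. The
  `noise/r` correction removes the bias from trial noise surviving in
  the trial mean, so the true-rate oracle scores 1 and a constant scores
  0 in expectation (both verified by simulation in the tests). Neurons
  with normalized noise power above 70% are excluded from FEV summaries.
* **Linearization and NLI** — the fitted model is linearized by running
  the full rLN pipeline on its *own* training-set predictions. With `LC`
  the validation correlation of the model and `LLC` that of its
  linearization, `NLI = (LC - max(LLC, 0))/LC`, set to 0 when
  `LC < LLC` and when `LC <= 0`; it always lies in [0, 1].
* Summaries pool the mean across all neurons (the pooled mean is used for
  model comparisons; per-region lines can be computed by subsetting).

# The synthetic generator

`synth_spec`/`sample_ground_truth`/`simulate_dataset` emulate the
recorded data's structure exactly: an `n×m` single-trial training matrix
and a `v×m×r` validation tensor, defaulting to 1800 training
presentations, 50 validation images and 10 trials for a 103-neuron
population on a 31×31 grid. Stimuli are spectral (1/f) noise images,
standardized per image, which reproduce the second-order statistics of
natural scenes; generated populations have DoG centers in the central
half of the image, surrounds 1.5–2.5× wider than centers, mixed ON/OFF
polarity, sparse signed hidden mixtures, non-negative output mixtures,
and positive thresholds so that rates are sparse and strongly
stimulus-modulated (coefficient of variation near 1), as cortical
responses to natural scenes are. A global output gain is calibrated by
root finding so the mean rate over a calibration batch matches the
target (default 1 count per presentation); the calibration is verified on
fresh images to within 10%, enlarging the batch and repeating for at most
six rounds before erroring. Emission is Poisson to match the likelihood;
a truncated-Gaussian mode exists to probe misspecification.

What the generator does *not* emulate: higher-order natural-image
statistics (edges, objects), calcium-indicator dynamics, deconvolution
artifacts, correlated (non-Poisson) trial noise, and any temporal
structure. Tests passing on synthetic data therefore demonstrate the
correctness and self-consistency of the estimator, not its performance on
recordings.

# Numerical choices

* Softplus is computed as `max(0, u) + log1p(exp(-|u|))`, and `log M` in
  the likelihood switches to `u` below `u = -33`, so neither over- nor
  underflow can occur anywhere in the objective; the gradient ratio
  `sigmoid(u)/softplus(u)` is pinned to 1 below `u = -30`.
* Pixel coordinates are 0-based integers; kernel grids are evaluated
  literally (no area normalization beyond the `1/sigma^2` factors, so a
  unit-weight Gaussian sums to ~2π when it fits in the image).
* Packing order (LGN blocks of six, hidden weights column-major, hidden
  thresholds, output weights, output thresholds) is frozen and
  round-trip tested; archives store this flat vector at full precision.
* A restart that fails to improve on its initial point returns the
  initial parameters and is flagged non-converged; restart selection
  breaks performance ties by log-likelihood.
* The Moore–Penrose pseudoinverse (SVD) in the rLN solver tolerates
  rank-deficient designs (fewer stimuli than pixels).
* Containers write doubles as `%.17g` text, which round-trips IEEE
  doubles bitwise.

# Problem sizes

The test suite and the reproduction script run everything at desk scale,
chosen so the full pipeline exercises every code path in minutes on one
CPU: populations of 3–6 neurons with 2–3 LGN units on 12×16-pixel grids,
400–600 training images, 6–10 restarts. The defaults of `synth_spec` and
`hsm_config` remain at the recorded-study scale (103 neurons, 31×31,
50 restarts); a full-scale population fit is an hours-long computation,
exactly as for the original recordings.

# Known limitations

* The objective is non-convex; restarts make the *function* estimate
  stable, but recovered parameters are not identifiable (different
  restarts reach different parameterizations with near-identical
  input–output behavior), so fitted DoG parameters should be interpreted
  through the linearized kernels, not read off directly.
* FEV and the power decomposition assume independent trials.
* The per-neuron Poisson likelihood ignores noise correlations between
  neurons; only the mean structure is shared.
* `NLI` compares against one particular linearization (the rLN pipeline);
  a different linear reduction would give slightly different indices.
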