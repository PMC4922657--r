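# Evaluation statistics: per-neuron prediction correlation on the
# multi-trial validation set, signal/noise power decomposition, fraction of
# explained variance with the high-noise exclusion rule, HSM linearization,
# the non-linearity index, and bootstrap significance of the correlations.

val_trial_mean <- function(val_responses) {
  apply(val_responses, c(1, 2), mean)
}

#' Per-neuron correlation between predictions and trial-averaged responses
#'
#' Pearson correlation, per neuron, between the model's predicted rates to
#' the validation images and the response averaged over repeated trials.
#' Neurons whose prediction or trial mean has zero variance get `NA`.
#'
#' @param pred v x m matrix of predicted rates.
#' @param val_responses v x m x r array of validation trials.
#' @return length-m numeric vector of correlations.
#' @export
pearson_per_neuron <- function(pred, val_responses) {
  if (length(dim(val_responses)) != 3L) stop("val_responses must be v x m x r")
  if (nrow(pred) != dim(val_responses)[1] || ncol(pred) != dim(val_responses)[2])
    stop("prediction dimensions do not match the validation tensor")
  if (nrow(pred) < 3) stop("need at least 3 validation stimuli")
  mu <- val_trial_mean(val_responses)
  vapply(seq_len(ncol(pred)), function(j) {
    if (sd(pred[, j]) == 0 || sd(mu[, j]) == 0) return(NA_real_)
    cor(pred[, j], mu[, j])
  }, numeric(1))
}

#' Signal and noise power of multi-trial responses
#'
#' Per neuron, with `Var_s` the variance across stimuli and `r` trials:
#' total power is the mean over trials of `Var_s` of the single-trial
#' response; signal power is the unbiased estimate
#' `(r * Var_s(trial mean) - total) / (r - 1)`; noise power is
#' `total - signal`. Normalized noise power is `noise / total`, clipped to
#' `[0, 1]` with a flag recording when clipping occurred (sampling noise can
#' push the raw estimate outside the interval).
#'
#' @param val_responses v x m x r array, r >= 2.
#' @return data.frame with columns `signal_power`, `noise_power`,
#'   `total_power`, `normalized_noise_power`, `clipped`.
#' @export
power_decomposition <- function(val_responses) {
  if (length(dim(val_responses)) != 3L) stop("val_responses must be v x m x r")
  r <- dim(val_responses)[3]
  if (r < 2) stop("power decomposition needs at least 2 trials")
  m <- dim(val_responses)[2]
  mu <- val_trial_mean(val_responses)
  out <- lapply(seq_len(m), function(j) {
    total <- mean(apply(val_responses[, j, , drop = FALSE], 3,
                        function(x) var(as.vector(x))))
    signal <- (r * var(mu[, j]) - total) / (r - 1)
    noise <- total - signal
    nn_raw <- if (total > 0) noise / total else NA_real_
    nn <- min(max(nn_raw, 0), 1)
    data.frame(signal_power = signal, noise_power = noise,
               total_power = total, normalized_noise_power = nn,
               clipped = !is.na(nn_raw) && (nn_raw < 0 || nn_raw > 1))
  })
  do.call(rbind, out)
}

#' Fraction of explained variance with high-noise exclusion
#'
#' Noise-corrected share of the stimulus-driven (signal) variance captured
#' by a prediction:
#' `FEV = (signal - (MSE(pred, trial mean) - noise / r)) / signal`.
#' The `noise / r` term removes the bias contributed by trial-to-trial
#' noise surviving in the trial mean, so a prediction equal to the true
#' underlying rate scores 1 in expectation and a constant prediction
#' scores 0. Neurons with normalized noise power above `exclude_above`
#' (default 70%) or with non-positive estimated signal power are flagged
#' excluded and their FEV is reported as `NA` in summaries.
#'
#' @param pred v x m matrix of predicted rates.
#' @param val_responses v x m x r array, r >= 2.
#' @param exclude_above normalized-noise-power exclusion threshold.
#' @return data.frame with `fev`, `fev_included`, plus the power columns.
#' @export
fev <- function(pred, val_responses, exclude_above = 0.70) {
  pw <- power_decomposition(val_responses)
  r <- dim(val_responses)[3]
  mu <- val_trial_mean(val_responses)
  mse <- colMeans((pred - mu)^2)
  fv <- (pw$signal_power - (mse - pw$noise_power / r)) / pw$signal_power
  defined <- pw$signal_power > 0
  fv[!defined] <- NA_real_
  included <- defined & pw$normalized_noise_power <= exclude_above
  cbind(data.frame(fev = fv, fev_included = included), pw)
}

#' Linearize a fitted HSM
#'
#' Fits the regularized linear-nonlinear model to the HSM's own predicted
#' responses on the training images, yielding, per neuron, the linear
#' kernel plus point nonlinearity that best mimics the full model. Used
#' for visualization and for the non-linearity index.
#'
#' @param fit an `hsm_fit` (population model).
#' @param images training image stack.
#' @param ... passed to [fit_rln_population()] (`grid`, `seed`, ...).
#' @return an `rln_population` of per-neuron linearized models.
#' @export
linearize_hsm <- function(fit, images, ...) {
  ds <- list(images = as_image_matrix(images, fit$params$p))
  pred <- hsm_forward(fit$params, ds$images)
  fit_rln_population(ds, responses = pred, ...)
}

#' Non-linearity index
#'
#' `NLI = (LC - max(LLC, 0)) / LC`, where `LC` is the validation
#' correlation of the full model and `LLC` that of its linearization. The
#' index is set to 0 whenever `LC < LLC` (the linearization predicts
#' better) and whenever `LC <= 0` (the ratio is meaningless), so it always
#' lies in `[0, 1]`: 0 means the predictive power is entirely linear, 1
#' means none of it is captured by the linearized model.
#'
#' @param lc,llc correlation vectors in `[-1, 1]` (recycled).
#' @return numeric vector of indices in `[0, 1]`.
#' @export
nli <- function(lc, llc) {
  out <- (lc - pmax(llc, 0)) / lc
  out[lc < llc] <- 0
  out[lc <= 0] <- 0
  out[is.na(lc) | is.na(llc)] <- NA_real_
  out
}

#' Bootstrap significance of prediction correlations
#'
#' Percentile bootstrap over validation stimuli of the per-neuron
#' correlation between predictions and trial-averaged responses; a neuron
#' is significant when its 95% CI excludes zero.
#'
#' @param pred v x m prediction matrix.
#' @param val_responses v x m x r array.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return data.frame with `ci_lo`, `ci_hi`, `significant` per neuron.
#' @export
bootstrap_significance <- function(pred, val_responses, n_boot = 1000L,
                                   seed = 1L, level = 0.95) {
  v <- nrow(pred)
  if (v < 10) stop("need at least 10 validation stimuli for the bootstrap")
  mu <- val_trial_mean(val_responses)
  m <- ncol(pred)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, m)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(v, v, replace = TRUE)
    for (j in seq_len(m)) {
      if (sd(pred[idx, j]) > 0 && sd(mu[idx, j]) > 0)
        reps[b, j] <- cor(pred[idx, j], mu[idx, j])
    }
  }
  a <- (1 - level) / 2
  ci <- t(apply(reps, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  data.frame(ci_lo = ci[, 1], ci_hi = ci[, 2],
             significant = ci[, 1] > 0 | ci[, 2] < 0)
}

#' Per-neuron evaluation report
#'
#' Combines the validation correlation, power decomposition, FEV with its
#' inclusion flag, bootstrap significance, and (when a linearized model's
#' correlations are supplied) the non-linearity index into one table.
#'
#' @param pred v x m prediction matrix.
#' @param val_responses v x m x r array.
#' @param llc optional length-m correlations of the linearized model (for
#'   the NLI column).
#' @param n_boot,seed bootstrap settings; `n_boot = 0` skips the bootstrap.
#' @return data.frame with one row per neuron, class `eval_report`.
#' @export
eval_report <- function(pred, val_responses, llc = NULL, n_boot = 1000L,
                        seed = 1L) {
  rs <- pearson_per_neuron(pred, val_responses)
  tab <- cbind(data.frame(neuron = seq_along(rs), pearson_r = rs),
               fev(pred, val_responses))
  if (!is.null(llc)) tab$nli <- nli(rs, llc)
  if (n_boot > 0)
    tab <- cbind(tab, bootstrap_significance(pred, val_responses, n_boot, seed))
  class(tab) <- c("eval_report", "data.frame")
  tab
}

#' Summary statistics of an evaluation report
#'
#' Pooled mean and median correlation across neurons, mean FEV over the
#' included (low-noise) neurons, and mean NLI when present.
#'
#' @param object an `eval_report`.
#' @param ... ignored.
#' @return named list of scalars.
#' @export
summary.eval_report <- function(object, ...) {
  out <- list(
    n_neurons = nrow(object),
    mean_correlation = mean(object$pearson_r, na.rm = TRUE),
    median_correlation = median(object$pearson_r, na.rm = TRUE),
    mean_fev_included = mean(object$fev[object$fev_included], na.rm = TRUE),
    n_fev_included = sum(object$fev_included, na.rm = TRUE))
  if (!is.null(object$nli)) out$mean_nli <- mean(object$nli, na.rm = TRUE)
  if (!is.null(object$significant))
    out$n_significant <- sum(object$significant, na.rm = TRUE)
  out
}
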