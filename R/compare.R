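# Meta-parameter sweeps and model comparison tables.

#' Sweep a meta-parameter of the HSM
#'
#' Refits the model across a grid of values of one meta-parameter (the
#' number of LGN units `s1` or the hidden fraction `gamma`) with the other
#' fixed, recording the training-set performance of the selected restart
#' (and the validation correlation when trials are available). Sweeps
#' conventionally use a reduced restart budget (20 in the original
#' protocol) because of their cost.
#'
#' @param data an `hsm_dataset`.
#' @param config base `hsm_config`; the swept field is overridden.
#' @param s1_values,gamma_values grid for exactly one of the two.
#' @return data.frame: `parameter`, `value`, `train_performance`,
#'   `val_correlation`, `final_loglik`.
#' @export
sweep_meta <- function(data, config, s1_values = NULL, gamma_values = NULL) {
  if (is.null(s1_values) == is.null(gamma_values))
    stop("supply exactly one of s1_values or gamma_values")
  param <- if (!is.null(s1_values)) "s1" else "gamma"
  values <- if (!is.null(s1_values)) s1_values else gamma_values
  rows <- lapply(values, function(v) {
    cfg <- hsm_config(
      s3 = config$s3,
      s1 = if (param == "s1") v else config$s1,
      gamma = if (param == "gamma") v else config$gamma,
      p = config$p, n_restarts = config$n_restarts, seed = config$seed,
      maxit = config$maxit, factr = config$factr,
      init_ranges = config$init_ranges)
    fit <- fit_multi_restart(data, cfg)
    val_r <- NA_real_
    if (!is.null(data$val_responses)) {
      pred <- hsm_forward(fit$params, data$val_images)
      val_r <- mean(pearson_per_neuron(pred, data$val_responses), na.rm = TRUE)
    }
    data.frame(parameter = param, value = v,
               train_performance = fit$train_performance,
               val_correlation = val_r, final_loglik = fit$final_loglik)
  })
  do.call(rbind, rows)
}

#' Compare models on a shared validation set
#'
#' Takes named prediction matrices (e.g. the population HSM, the
#' per-neuron HSM and the rLN baseline) and tabulates their pooled mean
#' and median validation correlation and their mean FEV over the included
#' low-noise neurons.
#'
#' @param predictions named list of v x m prediction matrices.
#' @param val_responses v x m x r array.
#' @return data.frame, one row per model.
#' @export
compare_models <- function(predictions, val_responses) {
  stopifnot(length(predictions) >= 1, !is.null(names(predictions)))
  rows <- lapply(names(predictions), function(nm) {
    rep <- eval_report(predictions[[nm]], val_responses, n_boot = 0)
    s <- summary(rep)
    data.frame(model = nm,
               mean_correlation = s$mean_correlation,
               median_correlation = s$median_correlation,
               mean_fev_included = s$mean_fev_included,
               n_fev_included = s$n_fev_included)
  })
  do.call(rbind, rows)
}
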