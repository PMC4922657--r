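# Poisson maximum-likelihood fitting of the hierarchical structural model:
# objective, analytic gradient (backprop through the softplus layers and the
# DoG kernels), uniform random initialization within the optimizer bounds,
# bound-constrained optimization and random-restart model selection.

#' Assemble a dataset of stimuli and population responses
#'
#' The training set is an n x m matrix of single-trial responses of m
#' neurons to n image presentations (non-negative inferred spike counts,
#' possibly non-integer after deconvolution and smoothing); the validation
#' set holds repeated trials of a separate image set as a v x m x r tensor.
#'
#' @param images training image stack (n x p x p array or n x p^2 matrix).
#' @param train_responses n x m matrix, non-negative.
#' @param val_images validation image stack (v images), or NULL.
#' @param val_responses v x m x r array of validation trials, or NULL.
#' @param meta named list of free-form metadata (region name, units, seed,
#'   provenance); stored as-is.
#' @return object of class `hsm_dataset`.
#' @export
hsm_dataset <- function(images, train_responses, val_images = NULL,
                        val_responses = NULL, meta = list()) {
  p <- image_side(images)
  X <- as_image_matrix(images, p)
  train_responses <- as.matrix(train_responses)
  if (nrow(train_responses) != nrow(X))
    stop("train_responses has ", nrow(train_responses),
         " rows but there are ", nrow(X), " training images")
  if (any(!is.finite(train_responses)) || any(train_responses < 0))
    stop("train_responses must be finite and non-negative")
  ds <- list(images = X, train_responses = train_responses,
             val_images = NULL, val_responses = NULL,
             p = p, meta = meta)
  if (!is.null(val_images)) {
    ds$val_images <- as_image_matrix(val_images, p)
    if (is.null(val_responses)) stop("val_images given without val_responses")
    if (length(dim(val_responses)) != 3L)
      stop("val_responses must be a v x m x r array")
    if (dim(val_responses)[1] != nrow(ds$val_images))
      stop("val_responses first dimension (", dim(val_responses)[1],
           ") must match the number of validation images (",
           nrow(ds$val_images), ")")
    if (dim(val_responses)[2] != ncol(train_responses))
      stop("val_responses neuron dimension (", dim(val_responses)[2],
           ") must match train_responses (", ncol(train_responses), ")")
    if (any(!is.finite(val_responses)) || any(val_responses < 0))
      stop("val_responses must be finite and non-negative")
    ds$val_responses <- val_responses
  }
  class(ds) <- "hsm_dataset"
  ds
}

#' @export
print.hsm_dataset <- function(x, ...) {
  cat("Population dataset:", ncol(x$train_responses), "neurons,",
      nrow(x$images), "training images (", x$p, "x", x$p, ")\n")
  if (!is.null(x$val_responses))
    cat("  validation:", dim(x$val_responses)[1], "images x",
        dim(x$val_responses)[3], "trials\n")
  else cat("  validation: absent\n")
  invisible(x)
}

n_neurons <- function(data) ncol(data$train_responses)

# ---------------------------------------------------------------------------
# objective and gradient
# ---------------------------------------------------------------------------

#' Poisson log-likelihood of an HSM given a dataset
#'
#' The objective maximized during fitting,
#' `sum(y * log M - M)` over stimuli and neurons, where `M` is the model's
#' predicted rate. The additive `log(y!)` term, constant in the parameters,
#' is omitted, so non-integer (deconvolved) responses are admissible. The
#' value is finite for every valid parameter set because the softplus output
#' is strictly positive.
#'
#' @param params an `hsm_params` object.
#' @param data an `hsm_dataset` (training portion is used).
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(params, data) {
  Y <- data$train_responses
  if (any(Y < 0)) stop("responses must be non-negative")
  fw <- hsm_forward_full(params, data$images)
  sum(Y * log_softplus(fw$u3)) - sum(fw$M)
}

#' Gradient of the Poisson log-likelihood
#'
#' Analytic gradient with respect to every free parameter, in the canonical
#' packing order of [pack_params()]. Derivatives are propagated through the
#' two softplus layers (whose derivative is the logistic function) and into
#' the six parameters of each LGN difference-of-Gaussians kernel.
#'
#' @inheritParams poisson_loglik
#' @return numeric vector aligned with `pack_params(params)`.
#' @export
loglik_gradient <- function(params, data) {
  X <- data$images
  Y <- data$train_responses
  if (any(Y < 0)) stop("responses must be non-negative")
  p <- params$p
  fw <- hsm_forward_full(params, X)

  # dLL/du3 = (y / M) * sigmoid(u3) - sigmoid(u3); the ratio sigmoid/softplus
  # tends to 1 as u -> -Inf, guard against 0/0 underflow there
  ratio3 <- logistic(fw$u3) / fw$M
  ratio3[fw$u3 < -30] <- 1
  G3 <- Y * ratio3 - logistic(fw$u3)                     # n x s3

  g_ot <- -colSums(G3)
  g_ow <- t(G3) %*% fw$psi2                              # s3 x s2

  G2 <- (G3 %*% params$output$weights) * logistic(fw$u2) # n x s2
  g_ht <- -colSums(G2)
  g_hw <- t(G2) %*% fw$psi1                              # s2 x s1

  Gpsi1 <- G2 %*% params$hidden$weights                  # n x s1
  Cmat <- crossprod(X, Gpsi1)                            # p^2 x s1
  coords <- 0:(p - 1)
  g_lgn <- lapply(seq_along(params$lgn), function(i) {
    d <- params$lgn[[i]]
    dx <- coords - d$mu_x
    dy <- coords - d$mu_y
    d2 <- outer(dx^2, dy^2, "+")
    Gc <- exp(-d2 / (2 * d$sigma_c^2))
    Gs <- exp(-d2 / (2 * d$sigma_s^2))
    Ac <- d$alpha / d$sigma_c^2 * Gc
    As <- d$beta / d$sigma_s^2 * Gs
    ci <- Cmat[, i]
    dot <- function(Kd) sum(ci * as.vector(Kd))
    c(mu_x    = dot((Ac / d$sigma_c^2 - As / d$sigma_s^2) * dx),  # recycled by row
      mu_y    = dot(sweep(Ac / d$sigma_c^2 - As / d$sigma_s^2, 2, dy, "*")),
      sigma_c = dot(d$alpha / d$sigma_c^3 * Gc * (d2 / d$sigma_c^2 - 2)),
      sigma_s = dot(-d$beta / d$sigma_s^3 * Gs * (d2 / d$sigma_s^2 - 2)),
      alpha   = dot(Gc / d$sigma_c^2),
      beta    = dot(-Gs / d$sigma_s^2))
  })
  c(unlist(g_lgn), as.vector(g_hw), g_ht, as.vector(g_ow), g_ot,
    use.names = FALSE)
}

# ---------------------------------------------------------------------------
# initialization
# ---------------------------------------------------------------------------

#' Draw random initial HSM parameters
#'
#' Every parameter is drawn uniformly from its initialization range: LGN
#' centers over the full extent of the image, widths within the box bounds,
#' weights and thresholds from small symmetric/positive ranges (see
#' `init_ranges` in [hsm_config()]). The draw depends only on the R RNG
#' state, so it is reproducible under `set.seed`.
#'
#' @param config an `hsm_config`.
#' @return an `hsm_params` object inside the optimizer bounds.
#' @export
random_init <- function(config) {
  r <- config$init_ranges
  p <- config$p
  runi <- function(n, rg) runif(n, rg[1], rg[2])
  lgn <- lapply(seq_len(config$s1), function(i) {
    list(mu_x = runi(1, r$mu), mu_y = runi(1, r$mu),
         sigma_c = runi(1, r$sigma_c),
         sigma_s = runi(1, r$sigma_s),
         alpha = runi(1, r$alpha), beta = runi(1, r$beta))
  })
  hidden <- list(weights = matrix(runi(config$s2 * config$s1, r$weight),
                                  config$s2, config$s1),
                 thresholds = runi(config$s2, r$threshold))
  output <- list(weights = matrix(runi(config$s3 * config$s2, r$weight),
                                  config$s3, config$s2),
                 thresholds = runi(config$s3, r$threshold))
  hsm_params(lgn, hidden, output, p)
}

# ---------------------------------------------------------------------------
# fitting
# ---------------------------------------------------------------------------

# mean per-neuron Pearson correlation between predictions and responses;
# neurons with zero variance on either side are dropped from the mean
mean_pearson <- function(pred, resp) {
  rs <- vapply(seq_len(ncol(resp)), function(j) {
    if (sd(pred[, j]) == 0 || sd(resp[, j]) == 0) return(NA_real_)
    cor(pred[, j], resp[, j])
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Fit the HSM from one initial condition
#'
#' Maximizes the Poisson log-likelihood by bound-constrained quasi-Newton
#' optimization (`optim` method `"L-BFGS-B"`) with the analytic gradient,
#' keeping LGN centers inside the image and Gaussian widths in `(0, p]`.
#' If the optimizer terminates without improving on the initial point, the
#' initial parameters are returned and the fit is flagged non-converged.
#'
#' @param data an `hsm_dataset`.
#' @param config an `hsm_config`.
#' @param init initial `hsm_params`; drawn by [random_init()] if missing.
#' @param seed bookkeeping tag stored in the result (the fit itself is
#'   deterministic given `init`).
#' @return object of class `hsm_fit`: `params`, `final_loglik`,
#'   `init_loglik`, `train_performance` (mean per-neuron Pearson r on the
#'   training set), `converged`, `counts`, `seed`.
#' @export
fit_hsm <- function(data, config, init = NULL, seed = NA_integer_) {
  if (ncol(data$train_responses) != config$s3)
    stop("config$s3 = ", config$s3, " but dataset has ",
         ncol(data$train_responses), " neurons")
  if (data$p != config$p)
    stop("config grid side ", config$p, " does not match dataset grid ", data$p)
  if (is.null(init)) init <- random_init(config)
  b <- hsm_bounds(config)
  theta0 <- pack_params(init)
  ll0 <- poisson_loglik(init, data)

  negll <- function(th) -poisson_loglik(unpack_params(th, config), data)
  neggr <- function(th) -loglik_gradient(unpack_params(th, config), data)
  opt <- optim(theta0, negll, neggr, method = "L-BFGS-B",
               lower = b$lower, upper = b$upper,
               control = list(maxit = config$maxit, factr = config$factr))

  improved <- -opt$value >= ll0
  theta <- if (improved) opt$par else theta0
  params <- unpack_params(theta, config)
  pred <- hsm_forward(params, data$images)
  structure(list(params = params,
                 final_loglik = if (improved) -opt$value else ll0,
                 init_loglik = ll0,
                 train_performance = mean_pearson(pred, data$train_responses),
                 converged = improved && opt$convergence == 0,
                 counts = opt$counts, message = opt$message,
                 seed = seed, config = config),
            class = "hsm_fit")
}

#' @export
print.hsm_fit <- function(x, ...) {
  cat("HSM fit: logLik", format(x$final_loglik, digits = 6),
      "; training r =", round(x$train_performance, 4),
      if (isTRUE(x$converged)) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' Fit with random restarts, keeping the best model on the training set
#'
#' Runs `config$n_restarts` independent fits from random initial parameter
#' draws and returns the restart with the highest training-set performance
#' (mean per-neuron Pearson correlation; log-likelihood breaks ties). All
#' restart seeds derive from `config$seed`, so the selected model is
#' bitwise reproducible.
#'
#' @inheritParams fit_hsm
#' @return the winning `hsm_fit`, with a `restarts` data.frame
#'   (seed, final_loglik, train_performance, converged) attached.
#' @export
fit_multi_restart <- function(data, config) {
  stopifnot(config$n_restarts >= 1)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_restarts)
  fits <- vector("list", config$n_restarts)
  for (i in seq_len(config$n_restarts)) {
    set.seed(seeds[i])
    init <- random_init(config)
    fits[[i]] <- tryCatch(fit_hsm(data, config, init, seed = seeds[i]),
                          error = function(e) e)
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok))
    stop("all ", config$n_restarts, " restarts failed; first error: ",
         conditionMessage(fits[[1]]))
  fits <- fits[ok]
  perf <- vapply(fits, `[[`, numeric(1), "train_performance")
  ll <- vapply(fits, `[[`, numeric(1), "final_loglik")
  best <- order(-perf, -ll)[1]
  out <- fits[[best]]
  out$restarts <- data.frame(
    seed = vapply(fits, `[[`, integer(1), "seed"),
    final_loglik = ll, train_performance = perf,
    converged = vapply(fits, `[[`, logical(1), "converged"))
  out
}

#' Fit each neuron with its own single-output HSM
#'
#' The ablation of the shared-input structure: every neuron is fitted
#' independently as an `s3 = 1` model with the same number of LGN units and
#' the same hidden-layer size as the population model (`s2` is kept relative
#' to the population size, not recomputed for a single neuron). Restart
#' seeds derive from `config$seed` and the neuron index.
#'
#' @inheritParams fit_hsm
#' @return list of `hsm_fit` objects, one per neuron, with class
#'   `hsm_fit_per_neuron`.
#' @export
fit_per_neuron <- function(data, config) {
  m <- n_neurons(data)
  s2_pop <- config$s2
  fits <- lapply(seq_len(m), function(j) {
    cfg_j <- hsm_config(s3 = 1L, s1 = config$s1, gamma = config$gamma,
                        p = config$p, n_restarts = config$n_restarts,
                        seed = (config$seed + 7919L * (j - 1L)) %% .Machine$integer.max,
                        maxit = config$maxit, factr = config$factr,
                        init_ranges = config$init_ranges)
    cfg_j$s2 <- s2_pop
    data_j <- data
    data_j$train_responses <- data$train_responses[, j, drop = FALSE]
    if (!is.null(data_j$val_responses))
      data_j$val_responses <- data$val_responses[, j, , drop = FALSE]
    fit_multi_restart(data_j, cfg_j)
  })
  class(fits) <- "hsm_fit_per_neuron"
  fits
}

#' Predictions of a per-neuron fit collection
#'
#' @param fits an `hsm_fit_per_neuron` list.
#' @param images image stack.
#' @return n_images x m matrix of predicted rates.
#' @export
per_neuron_forward <- function(fits, images) {
  do.call(cbind, lapply(fits, function(f) hsm_forward(f$params, images)))
}
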