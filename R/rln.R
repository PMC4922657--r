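# Regularized linear-nonlinear baseline: pixel-space linear kernel with a
# squared-Laplacian smoothness penalty, regularization strength chosen on a
# 10% holdout, and a 20-bin histogram point nonlinearity.

#' Discrete Laplacian smoothness penalty
#'
#' Builds `L = D' D` where `D` is the 5-point discrete Laplacian operator on
#' the p x p pixel grid, with reduced stencils at the borders (each pixel's
#' diagonal entry is minus its number of in-grid neighbors, so constant
#' kernels are in the null space; no wraparound and no ghost pixels). The
#' quadratic form `k' L k` is the summed squared Laplacian of the kernel and
#' `L` is symmetric positive semidefinite.
#'
#' @param p grid side length (at least 3).
#' @return a p^2 x p^2 matrix.
#' @export
build_laplacian_penalty <- function(p) {
  stopifnot(p >= 3)
  n <- p * p
  idx <- function(k, l) (l - 1L) * p + k  # column-major, matching image flattening
  D <- matrix(0, n, n)
  for (l in seq_len(p)) for (k in seq_len(p)) {
    row <- idx(k, l)
    nb <- rbind(c(k - 1L, l), c(k + 1L, l), c(k, l - 1L), c(k, l + 1L))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= p & nb[, 2] >= 1 & nb[, 2] <= p, ,
             drop = FALSE]
    D[row, row] <- -nrow(nb)
    D[row, idx(nb[, 1], nb[, 2])] <- 1
  }
  crossprod(D)
}

#' Estimate a regularized linear kernel
#'
#' The Laplacian-regularized least-squares estimate
#' `k = pinv(S'S + alpha * L) S' r`, where `S` is the n x p^2 stimulus
#' matrix (rows are flattened images), `r` the response vector and `pinv`
#' the Moore-Penrose pseudoinverse. With `alpha = 0` and a full-column-rank
#' design this is ordinary least squares.
#'
#' @param S stimulus matrix (n x p^2).
#' @param r length-n response vector.
#' @param alpha regularization constant (>= 0).
#' @param L penalty matrix from [build_laplacian_penalty()]; built on the
#'   fly when omitted.
#' @return length-p^2 kernel (reshape with `matrix(k, p, p)` for display).
#' @export
fit_rln_filter <- function(S, r, alpha, L = NULL) {
  if (!all(is.finite(S)) || !all(is.finite(r))) stop("non-finite inputs")
  if (alpha < 0) stop("alpha must be non-negative")
  if (length(r) != nrow(S)) stop("response length does not match stimulus rows")
  p <- as.integer(round(sqrt(ncol(S))))
  if (is.null(L)) L <- build_laplacian_penalty(p)
  A <- crossprod(S) + alpha * L
  drop(MASS::ginv(A) %*% crossprod(S, r))
}

#' Default regularization grid
#'
#' Ten logarithmically spaced values spanning 1e-2 to 1e5 relative to the
#' mean diagonal scale of the design, `trace(S'S) / p^2`.
#'
#' @param S stimulus matrix.
#' @return decreasing-to-increasing numeric vector of length 10.
#' @export
default_alpha_grid <- function(S) {
  scale <- sum(S * S) / ncol(S)
  10^seq(-2, 5, length.out = 10) * scale
}

#' Select the regularization strength on a holdout split
#'
#' Sets aside a fraction of the training stimuli (default 10%), fits the
#' linear kernel on the remainder for every candidate `alpha`, and returns
#' the candidate whose linear-stage prediction has the highest Pearson
#' correlation with the held-out responses. The split depends only on
#' `seed`, so the selection is deterministic.
#'
#' @param S stimulus matrix (n x p^2).
#' @param r length-n response vector.
#' @param grid candidate alphas; [default_alpha_grid()] when omitted.
#' @param holdout_fraction fraction of rows held out (default 0.1).
#' @param seed RNG seed for the split.
#' @param L penalty matrix (rebuilt when omitted).
#' @return list: `alpha` (selected value), `correlations` (per grid point),
#'   `holdout` (row indices held out).
#' @export
select_alpha <- function(S, r, grid = NULL, holdout_fraction = 0.1,
                         seed = 1L, L = NULL) {
  if (is.null(grid)) grid <- default_alpha_grid(S)
  if (length(grid) < 1) stop("alpha grid is empty")
  p <- as.integer(round(sqrt(ncol(S))))
  if (is.null(L)) L <- build_laplacian_penalty(p)
  n <- nrow(S)
  set.seed(seed)
  hold <- sort(sample.int(n, max(1L, round(holdout_fraction * n))))
  if (sd(r[hold]) == 0) stop("holdout responses are constant; cannot score alpha")
  Str <- S[-hold, , drop = FALSE]
  rtr <- r[-hold] - mean(r[-hold])
  cors <- vapply(grid, function(a) {
    k <- fit_rln_filter(Str, rtr, a, L)
    pred <- drop(S[hold, , drop = FALSE] %*% k)
    if (sd(pred) == 0) return(-Inf)
    cor(pred, r[hold])
  }, numeric(1))
  list(alpha = grid[which.max(cors)], correlations = cors, holdout = hold)
}

#' Histogram estimate of the point nonlinearity
#'
#' Partitions the range of the linear filter outputs into `n_bins` equal
#' intervals and assigns each bin the mean training response of the points
#' falling in it; empty bins are filled by linear interpolation between the
#' nearest non-empty neighbors (end bins take the nearest value). The
#' fitted map is evaluated by linear interpolation between the two bin
#' centers bracketing a query, clamped to the end-bin values outside the
#' training range.
#'
#' @param filter_outputs length-n linear-stage outputs on the training set.
#' @param responses length-n training responses.
#' @param n_bins number of histogram bins (default 20).
#' @return list with `centers` and `values` (both length `n_bins`), class
#'   `rln_nonlinearity`.
#' @export
fit_point_nonlinearity <- function(filter_outputs, responses, n_bins = 20L) {
  n <- length(filter_outputs)
  if (n < n_bins) stop("need at least n_bins = ", n_bins, " training points")
  if (length(responses) != n) stop("length mismatch")
  rng <- range(filter_outputs)
  if (diff(rng) == 0) stop("filter outputs are constant; nonlinearity undefined")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  bin <- findInterval(filter_outputs, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  values <- vapply(seq_len(n_bins), function(b) {
    if (any(bin == b)) mean(responses[bin == b]) else NA_real_
  }, numeric(1))
  if (anyNA(values)) {
    filled <- !is.na(values)
    values <- approx(centers[filled], values[filled], xout = centers,
                     rule = 2)$y
  }
  structure(list(centers = centers, values = values),
            class = "rln_nonlinearity")
}

eval_nonlinearity <- function(nl, x) {
  approx(nl$centers, nl$values, xout = x, rule = 2)$y
}

#' Fit the full regularized linear-nonlinear model for one neuron
#'
#' Pipeline: pick `alpha` on the holdout split, estimate the kernel on the
#' full training set at the selected `alpha` (responses mean-centered for
#' the linear stage, which has no intercept), then fit the histogram point
#' nonlinearity mapping raw training filter outputs to raw responses.
#'
#' @inheritParams select_alpha
#' @param n_bins bins for the point nonlinearity.
#' @return object of class `rln_model`: `kernel` (length p^2), `p`,
#'   `alpha_reg`, `nonlinearity`, `alpha_correlations`.
#' @export
fit_rln <- function(S, r, grid = NULL, holdout_fraction = 0.1, seed = 1L,
                    n_bins = 20L, L = NULL) {
  p <- as.integer(round(sqrt(ncol(S))))
  if (is.null(L)) L <- build_laplacian_penalty(p)
  sel <- select_alpha(S, r, grid, holdout_fraction, seed, L)
  # the filter is estimated on mean-centered responses: with no intercept in
  # the linear stage a raw response mean would leak into the kernel as an
  # arbitrary pseudo-DC component; the histogram nonlinearity, fitted on the
  # raw responses, restores the operating level
  k <- fit_rln_filter(S, r - mean(r), sel$alpha, L)
  nl <- fit_point_nonlinearity(drop(S %*% k), r, n_bins)
  structure(list(kernel = k, p = p, alpha_reg = sel$alpha,
                 nonlinearity = nl, alpha_correlations = sel$correlations),
            class = "rln_model")
}

#' @export
print.rln_model <- function(x, ...) {
  cat("rLN model:", x$p, "x", x$p, "kernel, alpha =",
      format(x$alpha_reg, digits = 4), "\n")
  invisible(x)
}

#' Predict responses with a fitted rLN model
#'
#' @param model an `rln_model`.
#' @param images image stack on the model's grid.
#' @return numeric vector of predicted responses.
#' @export
rln_predict <- function(model, images) {
  X <- as_image_matrix(images, model$p)
  eval_nonlinearity(model$nonlinearity, drop(X %*% model$kernel))
}

#' Fit the rLN baseline to every neuron of a population dataset
#'
#' One shared holdout split (single seed) is used for the `alpha` selection
#' of all neurons; each neuron selects its own `alpha` on that split.
#'
#' @param data an `hsm_dataset`, or a list with `images` and a response
#'   matrix supplied via `responses`.
#' @param responses optional n x m response matrix overriding
#'   `data$train_responses` (used to linearize a fitted HSM).
#' @inheritParams fit_rln
#' @return list of `rln_model`, one per neuron, class `rln_population`.
#' @export
fit_rln_population <- function(data, responses = NULL, grid = NULL,
                               holdout_fraction = 0.1, seed = 1L,
                               n_bins = 20L) {
  S <- data$images
  if (is.null(responses)) responses <- data$train_responses
  L <- build_laplacian_penalty(as.integer(round(sqrt(ncol(S)))))
  models <- lapply(seq_len(ncol(responses)), function(j)
    fit_rln(S, responses[, j], grid, holdout_fraction, seed, n_bins, L))
  class(models) <- "rln_population"
  models
}

#' @rdname fit_rln_population
#' @param models an `rln_population` list.
#' @param images image stack.
#' @return n_images x m matrix of predictions.
#' @export
rln_population_predict <- function(models, images) {
  do.call(cbind, lapply(models, rln_predict, images = images))
}
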