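#' hsmrf: hierarchical structural models of V1 population receptive fields
#'
#' Fits a three-layer feedforward encoding model (difference-of-Gaussians
#' LGN layer, softplus hidden and output layers) to single-trial responses
#' of a local population of visual cortical neurons by Poisson maximum
#' likelihood, together with a Laplacian-regularized linear-nonlinear
#' baseline and the evaluation statistics used to compare them
#' (prediction correlation, signal/noise power, fraction of explained
#' variance, non-linearity index).
#'
#' @importFrom stats optim cor rnorm runif rpois var fft quantile approx
#'   sd uniroot median
#' @importFrom utils modifyList
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# image stacks
# ---------------------------------------------------------------------------

#' Coerce an image stack to a flat stimulus matrix
#'
#' Images live on a square p x p pixel grid with 0-based integer coordinates
#' (k, l): k indexes rows, l indexes columns. Internally stimuli are handled
#' as an n x p^2 matrix whose columns follow R's column-major order, i.e.
#' pixel (k, l) maps to flat index l * p + k + 1.
#'
#' @param images an n x p x p array, a single p x p matrix, or an n x p^2
#'   matrix (already flat).
#' @param p grid side length; inferred when `images` is an array.
#' @return an n x p^2 numeric matrix.
#' @export
as_image_matrix <- function(images, p = NULL) {
  if (is.matrix(images)) {
    if (!is.null(p) && ncol(images) == p && nrow(images) == p) {
      images <- array(images, c(1L, p, p))
    } else {
      if (!is.null(p) && ncol(images) != p * p)
        stop("stimulus matrix has ", ncol(images), " columns, expected p^2 = ", p * p)
      if (is.null(p)) {
        p <- as.integer(round(sqrt(ncol(images))))
        if (p * p != ncol(images))
          stop("stimulus matrix columns (", ncol(images), ") are not a square number")
      }
      stopifnot(all(is.finite(images)))
      return(images)
    }
  }
  if (length(dim(images)) != 3L)
    stop("images must be an n x p x p array or an n x p^2 matrix")
  d <- dim(images)
  if (d[2] != d[3]) stop("image grid must be square, got ", d[2], " x ", d[3])
  if (!is.null(p) && d[2] != p)
    stop("image grid side ", d[2], " does not match expected p = ", p)
  if (!all(is.finite(images))) stop("images contain non-finite values")
  matrix(images, nrow = d[1], ncol = d[2] * d[3])
}

#' @rdname as_image_matrix
#' @export
image_side <- function(images) {
  if (is.matrix(images)) {
    p <- as.integer(round(sqrt(ncol(images))))
    if (p * p != ncol(images)) stop("cannot infer grid side from matrix")
    p
  } else dim(images)[2]
}

# ---------------------------------------------------------------------------
# model configuration
# ---------------------------------------------------------------------------

#' Model configuration for the hierarchical structural model
#'
#' Collects the meta-parameters that are fixed during fitting: the number of
#' LGN units `s1`, the hidden-layer fraction `gamma` (the hidden layer has
#' `s2 = max(1, floor(gamma * s3))` units), the number of modeled neurons
#' `s3`, the stimulus grid side `p`, the restart budget, and optimizer
#' settings.
#'
#' @param s3 number of modeled neurons (output units).
#' @param s1 number of LGN (difference-of-Gaussians) units. Default 9.
#' @param gamma hidden-layer size as a fraction of `s3`. Default 0.2.
#' @param p stimulus grid side in pixels. Default 31.
#' @param n_restarts random restarts for [fit_multi_restart()]. Default 50.
#' @param seed master seed for initialization draws.
#' @param maxit optimizer iteration cap per restart.
#' @param factr relative-tolerance factor handed to `optim`'s L-BFGS-B
#'   (`factr * .Machine$double.eps` is the relative reduction tolerance;
#'   the default corresponds to about 1e-8).
#' @param init_ranges named list overriding initialization ranges; see
#'   [random_init()].
#' @return an object of class `hsm_config`.
#' @export
hsm_config <- function(s3, s1 = 9L, gamma = 0.2, p = 31L, n_restarts = 50L,
                       seed = 1L, maxit = 2000L, factr = 4.5e7,
                       init_ranges = list()) {
  stopifnot(s1 >= 1, gamma > 0, gamma <= 1, s3 >= 1, p >= 3)
  cfg <- list(
    s1 = as.integer(s1), gamma = gamma, s3 = as.integer(s3),
    s2 = max(1L, as.integer(floor(gamma * s3))),
    p = as.integer(p), n_restarts = as.integer(n_restarts),
    seed = as.integer(seed), maxit = as.integer(maxit), factr = factr,
    init_ranges = utils::modifyList(default_init_ranges(p), init_ranges)
  )
  class(cfg) <- "hsm_config"
  cfg
}

default_init_ranges <- function(p) {
  list(
    mu      = c(0, p - 1),
    sigma_c = c(0.5, max(p / 8, 0.75)),
    sigma_s = c(0.5, p / 2),
    alpha   = c(0, 1),
    beta    = c(0, 1),
    weight  = c(-0.1, 0.1),
    threshold = c(0, 1)
  )
}

#' @export
print.hsm_config <- function(x, ...) {
  cat("HSM configuration: s1 =", x$s1, " s2 =", x$s2, " s3 =", x$s3,
      " (gamma =", x$gamma, ")\n")
  cat("  grid", x$p, "x", x$p, "; restarts", x$n_restarts,
      "; maxit", x$maxit, "; seed", x$seed, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# DoG kernels (LGN layer)
# ---------------------------------------------------------------------------

#' Difference-of-Gaussians kernel of one LGN unit
#'
#' Evaluates, on the discrete pixel grid, the kernel
#' \deqn{K(k, l) = \frac{\alpha}{\sigma_c^2} e^{-\frac{(k-\mu_x)^2 + (l-\mu_y)^2}{2\sigma_c^2}}
#'              - \frac{\beta}{\sigma_s^2}  e^{-\frac{(k-\mu_x)^2 + (l-\mu_y)^2}{2\sigma_s^2}}}
#' with 0-based pixel coordinates. No area normalization beyond the 1/sigma^2
#' factors is applied, so the grid sum of a single Gaussian term of weight w
#' is approximately 2*pi*w when the kernel fits inside the image.
#'
#' @param dog named list or vector with elements `mu_x`, `mu_y` (center, in
#'   `[0, p-1]`), `sigma_c`, `sigma_s` (widths, in `(0, p]`), `alpha`, `beta`
#'   (center/surround weights, unconstrained sign).
#' @param p grid side length.
#' @return a p x p matrix; rows index k, columns index l.
#' @export
dog_kernel <- function(dog, p) {
  dog <- as.list(dog)
  validate_dog(dog, p)
  coords <- 0:(p - 1)
  d2 <- outer((coords - dog$mu_x)^2, (coords - dog$mu_y)^2, "+")
  dog$alpha / dog$sigma_c^2 * exp(-d2 / (2 * dog$sigma_c^2)) -
    dog$beta / dog$sigma_s^2 * exp(-d2 / (2 * dog$sigma_s^2))
}

validate_dog <- function(dog, p) {
  req <- c("mu_x", "mu_y", "sigma_c", "sigma_s", "alpha", "beta")
  if (!all(req %in% names(dog))) stop("DoG parameters must contain ",
                                      paste(req, collapse = ", "))
  if (!all(vapply(dog[req], is.finite, logical(1))))
    stop("DoG parameters must be finite")
  if (dog$sigma_c <= 0 || dog$sigma_c > p) stop("center width out of (0, p]")
  if (dog$sigma_s <= 0 || dog$sigma_s > p) stop("surround width out of (0, p]")
  if (dog$mu_x < 0 || dog$mu_x > p - 1 || dog$mu_y < 0 || dog$mu_y > p - 1)
    stop("DoG center lies outside the image")
  invisible(TRUE)
}

#' LGN layer response to a stack of images
#'
#' The output of LGN unit i to image n is the pixelwise product of the image
#' with the unit's difference-of-Gaussians kernel, summed over pixels; it is
#' exactly linear in the image.
#'
#' @param lgn list of DoG parameter sets (see [dog_kernel()]).
#' @param images image stack (see [as_image_matrix()]).
#' @param p grid side; inferred from `images` when possible.
#' @return an n_images x s1 matrix of LGN unit outputs.
#' @export
lgn_forward <- function(lgn, images, p = NULL) {
  if (is.null(p)) p <- image_side(images)
  X <- as_image_matrix(images, p)
  K <- vapply(lgn, function(d) as.vector(dog_kernel(d, p)), numeric(p * p))
  X %*% K
}

# ---------------------------------------------------------------------------
# softplus transfer
# ---------------------------------------------------------------------------

#' Softplus (logistic-loss) transfer function
#'
#' `f(x) = log(1 + exp(x - t))`, computed as
#' `max(0, u) + log1p(exp(-|u|))` with `u = x - t` so that it never
#' overflows and never underflows to exactly zero. The output is strictly
#' positive, approaches `exp(x - t)` for large negative drive and the line
#' `x - t` (slope 1) for large positive drive.
#'
#' @param x drive (any numeric array).
#' @param t threshold, subtracted from the drive (default 0).
#' @return softplus of `x - t`, same shape as `x`.
#' @export
softplus_transfer <- function(x, t = 0) {
  u <- x - t
  pmax(u, 0) + log1p(exp(-abs(u)))
}

# log(softplus(u)), stable for very negative u where softplus(u) ~ exp(u)
log_softplus <- function(u) {
  out <- u
  hi <- u > -33  # below this, log(log1p(exp(u))) == u to double precision
  out[hi] <- log(softplus_transfer(u[hi]))
  out
}

logistic <- function(u) 1 / (1 + exp(-u))

# ---------------------------------------------------------------------------
# parameter container, packing, bounds
# ---------------------------------------------------------------------------

#' Construct a full HSM parameter set
#'
#' @param lgn list of `s1` DoG parameter lists.
#' @param hidden,output cortical layers: lists with `weights`
#'   (out_units x in_units matrix) and `thresholds` (length out_units).
#' @param p stimulus grid side the LGN kernels are evaluated on.
#' @return an object of class `hsm_params`.
#' @export
hsm_params <- function(lgn, hidden, output, p) {
  stopifnot(is.list(lgn), length(lgn) >= 1)
  s1 <- length(lgn)
  s2 <- nrow(hidden$weights)
  s3 <- nrow(output$weights)
  if (ncol(hidden$weights) != s1)
    stop("hidden weights must be s2 x s1 (got ", ncol(hidden$weights), " columns)")
  if (ncol(output$weights) != s2)
    stop("output weights must be s3 x s2 (got ", ncol(output$weights), " columns)")
  if (length(hidden$thresholds) != s2 || length(output$thresholds) != s3)
    stop("threshold lengths must match layer sizes")
  for (d in lgn) validate_dog(as.list(d), p)
  structure(list(lgn = lapply(lgn, as.list), hidden = hidden, output = output,
                 p = as.integer(p)),
            class = "hsm_params")
}

#' @export
print.hsm_params <- function(x, ...) {
  cat("HSM parameters: s1 =", length(x$lgn),
      " s2 =", nrow(x$hidden$weights),
      " s3 =", nrow(x$output$weights),
      " (", length(pack_params(x)), "free parameters, grid", x$p, "x", x$p, ")\n")
  invisible(x)
}

#' Number of free parameters of an HSM
#'
#' `6*s1 + s2 + s3 + s1*s2 + s2*s3`: six parameters per LGN unit, one
#' threshold per cortical unit, and the two dense weight matrices.
#'
#' @param s1,s2,s3 layer sizes.
#' @export
n_hsm_params <- function(s1, s2, s3) 6L * s1 + s2 + s3 + s1 * s2 + s2 * s3

#' Pack HSM parameters into a flat vector / unpack a flat vector
#'
#' Canonical packing order used by the optimizer: for each LGN unit in turn
#' `(mu_x, mu_y, sigma_c, sigma_s, alpha, beta)`; then the hidden weight
#' matrix (column-major), hidden thresholds, output weight matrix
#' (column-major), output thresholds. `unpack_params(pack_params(x), cfg)`
#' is the identity.
#'
#' @param params an `hsm_params` object.
#' @return `pack_params`: a numeric vector of length
#'   `n_hsm_params(s1, s2, s3)`.
#' @export
pack_params <- function(params) {
  ord <- c("mu_x", "mu_y", "sigma_c", "sigma_s", "alpha", "beta")
  c(unlist(lapply(params$lgn, function(d) unlist(d[ord]))),
    as.vector(params$hidden$weights), params$hidden$thresholds,
    as.vector(params$output$weights), params$output$thresholds,
    use.names = FALSE)
}

#' @rdname pack_params
#' @param theta flat parameter vector in canonical packing order.
#' @param config an `hsm_config` (supplies `s1`, `s2`, `s3`, `p`).
#' @export
unpack_params <- function(theta, config) {
  s1 <- config$s1; s2 <- config$s2; s3 <- config$s3
  if (length(theta) != n_hsm_params(s1, s2, s3))
    stop("parameter vector has length ", length(theta), ", expected ",
         n_hsm_params(s1, s2, s3))
  ord <- c("mu_x", "mu_y", "sigma_c", "sigma_s", "alpha", "beta")
  i <- 0L
  take <- function(k) { out <- theta[(i + 1L):(i + k)]; i <<- i + k; out }
  lgn <- lapply(seq_len(s1), function(j) {
    v <- as.list(take(6L)); names(v) <- ord; v
  })
  hw <- matrix(take(s1 * s2), s2, s1)
  ht <- take(s2)
  ow <- matrix(take(s2 * s3), s3, s2)
  ot <- take(s3)
  hsm_params(lgn, list(weights = hw, thresholds = ht),
             list(weights = ow, thresholds = ot), config$p)
}

#' Box bounds aligned with the canonical packing
#'
#' Centers are constrained to the image (`[0, p-1]`), Gaussian widths to be
#' positive and at most the image side; all other parameters are unbounded.
#'
#' @param config an `hsm_config`.
#' @param width_floor smallest admissible Gaussian width (the open interval
#'   `(0, p]` is closed off numerically at this value for the optimizer).
#' @return list with numeric vectors `lower` and `upper`.
#' @export
hsm_bounds <- function(config, width_floor = 1e-3) {
  p <- config$p
  per_unit_lo <- c(0, 0, width_floor, width_floor, -Inf, -Inf)
  per_unit_hi <- c(p - 1, p - 1, p, p, Inf, Inf)
  n_rest <- n_hsm_params(config$s1, config$s2, config$s3) - 6L * config$s1
  list(lower = c(rep(per_unit_lo, config$s1), rep(-Inf, n_rest)),
       upper = c(rep(per_unit_hi, config$s1), rep(Inf, n_rest)))
}

# ---------------------------------------------------------------------------
# forward pass
# ---------------------------------------------------------------------------

# forward pass keeping intermediates (needed by the gradient)
hsm_forward_full <- function(params, X) {
  p <- params$p
  K <- vapply(params$lgn, function(d) as.vector(dog_kernel(d, p)),
              numeric(p * p))
  psi1 <- X %*% K                                        # n x s1
  u2 <- sweep(psi1 %*% t(params$hidden$weights), 2, params$hidden$thresholds)
  psi2 <- softplus_transfer(u2)                          # n x s2
  u3 <- sweep(psi2 %*% t(params$output$weights), 2, params$output$thresholds)
  M <- softplus_transfer(u3)                             # n x s3
  list(psi1 = psi1, u2 = u2, psi2 = psi2, u3 = u3, M = M)
}

#' Predicted firing rates of the hierarchical structural model
#'
#' Deterministic forward pass: LGN difference-of-Gaussians filtering, a
#' hidden softplus layer, and a softplus output layer, each threshold
#' applied subtractively inside its unit's transfer. All predicted rates
#' are strictly positive.
#'
#' @param params an `hsm_params` object.
#' @param images image stack on the same grid.
#' @return an n_images x s3 matrix of predicted rates.
#' @export
hsm_forward <- function(params, images) {
  X <- as_image_matrix(images, params$p)
  hsm_forward_full(params, X)$M
}
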