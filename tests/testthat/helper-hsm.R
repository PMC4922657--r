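# Shared fixtures: tiny configurations, random small models and datasets,
# and naive loop-based oracles the vectorized implementation is checked
# against.

tiny_config <- function(s1 = 2L, s3 = 3L, gamma = 0.7, p = 8L, seed = 1L,
                        n_restarts = 1L, maxit = 400L) {
  hsm_config(s3 = s3, s1 = s1, gamma = gamma, p = p, seed = seed,
             n_restarts = n_restarts, maxit = maxit)
}

random_params <- function(config, seed = 1L) {
  set.seed(seed)
  random_init(config)
}

random_stack <- function(n, p, seed = 1L) {
  set.seed(seed)
  array(rnorm(n * p * p), c(n, p, p))
}

random_dataset <- function(config, n = 20L, seed = 1L) {
  imgs <- random_stack(n, config$p, seed)
  set.seed(seed + 1L)
  Y <- matrix(rpois(n * config$s3, 1.5), n, config$s3)
  hsm_dataset(imgs, Y)
}

# Eq-by-eq naive forward pass: explicit loops over pixels and units
naive_dog_response <- function(dog, img) {
  p <- nrow(img)
  acc <- 0
  for (k in 0:(p - 1)) for (l in 0:(p - 1)) {
    d2 <- (k - dog$mu_x)^2 + (l - dog$mu_y)^2
    acc <- acc + img[k + 1, l + 1] *
      (dog$alpha / dog$sigma_c^2 * exp(-d2 / (2 * dog$sigma_c^2)) -
         dog$beta / dog$sigma_s^2 * exp(-d2 / (2 * dog$sigma_s^2)))
  }
  acc
}

naive_hsm_forward <- function(params, images) {
  n <- dim(images)[1]
  s1 <- length(params$lgn)
  s2 <- nrow(params$hidden$weights)
  s3 <- nrow(params$output$weights)
  sp <- function(x, t) log(1 + exp(x - t))
  out <- matrix(0, n, s3)
  for (im in seq_len(n)) {
    psi1 <- vapply(params$lgn, naive_dog_response,
                   numeric(1), img = images[im, , ])
    psi2 <- vapply(seq_len(s2), function(h)
      sp(sum(params$hidden$weights[h, ] * psi1),
         params$hidden$thresholds[h]), numeric(1))
    out[im, ] <- vapply(seq_len(s3), function(o)
      sp(sum(params$output$weights[o, ] * psi2),
         params$output$thresholds[o]), numeric(1))
  }
  out
}

naive_poisson_loglik <- function(params, data) {
  M <- naive_hsm_forward(params,
                         array(data$images,
                               c(nrow(data$images), params$p, params$p)))
  acc <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
    acc <- acc + data$train_responses[i, j] * log(M[i, j]) - M[i, j]
  acc
}

fd_gradient <- function(params, data, config, h = 1e-5) {
  th <- pack_params(params)
  vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    (poisson_loglik(unpack_params(tp, config), data) -
       poisson_loglik(unpack_params(tm, config), data)) / (2 * h)
  }, numeric(1))
}

# small synthetic population with Poisson noise, shared across tests
shared_input_population <- function(seed = 21L, n_train = 300L,
                                    n_val = 100L) {
  spec <- synth_spec(n_train = n_train, n_val = n_val, n_trials = 1L,
                     p = 12L, s1 = 3L, gamma = 0.5, s3 = 4L, seed = seed)
  gt <- sample_ground_truth(spec)
  list(spec = spec, gt = gt, data = simulate_dataset(gt$params, spec))
}
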