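test_that("Poisson log-likelihood matches the naive summation oracle", {
  cfg <- tiny_config(s1 = 2, s3 = 3, gamma = 0.7, p = 6)
  data <- random_dataset(cfg, n = 8, seed = 5)
  pars <- random_params(cfg, seed = 6)
  expect_equal(poisson_loglik(pars, data),
               naive_poisson_loglik(pars, data), tolerance = 1e-10)

  # zero responses: only the -sum(M) term remains
  data0 <- data
  data0$train_responses[] <- 0
  expect_equal(poisson_loglik(pars, data0),
               -sum(hsm_forward(pars, data$images)))

  dneg <- data
  dneg$train_responses[1, 1] <- -1
  expect_error(poisson_loglik(pars, dneg), "non-negative")
})

test_that("the Poisson term y*log(M) - M peaks at M = y", {
  y <- 3.7
  f <- function(m) y * log(m) - m
  opt <- optimize(f, c(0.01, 50), maximum = TRUE)
  expect_equal(opt$maximum, y, tolerance = 1e-4)
})

test_that("analytic gradient matches central finite differences", {
  cfg <- tiny_config(s1 = 2, s3 = 3, gamma = 0.7, p = 8)
  data <- random_dataset(cfg, n = 20, seed = 11)
  for (s in 1:3) {
    pars <- random_params(cfg, seed = s + 30)
    g <- loglik_gradient(pars, data)
    fd <- fd_gradient(pars, data, cfg)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-4)
  }
})

test_that("gradient vanishes at a one-parameter optimum and respects symmetry", {
  cfg <- tiny_config(s1 = 1, s3 = 1, gamma = 1, p = 6)
  data <- random_dataset(cfg, n = 15, seed = 8)
  pars <- random_params(cfg, seed = 8)
  # free only the output threshold; locate its optimum numerically
  ll_of_t <- function(t) {
    pp <- pars; pp$output$thresholds <- t
    poisson_loglik(pp, data)
  }
  topt <- optimize(ll_of_t, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  pars_opt <- pars; pars_opt$output$thresholds <- topt
  g <- loglik_gradient(pars_opt, data)
  expect_lt(abs(g[length(g)]), 1e-4)  # last packed entry = output threshold

  # permuting hidden units permutes the matching gradient blocks
  cfg2 <- tiny_config(s1 = 2, s3 = 3, gamma = 0.7, p = 6)
  data2 <- random_dataset(cfg2, n = 10, seed = 9)
  pars2 <- random_params(cfg2, seed = 9)
  perm <- c(2, 1)
  pp <- pars2
  pp$hidden$weights <- pars2$hidden$weights[perm, , drop = FALSE]
  pp$hidden$thresholds <- pars2$hidden$thresholds[perm]
  pp$output$weights <- pars2$output$weights[, perm, drop = FALSE]
  g1 <- loglik_gradient(pars2, data2)
  g2 <- loglik_gradient(pp, data2)
  s1 <- cfg2$s1; s2 <- cfg2$s2; s3 <- cfg2$s3
  i_hw <- 6 * s1 + seq_len(s1 * s2)
  i_ht <- 6 * s1 + s1 * s2 + seq_len(s2)
  hw1 <- matrix(g1[i_hw], s2, s1); hw2 <- matrix(g2[i_hw], s2, s1)
  expect_equal(hw2, hw1[perm, , drop = FALSE])
  expect_equal(g2[i_ht], g1[i_ht][perm])
})

test_that("random initialization stays inside the constraint box and is reproducible", {
  cfg <- hsm_config(s3 = 5, s1 = 4, gamma = 0.4, p = 31)
  b <- hsm_bounds(cfg)
  set.seed(123)
  draws <- replicate(1000, pack_params(random_init(cfg)))
  expect_true(all(draws >= b$lower & draws <= b$upper))
  # centers inside the image, widths positive and at most the image side
  mu_rows <- as.vector(outer(1:2, 6 * (0:(cfg$s1 - 1)), "+"))
  sd_rows <- as.vector(outer(3:4, 6 * (0:(cfg$s1 - 1)), "+"))
  expect_true(all(draws[mu_rows, ] >= 0 & draws[mu_rows, ] <= 30))
  expect_true(all(draws[sd_rows, ] > 0 & draws[sd_rows, ] <= 31))

  set.seed(77); a <- pack_params(random_init(cfg))
  set.seed(77); b2 <- pack_params(random_init(cfg))
  expect_identical(a, b2)
})

test_that("single fits ascend the likelihood and respect bounds", {
  cfg <- tiny_config(s1 = 2, s3 = 3, gamma = 0.7, p = 8, maxit = 150)
  data <- random_dataset(cfg, n = 40, seed = 13)
  set.seed(14)
  fit <- fit_hsm(data, cfg)
  expect_gte(fit$final_loglik, fit$init_loglik)
  b <- hsm_bounds(cfg)
  th <- pack_params(fit$params)
  expect_true(all(th >= b$lower & th <= b$upper))
})

test_that("restart selection keeps the best training performance and is deterministic", {
  cfg5 <- tiny_config(s1 = 2, s3 = 2, gamma = 0.9, p = 6, n_restarts = 5,
                      maxit = 60, seed = 31)
  data <- random_dataset(cfg5, n = 30, seed = 17)
  f5 <- fit_multi_restart(data, cfg5)
  expect_equal(f5$train_performance, max(f5$restarts$train_performance))
  expect_true(all(f5$restarts$final_loglik >= -Inf))

  # nested seed sets: the 2-restart run sees a prefix of the 5-restart seeds,
  # so best-of-2 cannot beat best-of-5
  cfg2 <- cfg5; cfg2$n_restarts <- 2L
  f2 <- fit_multi_restart(data, cfg2)
  expect_identical(f2$restarts$seed, f5$restarts$seed[1:2])
  expect_lte(f2$train_performance, f5$train_performance)

  # bitwise determinism under the master seed
  g5 <- fit_multi_restart(data, cfg5)
  expect_identical(pack_params(f5$params), pack_params(g5$params))
})

test_that("per-neuron fitting keeps shapes and degenerates to the population fit at m = 1", {
  cfg <- tiny_config(s1 = 2, s3 = 3, gamma = 0.7, p = 6, n_restarts = 2,
                     maxit = 60, seed = 41)
  data <- random_dataset(cfg, n = 25, seed = 19)
  fits <- fit_per_neuron(data, cfg)
  expect_length(fits, 3)
  pred <- per_neuron_forward(fits, data$images)
  expect_equal(dim(pred), c(25L, 3L))

  # m = 1: identical procedure, identical selected parameters
  d1 <- data
  d1$train_responses <- data$train_responses[, 1, drop = FALSE]
  cfg1 <- tiny_config(s1 = 2, s3 = 1, gamma = 0.7, p = 6, n_restarts = 2,
                      maxit = 60, seed = 41)
  cfg1$s2 <- cfg$s2
  fpop <- fit_multi_restart(d1, cfg1)
  fpn <- fit_per_neuron(d1, cfg1)
  expect_identical(pack_params(fpn[[1]]$params), pack_params(fpop$params))
})

test_that("the objective is invariant to stimulus ordering", {
  cfg <- tiny_config(s1 = 2, s3 = 3, gamma = 0.7, p = 6)
  data <- random_dataset(cfg, n = 12, seed = 23)
  pars <- random_params(cfg, seed = 23)
  set.seed(1); perm <- sample(12)
  shuf <- data
  shuf$images <- data$images[perm, , drop = FALSE]
  shuf$train_responses <- data$train_responses[perm, , drop = FALSE]
  expect_equal(poisson_loglik(pars, shuf), poisson_loglik(pars, data))
  expect_equal(loglik_gradient(pars, shuf), loglik_gradient(pars, data))
})
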