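test_that("DoG kernel degenerates correctly and integrates to ~2*pi*(alpha-beta)", {
  p <- 31
  # pure center Gaussian: non-negative, peaked at the pixel nearest the center
  k <- dog_kernel(list(mu_x = 10.3, mu_y = 20.6, sigma_c = 2, sigma_s = 3,
                       alpha = 1, beta = 0), p)
  expect_true(all(k >= 0))
  peak <- which(k == max(k), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(10 + 1, 21 + 1))  # 0-based (10, 21)

  # identical center and surround cancel exactly
  k0 <- dog_kernel(list(mu_x = 5, mu_y = 5, sigma_c = 2, sigma_s = 2,
                        alpha = 0.7, beta = 0.7), p)
  expect_equal(max(abs(k0)), 0)

  # grid sum of a mid-grid unit: each Gaussian term of weight w sums to
  # ~2*pi*w under the 1/sigma^2 scaling, so the kernel mass is ~pi here
  km <- dog_kernel(list(mu_x = 15, mu_y = 15, sigma_c = 2, sigma_s = 4,
                        alpha = 1, beta = 0.5), p)
  expect_equal(sum(km), 2 * pi * (1 - 0.5), tolerance = 1e-3)
})

test_that("DoG kernel rejects invalid parameters", {
  base <- list(mu_x = 3, mu_y = 3, sigma_c = 1, sigma_s = 2,
               alpha = 1, beta = 0.5)
  expect_error(dog_kernel(modifyList(base, list(sigma_c = 0)), 8), "width")
  expect_error(dog_kernel(modifyList(base, list(sigma_s = 9)), 8), "width")
  expect_error(dog_kernel(modifyList(base, list(mu_x = -1)), 8), "center")
  expect_error(dog_kernel(modifyList(base, list(mu_y = 7.5)), 8), "center")
})

test_that("LGN layer is exactly linear in the image and matches the pixel-loop oracle", {
  p <- 5
  dog <- list(mu_x = 2.2, mu_y = 1.7, sigma_c = 1.1, sigma_s = 2.3,
              alpha = 0.9, beta = 0.4)
  set.seed(7)
  A <- array(rnorm(2 * p * p), c(2, p, p))
  out <- lgn_forward(list(dog), A)
  expect_equal(out[1, 1], naive_dog_response(dog, A[1, , ]), tolerance = 1e-12)
  expect_equal(out[2, 1], naive_dog_response(dog, A[2, , ]), tolerance = 1e-12)

  # zero image, additivity and homogeneity to machine precision
  Z <- array(0, c(1, p, p))
  expect_equal(as.vector(lgn_forward(list(dog), Z)), 0)
  S <- array(A[1, , ] + A[2, , ], c(1, p, p))
  expect_equal(lgn_forward(list(dog), S)[1, 1], out[1, 1] + out[2, 1],
               tolerance = 1e-12)
  expect_equal(lgn_forward(list(dog), array(3.5 * A[1, , ], c(1, p, p)))[1, 1],
               3.5 * out[1, 1], tolerance = 1e-12)
  expect_error(lgn_forward(list(dog), A, p = 9), "columns|grid")
})

test_that("softplus transfer is stable, positive and has the slope-1 asymptote", {
  expect_equal(softplus_transfer(0, 0), log(2))
  expect_equal(softplus_transfer(5, 5), log(2))
  # linear asymptote: f(x) - (x - t) vanishes below 1e-12 by u = 30
  expect_lt(abs(softplus_transfer(30, 0) - 30), 1e-12)
  # deep below threshold: ~exp(u), strictly positive, no underflow to 0
  expect_equal(softplus_transfer(-50, 0), exp(-50), tolerance = 1e-10)
  expect_gt(softplus_transfer(-700, 0), 0)
  expect_true(is.finite(softplus_transfer(700, 0)))
  # bounded gap to the rectifier: f(u) - max(0, u) in (0, log 2]; in double
  # precision the gap underflows to exactly 0 once u exceeds ~36
  u <- seq(-40, 40, by = 0.37)
  gap <- softplus_transfer(u, 0) - pmax(u, 0)
  expect_true(all(gap >= 0 & gap <= log(2) + 1e-15))
  expect_true(all(gap[u <= 30] > 0))
  # strictly increasing
  expect_true(all(diff(softplus_transfer(u, 0)) > 0))
})

test_that("forward pass matches hand-composed and loop-based oracles", {
  # constant network: zero weights, zero thresholds -> every output log 2
  cfg <- tiny_config(s1 = 2, s3 = 3, gamma = 0.7, p = 6)
  pars <- random_params(cfg, seed = 3)
  pars$hidden$weights[] <- 0; pars$hidden$thresholds[] <- 0
  pars$output$weights[] <- 0; pars$output$thresholds[] <- 0
  M <- hsm_forward(pars, random_stack(4, 6, seed = 2))
  expect_equal(as.vector(M), rep(log(2), 12))

  # 1-1-1 chain, composed step by step
  cfg1 <- hsm_config(s3 = 1, s1 = 1, gamma = 1, p = 5)
  dog <- list(mu_x = 2, mu_y = 2, sigma_c = 1, sigma_s = 2,
              alpha = 1, beta = 0.3)
  pars1 <- hsm_params(list(dog),
                      list(weights = matrix(0.8), thresholds = 0.2),
                      list(weights = matrix(1.4), thresholds = -0.1), 5)
  img <- random_stack(1, 5, seed = 4)
  l1 <- naive_dog_response(dog, img[1, , ])
  l2 <- log(1 + exp(0.8 * l1 - 0.2))
  l3 <- log(1 + exp(1.4 * l2 + 0.1))
  expect_equal(hsm_forward(pars1, img)[1, 1], l3, tolerance = 1e-12)

  # random small instances against the naive loop oracle
  for (s in 1:3) {
    cfg <- tiny_config(s1 = 3, s3 = 4, gamma = 0.5, p = 7, seed = s)
    pars <- random_params(cfg, seed = s + 10)
    A <- random_stack(6, 7, seed = s + 20)
    expect_equal(hsm_forward(pars, A), naive_hsm_forward(pars, A),
                 tolerance = 1e-10)
  }
})

test_that("forward pass is strictly positive and permutation-symmetric", {
  cfg <- tiny_config(s1 = 3, s3 = 4, gamma = 0.5, p = 7)
  for (s in 1:5) {
    pars <- random_params(cfg, seed = s)
    M <- hsm_forward(pars, random_stack(5, 7, seed = s + 50))
    expect_true(all(M > 0))
  }
  # permuting hidden units together with weight rows/columns is invisible
  pars <- random_params(cfg, seed = 9)
  A <- random_stack(5, 7, seed = 60)
  perm <- c(2, 1)
  pp <- pars
  pp$hidden$weights <- pars$hidden$weights[perm, , drop = FALSE]
  pp$hidden$thresholds <- pars$hidden$thresholds[perm]
  pp$output$weights <- pars$output$weights[, perm, drop = FALSE]
  expect_equal(hsm_forward(pp, A), hsm_forward(pars, A))
})

test_that("parameter packing round-trips and counts match the layer formula", {
  cfg <- tiny_config(s1 = 3, s3 = 4, gamma = 0.5, p = 7)
  pars <- random_params(cfg, seed = 2)
  th <- pack_params(pars)
  expect_length(th, n_hsm_params(3, 2, 4))
  expect_equal(unpack_params(th, cfg), pars)
  expect_error(unpack_params(th[-1], cfg), "length")

  # production-scale bookkeeping: 9 LGN units, 20 hidden, 103 neurons
  expect_identical(n_hsm_params(9L, 20L, 103L), 2417L)
  cfg_big <- hsm_config(s3 = 103, s1 = 9, gamma = 0.2, p = 31)
  expect_identical(cfg_big$s2, 20L)

  b <- hsm_bounds(cfg)
  expect_length(b$lower, length(th))
  # center bounds [0, p-1], width bounds (0, p], rest unbounded
  expect_equal(b$upper[1:4], c(6, 6, 7, 7))
  expect_true(all(is.infinite(b$lower[-(1:(6 * 3))])))
})
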