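test_that("decode is the affine map beta + b'r", {
  expect_equal(decode(linear_decoder(c(2, -1)), c(3, 4)), 2)
  expect_equal(decode(linear_decoder(c(0, 0), beta = 5),
                      matrix(rnorm(10), 5, 2)), rep(5, 5))
  x <- rnorm(6)
  expect_equal(decode(linear_decoder(1), matrix(x)), x)
  expect_error(decode(linear_decoder(c(1, 2)), matrix(1, 1, 3)), "match")
})

test_that("closed-form decoding distribution matches direct substitution", {
  g <- stimulus_grid(2, 2)
  m <- encoding_model(g, matrix(c(1, 2), 2, 4), noise_cov = 1)
  d <- decoding_distribution(m, linear_decoder(c(1, 1), beta = 0.5),
                             condition = c(1, 1))
  expect_equal(d$mean, 3.5)
  expect_equal(d$var, 2)
  # independent channel noise: variance is sum b_k^2 sigma_k^2
  covs <- rep(list(diag(c(0.5, 2))), 4)
  m2 <- encoding_model(g, matrix(c(1, 2), 2, 4), covs)
  b <- c(0.3, -1.2)
  d2 <- decoding_distribution(m2, linear_decoder(b), condition = c(2, 1))
  expect_equal(d2$var, sum(b^2 * c(0.5, 2)))
})

test_that("closed-form decoding moments agree with simulation", {
  g <- stimulus_grid(2, 2)
  S <- matrix(c(1, 0.3, 0.3, 0.8), 2, 2)
  m <- encoding_model(g, matrix(c(0.5, -1), 2, 4), noise_cov = S)
  dec <- linear_decoder(c(1.5, -0.7), beta = 0.2)
  cf <- decoding_distribution(m, dec, condition = c(1, 1))
  vals <- decode(dec, sample_responses(m, c(1, 1), 2e4, seed = 5))
  expect_equal(mean(vals), cf$mean, tolerance = 0.02)
  expect_equal(var(vals), cf$var, tolerance = 0.05)
})

test_that("linear SVM classifier finds the separating axis and signed distances", {
  cl <- separable_clouds(n = 50)
  dec <- fit_linear_classifier(cl$x, cl$y)
  expect_gt(abs(dec$weights[1]), 5 * abs(dec$weights[2]))
  expect_equal(dec$training_accuracy, 1)
  expect_equal(sqrt(sum(dec$weights^2)), 1)  # unit-norm hyperplane normal
  # second class scores positive
  expect_gt(mean(decode(dec, cl$x[cl$y == 2, , drop = FALSE])), 0)
  expect_lt(mean(decode(dec, cl$x[cl$y == 1, , drop = FALSE])), 0)
  # duplication invariance
  dec2 <- fit_linear_classifier(rbind(cl$x, cl$x), c(cl$y, cl$y))
  expect_equal(dec2$weights, dec$weights, tolerance = 1e-6)
  expect_error(fit_linear_classifier(cl$x, rep(1, nrow(cl$x))), "two classes")
})

test_that("shuffled labels decode at chance on held-out data", {
  withr::with_seed(9, {
    x <- matrix(rnorm(400 * 4), 400, 4)
    y <- sample(rep(1:2, 200))
  })
  dec <- fit_linear_classifier(x[1:300, ], y[1:300])
  acc <- mean((decode(dec, x[301:400, ]) > 0) + 1 == y[301:400])
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
})

test_that("counterexample decoders hit the prescribed inner product", {
  b0 <- counterexample_decoder(c(1, -1, 0), d = 0, seed = 1)
  expect_lt(abs(sum(b0$weights * c(1, -1, 0))), 1e-10)
  expect_gt(sum(b0$weights^2), 0)
  b1 <- counterexample_decoder(c(2, 0), d = 4, seed = 1)
  expect_equal(sum(b1$weights * c(2, 0)), 4, tolerance = 1e-10)
  expect_error(counterexample_decoder(c(0, 0), d = 1), "infeasible")
  expect_error(counterexample_decoder(c(0, 0), d = 0), "non-zero")
  # seeded property sweep
  for (s in 1:100) {
    delta <- withr::with_seed(s, rnorm(sample(2:8, 1)))
    b <- counterexample_decoder(delta, d = 0, seed = s + 1000)
    expect_lt(abs(sum(b$weights * delta)), 1e-10)
    expect_gt(sqrt(sum(b$weights^2)), 0)
  }
})

test_that("encoding separability forces identical decoding distributions (green arrow)", {
  for (s in 1:5) {
    withr::with_seed(s, {
      N <- sample(2:5, 1)
      g <- stimulus_grid(2, 3)
      tb <- gaussian_tuning_bank(g, centers = runif(N, 0, 3),
                                 widths = runif(N, 0.5, 2),
                                 gains = runif(N, 0.5, 2),
                                 values_A = c(1, 2))
      m <- encoding_model(g, tb, noise_cov = runif(1, 0.2, 2))
      dec <- linear_decoder(rnorm(N), beta = rnorm(1))
    })
    d <- decoding_distribution(m, dec)
    for (i in 1:2) {
      sub <- d[d$level_A == i, ]
      expect_equal(diff(range(sub$mean)), 0)
      expect_equal(diff(range(sub$var)), 0)
    }
  }
})

test_that("decoded samples converge across irrelevant levels under separability", {
  w <- make_world("separable", seed = 3)
  tr <- generate_trials(w, 2000, seed = 4)
  x1 <- tr$decoded_value[tr$level_A == 1 & tr$level_B == 1]
  x2 <- tr$decoded_value[tr$level_A == 1 & tr$level_B == 2]
  ks <- suppressWarnings(stats::ks.test(x1, x2)$statistic)
  expect_lt(ks, 0.06)  # ~1.36/sqrt(1000) scale at n = 2000 per group
})

test_that("hidden and exposed constructions reproduce the two counterexamples", {
  # hidden: b'delta = 0 keeps the decoding distributions identical
  wh <- make_world("hidden_violation", effect_size = 1.5, seed = 6)
  expect_false(check_encoding_separability(wh$encoding)$encoding_separable)
  dh <- decoding_distribution(wh$encoding, wh$decoder)
  expect_lt(abs(dh$mean[1] - dh$mean[2]), 1e-10)
  # exposed: decoding means differ by exactly effect_size
  we <- make_world("exposed_violation", effect_size = 2, seed = 6)
  de <- decoding_distribution(we$encoding, we$decoder)
  expect_equal(de$mean[de$level_A == 1 & de$level_B == 1] -
                 de$mean[de$level_A == 1 & de$level_B == 2], 2,
               tolerance = 1e-10)
})

test_that("signed-distance decoding is invariant to joint rotation", {
  cl <- separable_clouds(n = 15)
  dec <- fit_linear_classifier(cl$x, cl$y)
  vals <- decode(dec, cl$x)
  Q <- qr.Q(qr(withr::with_seed(8, matrix(rnorm(4), 2, 2))))
  dec_rot <- linear_decoder(drop(Q %*% dec$weights), beta = dec$beta)
  vals_rot <- decode(dec_rot, cl$x %*% t(Q))
  expect_equal(vals_rot, vals, tolerance = 1e-12)
})
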