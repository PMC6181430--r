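test_that("Gaussian tuning bank evaluates the bell-shaped curve exactly", {
  g <- stimulus_grid(2, 2)
  # one channel peaking at its preferred value
  tb <- gaussian_tuning_bank(g, centers = 3, widths = 1, gains = 1,
                             values_A = c(3, 4))
  expect_equal(tb[1, 1], 1)
  # two channels, stimulus at the first center: c(1, exp(-0.5))
  tb2 <- gaussian_tuning_bank(g, centers = c(0, 1), widths = c(1, 1),
                              gains = c(1, 1), values_A = c(0, 2))
  expect_equal(unname(tb2[, 1]), c(1, exp(-0.5)))
  # columns with equal level_A are identical (separable by construction)
  expect_equal(tb2[, 1], tb2[, 2], ignore_attr = TRUE)
  expect_equal(tb2[, 3], tb2[, 4], ignore_attr = TRUE)
})

test_that("four-channel bank peaks at the matching channel, falls off symmetrically", {
  g <- stimulus_grid(2, 2)
  tb <- gaussian_tuning_bank(g, centers = 1:4, widths = rep(1, 4),
                             gains = rep(1, 4), values_A = c(3, 4))
  col <- tb[, 1]  # stimulus value 3
  expect_equal(which.max(col), 3, ignore_attr = TRUE)
  expect_equal(col[2], col[4], ignore_attr = TRUE)  # symmetric neighbours
})

test_that("tuning bank rejects invalid parameters", {
  g <- stimulus_grid(2, 2)
  expect_error(gaussian_tuning_bank(g, 1, widths = 0, gains = 1,
                                    values_A = c(0, 1)), "width")
  expect_error(gaussian_tuning_bank(g, 1, widths = 1, gains = -1,
                                    values_A = c(0, 1)), "gain")
  expect_error(gaussian_tuning_bank(g, numeric(0), numeric(0), numeric(0),
                                    values_A = c(0, 1)), "channel")
})

test_that("encoding_model expands scalar variance and validates covariances", {
  m <- tiny_separable_model(noise = 1)
  expect_equal(m$noise_cov[[1]], diag(2))
  expect_length(m$noise_cov, 4)
  # asymmetric covariance rejected
  g <- stimulus_grid(2, 2)
  tb <- m$tuning
  bad <- matrix(c(1, 0.5, -0.5, 1), 2, 2)
  expect_error(encoding_model(g, tb, bad), "semidefinite")
  # per-condition covariances differing across level_B are stored verbatim
  covs <- rep(list(diag(2)), 4)
  covs[[2]] <- 4 * diag(2)
  m2 <- encoding_model(g, tb, covs)
  expect_equal(m2$noise_cov[[2]], 4 * diag(2))
})

test_that("apply_violation edits exactly one condition and is invertible", {
  m <- tiny_separable_model()
  # zero delta is the identity
  expect_equal(apply_violation(m, delta = c(0, 0), condition = c(1, 1)), m)
  # vector addition on the target column: separable baseline with
  # f(A1B1) = f(A1B2) = (1, 2), then delta = (1, -1) on (1, 1)
  m$tuning[, 1] <- m$tuning[, 2] <- c(1, 2)
  m2 <- apply_violation(m, delta = c(1, -1), condition = c(1, 1))
  expect_equal(unname(m2$tuning[, 1]), c(2, 1))
  expect_equal(m2$tuning[, -1], m$tuning[, -1])
  # noise scaling touches only the target condition
  m3 <- apply_violation(m, condition = c(1, 2), kind = "noise",
                        noise_scale = 4)
  expect_equal(m3$noise_cov[[2]], 4 * diag(2))
  expect_equal(m3$noise_cov[[1]], diag(2))
  # inverse restores exactly
  expect_equal(apply_violation(m3, condition = c(1, 2), kind = "noise",
                               noise_scale = 1 / 4), m)
  m4 <- apply_violation(m, delta = c(0.3, -0.7), condition = c(2, 1))
  expect_equal(apply_violation(m4, delta = -c(0.3, -0.7),
                               condition = c(2, 1)), m)
  expect_error(apply_violation(m, delta = c(1, 0), condition = c(3, 1)),
               "outside")
})

test_that("sample_responses matches the stated moments and is seed-deterministic", {
  # zero-noise limit: every row equals the tuning vector
  m0 <- tiny_separable_model(noise = 0)
  s0 <- sample_responses(m0, c(1, 2), n = 5, seed = 1)
  expect_equal(s0, matrix(rep(m0$tuning[, 2], each = 5), 5, 2))
  # Monte-Carlo moments for a 1-channel standard normal model
  g <- stimulus_grid(2, 2)
  m1 <- encoding_model(g, matrix(0, 1, 4), noise_cov = 1)
  s <- sample_responses(m1, c(1, 1), n = 1e5, seed = 7)
  expect_lt(abs(mean(s)), 4 / sqrt(1e5))
  expect_lt(abs(var(as.vector(s)) - 1), 0.05)
  # determinism contract
  expect_identical(sample_responses(m1, c(1, 1), 100, seed = 3),
                   sample_responses(m1, c(1, 1), 100, seed = 3))
  expect_error(sample_responses(m1, c(1, 1), 0, seed = 1), "at least 1")
})

test_that("multichannel sampling reproduces the full mean vector and covariance", {
  g <- stimulus_grid(2, 2)
  S <- matrix(c(2, 0.8, 0.8, 1), 2, 2)
  m <- encoding_model(g, matrix(c(1, -1), 2, 4), noise_cov = S)
  s <- sample_responses(m, c(2, 2), n = 1e5, seed = 11)
  expect_equal(colMeans(s), c(1, -1), tolerance = 0.02)
  expect_equal(cov(s), S, tolerance = 0.05)
})

test_that("encoding separability check is exact on analytic models", {
  m <- tiny_separable_model()
  rep0 <- check_encoding_separability(m)
  expect_true(rep0$tuning_separable && rep0$noise_separable)
  expect_equal(rep0$max_tuning_gap, 0)
  expect_equal(rep0$max_cov_gap, 0)
  # tuning violation reported with its sup-norm gap
  m1 <- apply_violation(m, delta = c(1, -1), condition = c(1, 1))
  rep1 <- check_encoding_separability(m1)
  expect_false(rep1$tuning_separable)
  expect_equal(rep1$max_tuning_gap, 1)
  # noise violation: |4 sigma^2 - sigma^2| = 3
  m2 <- apply_violation(m, condition = c(1, 2), kind = "noise",
                        noise_scale = 4)
  rep2 <- check_encoding_separability(m2)
  expect_false(rep2$noise_separable)
  expect_equal(rep2$max_cov_gap, 3)
})

test_that("any bank depending only on the target dimension passes the check", {
  for (s in 1:10) {
    withr::with_seed(s, {
      LA <- sample(2:4, 1); LB <- sample(2:4, 1); N <- sample(2:6, 1)
      g <- stimulus_grid(LA, LB)
      tb <- gaussian_tuning_bank(g, centers = runif(N, 0, 4),
                                 widths = runif(N, 0.5, 2),
                                 gains = runif(N, 0.5, 3),
                                 values_A = sort(runif(LA, 0, 4)))
      m <- encoding_model(g, tb, noise_cov = runif(1, 0.1, 2))
      expect_true(check_encoding_separability(m)$encoding_separable)
    })
  }
})
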