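test_that("sphere offsets match brute-force lattice enumeration", {
  expect_equal(nrow(sphere_offsets(0)), 1)
  expect_equal(nrow(sphere_offsets(1)), 7)
  expect_equal(nrow(sphere_offsets(3)), 123)
  # independent count: explicit triple loop over the bounding cube
  for (r in 0:5) {
    count <- 0L
    for (x in -r:r) for (y in -r:r) for (z in -r:r)
      if (x * x + y * y + z * z <= r * r) count <- count + 1L
    offs <- sphere_offsets(r)
    expect_equal(nrow(offs), count)
    # symmetry under negation
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    expect_setequal(key(offs), key(-offs))
  }
  expect_error(sphere_offsets(-1), "non-negative")
})

test_that("volume dataset validates shapes and trial tables", {
  dat <- array(rnorm(4 * 4 * 4 * 8), c(4, 4, 4, 8))
  tt <- tibble::tibble(level_A = rep(1:2, 4), level_B = rep(1:2, each = 4))
  ds <- volume_dataset(dat, trial_table = tt)
  expect_equal(sum(ds$mask), 64)
  expect_error(volume_dataset(dat, mask = array(1, c(3, 4, 4)),
                              trial_table = tt), "mask dimensions")
  expect_error(volume_dataset(dat, trial_table = tt[1:4, ]), "rows")
})

test_that("searchlight maps are deterministic and flag degenerate centers", {
  w <- make_world("separable", seed = 41)
  ds <- generate_volume_dataset(w, shape = c(6, 6, 4), signal_radius = 1,
                                n_per_condition = 8, snr = 1, seed = 42,
                                signal_center = c(3, 3, 2))
  m1 <- searchlight_dds(ds, radius = 1, n_shuffles = 20, seed = 43)
  m2 <- searchlight_dds(ds, radius = 1, n_shuffles = 20, seed = 43)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$z, m2$z)
  expect_true(all(!is.na(m1$values)))
  # orthogonality map needs at least 2 voxels per sphere
  o0 <- searchlight_orthogonality(ds, radius = 0)
  expect_true(all(is.na(o0$values)))
  o1 <- searchlight_orthogonality(ds, radius = 1)
  expect_true(all(abs(o1$values[!is.na(o1$values)]) <= 1))
})

test_that("searchlight output is equivariant to spatial translation", {
  withr::with_seed(44, {
    core <- array(rnorm(5 * 5 * 4 * 24), c(5, 5, 4, 24))
  })
  tt <- tibble::tibble(level_A = rep(rep(1:2, each = 6), 2),
                       level_B = rep(1:2, each = 12))
  embed <- function(off) {
    dat <- array(0, c(8, 8, 7, 24))
    mask <- array(0L, c(8, 8, 7))
    dat[off[1] + 1:5, off[2] + 1:5, off[3] + 1:4, ] <- core
    mask[off[1] + 1:5, off[2] + 1:5, off[3] + 1:4] <- 1L
    volume_dataset(dat, mask, tt)
  }
  mA <- searchlight_dds(embed(c(0, 0, 0)), radius = 1, n_shuffles = 15,
                        seed = 45)
  mB <- searchlight_dds(embed(c(2, 1, 2)), radius = 1, n_shuffles = 15,
                        seed = 45)
  expect_identical(mA$values[1:5, 1:5, 1:4], mB$values[3:7, 2:6, 3:6])
})

test_that("null volumes give a calibrated searchlight map", {
  w <- make_world("separable", seed = 51)
  ds <- generate_volume_dataset(w, shape = c(10, 10, 6), signal_radius = 2,
                                n_per_condition = 15, snr = 0, seed = 52)
  map <- searchlight_dds(ds, radius = 2, n_shuffles = 40, seed = 53)
  v <- map$values[!is.na(map$values)]
  expect_gte(length(v), 500)
  expect_lt(abs(mean(v)), 3)  # percentile - 50 scale, null centered at 0
})

test_that("weight-orthogonality maps track the planted geometry", {
  # aligned A/B signal directions inside the sphere: |correlation| high
  w_obl <- make_world("oblique_weights", effect_size = 4, noise_sd = 0.3,
                      seed = 61)
  ds <- generate_volume_dataset(w_obl, shape = c(7, 7, 5),
                                signal_center = c(4, 4, 3),
                                signal_radius = 2, n_per_condition = 30,
                                snr = 3, seed = 62)
  om <- searchlight_orthogonality(ds, radius = 2)
  expect_gt(abs(om$values[4, 4, 3]), 0.3)
  # pure-noise data: correlations center near zero
  dsn <- generate_volume_dataset(w_obl, shape = c(7, 7, 5),
                                 signal_radius = 2, n_per_condition = 30,
                                 snr = 0, seed = 63)
  on <- searchlight_orthogonality(dsn, radius = 2)
  expect_lt(abs(mean(on$values, na.rm = TRUE)), 0.15)
})

test_that("group sign-flip test is exact under exhaustive enumeration", {
  one <- array(1, c(1, 1, 1))
  maps <- rep(list(one), 8)
  res <- group_sign_flip_test(maps, n_perm = 5000, alternative = "greater")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm_used, 256)
  expect_equal(res$p_uncorrected[1, 1, 1], 1 / 256)
  # flipping every subject map negates the statistic
  resneg <- group_sign_flip_test(rep(list(-one), 8), alternative = "greater")
  expect_equal(resneg$stat[1, 1, 1], -1)
  expect_equal(resneg$p_uncorrected[1, 1, 1], 1)
  expect_error(group_sign_flip_test(list(one)), "at least 2")
  expect_error(group_sign_flip_test(list(one, array(1, c(2, 1, 1)))),
               "lattice")
})

test_that("group test is calibrated on null maps and ignores subject order", {
  maps <- withr::with_seed(71, lapply(1:12, function(s)
    array(rnorm(10 * 10 * 5), c(10, 10, 5))))
  res <- group_sign_flip_test(maps, n_perm = 500, seed = 72)
  frac <- mean(res$p_uncorrected < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  res2 <- group_sign_flip_test(rev(maps), n_perm = 500, seed = 72)
  expect_equal(res2$stat, res$stat)
})
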