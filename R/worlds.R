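#' Synthetic encoding/decoding worlds
#'
#' Builds a fully specified simulation world -- encoding model, linear
#' decoder and measurement model over a 2 x 2 stimulus grid -- for one of
#' the named regimes:
#'
#' * `"separable"`: a Gaussian tuning bank depending only on the A-value
#'   with condition-independent channel noise; encoding separability holds,
#'   so decoding separability holds for any decoder (the decoder is the
#'   unit-norm discriminant direction between the two A-levels).
#' * `"hidden_violation"`: a tuning deviation `delta` (norm
#'   `effect_size * noise_sd`) is added to condition (1,1) and the decoder
#'   is constructed orthogonal to `delta`, so encoding separability fails
#'   while decoding separability still holds.
#' * `"exposed_violation"`: a deviation of the same norm along the
#'   discriminant direction between the two target levels, with the decoder
#'   aligned to it (`b = delta / ||delta||`), so decoding means at target
#'   level 1 differ by exactly `effect_size * noise_sd` -- i.e.
#'   `effect_size` decoding-distribution SDs.
#' * `"noise_violation"`: condition (1,1)'s channel-noise covariance is
#'   scaled by `1 + effect_size`; tuning stays separable.
#' * `"orthogonal_weights"` / `"oblique_weights"`: both dimensions modulate
#'   the mean response along unit directions `u_A`, `u_B` at 90 degrees
#'   (orthogonal) or 45 degrees (oblique); used to exercise the
#'   weight-orthogonality tests.
#'
#' @param regime One of the regime names above.
#' @param n_channels Number of channels, default 4.
#' @param effect_size Violation magnitude (see regime descriptions),
#'   default 1; must be >= 0.
#' @param noise_sd Channel noise SD (independent across channels),
#'   default 1.
#' @param measurement_error_sd SD of additive measurement error applied by
#'   [generate_trials()] (identity mixing), default 0.
#' @param seed Integer seed for the seeded constructions (deviation
#'   direction, decoder null-space component).
#' @return An object of class `ddsep_world`.
#' @export
make_world <- function(regime = c("separable", "hidden_violation",
                                  "exposed_violation", "noise_violation",
                                  "orthogonal_weights", "oblique_weights"),
                       n_channels = 4, effect_size = 1, noise_sd = 1,
                       measurement_error_sd = 0, seed = 1) {
  regime <- match.arg(regime)
  if (effect_size < 0) abort("`effect_size` must be non-negative")
  grid <- stimulus_grid(2, 2)
  centers <- seq_len(n_channels)
  values_A <- (n_channels + 1) / 2 + c(-0.5, 0.5)
  tuning <- gaussian_tuning_bank(grid, centers, widths = rep(1, n_channels),
                                 gains = rep(1, n_channels),
                                 values_A = values_A)
  model <- encoding_model(grid, tuning, noise_cov = noise_sd^2)
  delta <- NULL

  discriminant_decoder <- function(model) {
    f1 <- tuning_at(model, 1, 1); f2 <- tuning_at(model, 2, 1)
    w <- f2 - f1
    w <- w / sqrt(sum(w^2))
    linear_decoder(w, beta = -sum(w * (f1 + f2)) / 2)
  }

  if (regime %in% c("hidden_violation", "exposed_violation")) {
    u <- if (regime == "exposed_violation") {
      # canonical exposed case: the deviation lies along the discriminant
      # direction between the two target levels (pointing away from the
      # other level, so it widens rather than cancels the class
      # separation), shifting the decoded dimension itself; any reasonable
      # A-decoder sees it
      w <- tuning_at(model, 1, 1) - tuning_at(model, 2, 1)
      w / sqrt(sum(w^2))
    } else {
      with_seed(seed, {
        z <- rnorm(n_channels)
        z / sqrt(sum(z^2))
      })
    }
    delta <- effect_size * noise_sd * u
    model <- apply_violation(model, delta = delta, condition = c(1, 1))
    decoder <- if (regime == "hidden_violation") {
      d <- counterexample_decoder(delta, d = 0, seed = seed + 1L)
      linear_decoder(d$weights / sqrt(sum(d$weights^2)))
    } else {
      linear_decoder(u)
    }
  } else if (regime == "noise_violation") {
    model <- apply_violation(model, condition = c(1, 1), kind = "noise",
                             noise_scale = 1 + effect_size)
    decoder <- discriminant_decoder(model)
  } else if (regime %in% c("orthogonal_weights", "oblique_weights")) {
    dirs <- with_seed(seed, {
      u_A <- rnorm(n_channels); u_A <- u_A / sqrt(sum(u_A^2))
      z <- rnorm(n_channels)
      w <- z - sum(z * u_A) * u_A
      w <- w / sqrt(sum(w^2))
      list(u_A = u_A, w = w)
    })
    ang <- if (regime == "orthogonal_weights") pi / 2 else pi / 4
    u_B <- cos(ang) * dirs$u_A + sin(ang) * dirs$w
    cond <- conditions(grid)
    base <- rowMeans(tuning)
    amp <- max(effect_size, 1) / 2
    tuning2 <- vapply(seq_len(nrow(cond)), function(k) {
      base + amp * (2 * cond$level_A[k] - 3) * dirs$u_A +
        amp * (2 * cond$level_B[k] - 3) * u_B
    }, numeric(n_channels))
    model <- encoding_model(grid, matrix(tuning2, nrow = n_channels),
                            noise_cov = noise_sd^2)
    decoder <- linear_decoder(dirs$u_A)
    attr(model, "direction_B") <- u_B
  } else {
    decoder <- discriminant_decoder(model)
  }

  mm <- measurement_model(diag(n_channels),
                          error_cov = measurement_error_sd^2)
  structure(list(regime = regime, grid = grid, encoding = model,
                 decoder = decoder, measurement = mm, delta = delta,
                 n_channels = n_channels, effect_size = effect_size,
                 noise_sd = noise_sd,
                 measurement_error_sd = measurement_error_sd, seed = seed),
            class = "ddsep_world")
}

#' @export
print.ddsep_world <- function(x, ...) {
  cat(sprintf(
    "<ddsep_world> regime '%s': %d channels, effect size %.3g, noise SD %.3g\n",
    x$regime, x$n_channels, x$effect_size, x$noise_sd))
  invisible(x)
}

#' Simulate decoded trials from a world
#'
#' Chains the representational stages for every condition of the world's
#' grid: channel responses are drawn from the encoding model, passed through
#' the measurement model, and decoded with the world's linear decoder.
#'
#' @param world A [make_world()] object.
#' @param n_per_condition Trials per condition (>= 2).
#' @param seed Integer seed; (world, n, seed) fully determine the output.
#' @return A tibble with columns `trial`, `level_A`, `level_B`,
#'   `decoded_value`.  The per-condition channel responses and measured
#'   activity patterns are attached as attributes `responses` and
#'   `patterns` (named lists of matrices).
#' @export
generate_trials <- function(world, n_per_condition, seed) {
  stopifnot(inherits(world, "ddsep_world"))
  if (n_per_condition < 2) abort("`n_per_condition` must be at least 2")
  cond <- conditions(world$grid)
  mm <- world$measurement
  out <- with_seed(seed, {
    purrr::pmap(cond, function(condition, level_A, level_B) {
      f <- tuning_at(world$encoding, level_A, level_B)
      S <- noise_at(world$encoding, level_A, level_B)
      r <- rmvnorm_psd(n_per_condition, f, S)
      a <- r %*% t(mm$mixing)
      if (any(mm$error_cov != 0))
        a <- a + rmvnorm_psd(n_per_condition, rep(0, nrow(mm$mixing)),
                             mm$error_cov)
      list(r = r, a = a,
           tbl = tibble::tibble(level_A = level_A, level_B = level_B,
                                decoded_value = decode(world$decoder, a)))
    })
  })
  tbl <- dplyr::bind_rows(lapply(out, `[[`, "tbl"))
  tbl <- dplyr::mutate(tbl, trial = dplyr::row_number(),
                       .before = "level_A")
  nm <- paste0("A", cond$level_A, "B", cond$level_B)
  attr(tbl, "responses") <- stats::setNames(lapply(out, `[[`, "r"), nm)
  attr(tbl, "patterns") <- stats::setNames(lapply(out, `[[`, "a"), nm)
  tbl
}

#' Generate a volumetric dataset with a planted signal sphere
#'
#' Produces a 4-D volume (x, y, z, trial) in which voxels inside a signal
#' sphere carry a linear mixture of the world's channel responses while all
#' other voxels contain i.i.d. Gaussian measurement noise.  The mixing
#' coefficients are drawn once (seeded) with SD `snr * noise_sd_vox`, so
#' `snr` is the ratio of the mixing-coefficient scale to the voxel noise SD
#' and `snr = 0` yields a pure-noise volume.
#'
#' @param world A [make_world()] object.
#' @param shape Volume dimensions, default `c(20, 20, 20)`.
#' @param signal_center Voxel coordinates (1-based) of the signal sphere's
#'   center; defaults to the volume center.
#' @param signal_radius Sphere radius in voxels, default 4.
#' @param n_per_condition Trials per condition.
#' @param snr Signal-to-noise knob as defined above, default 1.
#' @param noise_sd_vox Voxel noise SD, default 1.
#' @param seed Integer seed.
#' @return A [volume_dataset()] with attributes `signal_center`,
#'   `signal_radius`, `signal_voxels` (count).
#' @export
generate_volume_dataset <- function(world, shape = c(20, 20, 20),
                                    signal_center = NULL, signal_radius = 4,
                                    n_per_condition, snr = 1,
                                    noise_sd_vox = 1, seed) {
  stopifnot(inherits(world, "ddsep_world"))
  signal_center <- signal_center %||% ceiling(shape / 2)
  offs <- sphere_offsets(signal_radius)
  vox <- sweep(offs, 2, signal_center, "+")
  inside <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
    vox[, 2] >= 1 & vox[, 2] <= shape[2] &
    vox[, 3] >= 1 & vox[, 3] <= shape[3]
  if (!all(inside)) abort("signal sphere extends outside the volume")
  cond <- conditions(world$grid)
  n_trials <- n_per_condition * nrow(cond)
  trial_table <- tibble::tibble(
    trial = seq_len(n_trials),
    level_A = rep(cond$level_A, each = n_per_condition),
    level_B = rep(cond$level_B, each = n_per_condition)
  )
  V <- nrow(vox)
  N <- world$n_channels
  dat <- with_seed(seed, {
    arr <- array(rnorm(prod(shape) * n_trials, sd = noise_sd_vox),
                 dim = c(shape, n_trials))
    if (snr > 0) {
      mixing <- matrix(rnorm(V * N, sd = snr * noise_sd_vox), V, N)
      lin <- vox[, 1] + (vox[, 2] - 1) * shape[1] +
        (vox[, 3] - 1) * shape[1] * shape[2]
      flat <- matrix(arr, prod(shape), n_trials)
      for (t in seq_len(n_trials)) {
        f <- tuning_at(world$encoding, trial_table$level_A[t],
                       trial_table$level_B[t])
        S <- noise_at(world$encoding, trial_table$level_A[t],
                      trial_table$level_B[t])
        r <- drop(rmvnorm_psd(1, f, S))
        flat[lin, t] <- flat[lin, t] + drop(mixing %*% r)
      }
      arr <- array(flat, dim = c(shape, n_trials))
    }
    arr
  })
  ds <- volume_dataset(dat, mask = array(1L, dim = shape),
                       trial_table = trial_table)
  attr(ds, "signal_center") <- signal_center
  attr(ds, "signal_radius") <- signal_radius
  attr(ds, "signal_voxels") <- V
  ds
}
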