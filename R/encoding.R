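#' Gaussian tuning bank over a stimulus grid
#'
#' Builds an N-channel tuning matrix in which channel c responds to the
#' stimulus value on dimension A with a Gaussian (bell-shaped) tuning curve
#' `gain_c * exp(-(v_A(i) - center_c)^2 / (2 width_c^2))`.  The bank depends
#' only on the A-value, so it is tuning-separable by construction; violations
#' are introduced afterwards with [apply_violation()].  Sigmoidal or other
#' tuning shapes can be supplied directly as a numeric matrix wherever a
#' tuning bank is accepted.
#'
#' @param grid A [stimulus_grid()].
#' @param centers Preferred A-values, one per channel.
#' @param widths Tuning widths (SD of the Gaussian bump), one per channel,
#'   all positive.
#' @param gains Peak responses, one per channel, all positive.
#' @param values_A Real stimulus values for the levels of A (length
#'   `grid$levels_A`).  The latent dimension has no canonical units; values
#'   are user-declared reals.
#' @param values_B Optional values for levels of B (stored for reference;
#'   the baseline bank does not use them).
#' @return An `N x (L_A * L_B)` matrix with one column per condition in
#'   row-major `(i, j)` order, with attribute `values_A`/`values_B`.
#' @examples
#' g <- stimulus_grid(2, 2)
#' gaussian_tuning_bank(g, centers = 1:4, widths = rep(1, 4),
#'                      gains = rep(1, 4), values_A = c(2, 3))
#' @export
gaussian_tuning_bank <- function(grid, centers, widths, gains, values_A,
                                 values_B = NULL) {
  stopifnot(inherits(grid, "stimulus_grid"))
  N <- length(centers)
  if (N == 0) abort("at least one channel is required")
  if (length(widths) != N || length(gains) != N)
    abort("`centers`, `widths` and `gains` must have the same length")
  if (any(widths <= 0)) abort("tuning widths must be positive")
  if (any(gains <= 0)) abort("channel gains must be positive")
  if (length(values_A) != grid$levels_A)
    abort("`values_A` must give one stimulus value per level of A")
  cond <- conditions(grid)
  tuning <- vapply(seq_len(nrow(cond)), function(k) {
    v <- values_A[cond$level_A[k]]
    gains * exp(-(v - centers)^2 / (2 * widths^2))
  }, numeric(N))
  tuning <- matrix(tuning, nrow = N)
  dimnames(tuning) <- list(paste0("ch", seq_len(N)),
                           paste0("A", cond$level_A, "B", cond$level_B))
  attr(tuning, "values_A") <- values_A
  attr(tuning, "values_B") <- values_B
  tuning
}

#' Multichannel Gaussian encoding model
#'
#' An encoding model is a bank of tuning functions plus per-condition channel
#' noise: the response vector to stimulus `A_i B_j` is distributed
#' `N(f(A_i B_j), Sigma(A_i B_j))`.
#'
#' @param grid A [stimulus_grid()].
#' @param tuning An `N x (L_A * L_B)` tuning matrix (columns in row-major
#'   condition order), e.g. from [gaussian_tuning_bank()].
#' @param noise_cov Either a single non-negative scalar variance (expanded to
#'   `sigma^2 * I` for every condition, i.e. independent channel noise), one
#'   `N x N` covariance shared by all conditions, or a list of per-condition
#'   `N x N` covariances.  All covariances must be symmetric positive
#'   semidefinite.
#' @return An object of class `encoding_model`.
#' @export
encoding_model <- function(grid, tuning, noise_cov = 1) {
  stopifnot(inherits(grid, "stimulus_grid"))
  tuning <- as.matrix(tuning)
  n_cond <- grid$levels_A * grid$levels_B
  if (ncol(tuning) != n_cond)
    abort("tuning matrix must have one column per condition")
  if (!all(is.finite(tuning))) abort("tuning values must be finite")
  N <- nrow(tuning)
  if (is.numeric(noise_cov) && length(noise_cov) == 1) {
    if (noise_cov < 0) abort("scalar noise variance must be non-negative")
    noise_cov <- rep(list(diag(noise_cov, N)), n_cond)
  } else if (is.matrix(noise_cov)) {
    noise_cov <- rep(list(noise_cov), n_cond)
  }
  if (!is.list(noise_cov) || length(noise_cov) != n_cond)
    abort("`noise_cov` must be a scalar, a matrix, or one matrix per condition")
  noise_cov <- lapply(noise_cov, function(m) {
    m <- as.matrix(m)
    if (!identical(dim(m), c(N, N)) && !all(dim(m) == N))
      abort("covariance dimensions must match the number of channels")
    if (!is_psd(m))
      abort("channel noise covariances must be symmetric positive semidefinite")
    unname(m)
  })
  structure(list(grid = grid, tuning = tuning, noise_cov = noise_cov),
            class = "encoding_model")
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf("<encoding_model> %d channels over a %d x %d stimulus grid\n",
              nrow(x$tuning), x$grid$levels_A, x$grid$levels_B))
  invisible(x)
}

# Mean vector / covariance of condition (i, j).
tuning_at <- function(model, i, j) {
  model$tuning[, condition_index(model$grid, i, j)]
}
noise_at <- function(model, i, j) {
  model$noise_cov[[condition_index(model$grid, i, j)]]
}

#' Inject an encoding-separability violation into a model
#'
#' A tuning violation adds a deviation vector `delta` to the tuning column of
#' one condition (so that, e.g., `f(A1B1) = f(A1B2) + delta`); a noise
#' violation rescales that condition's channel-noise covariance.  All other
#' conditions are untouched.  Applying the inverse (`-delta`, or
#' `1/noise_scale`) restores the model exactly.
#'
#' @param model An [encoding_model()].
#' @param delta Deviation vector (length N); used when `kind = "tuning"`.
#' @param condition Target condition as `c(i, j)`.
#' @param kind `"tuning"` or `"noise"`.
#' @param noise_scale Positive factor applied to the target condition's
#'   covariance when `kind = "noise"`.
#' @return The modified `encoding_model`.
#' @export
apply_violation <- function(model, delta = NULL, condition,
                            kind = c("tuning", "noise"), noise_scale = NULL) {
  stopifnot(inherits(model, "encoding_model"))
  kind <- match.arg(kind)
  k <- condition_index(model$grid, condition[1], condition[2])
  if (kind == "tuning") {
    if (is.null(delta) || length(delta) != nrow(model$tuning))
      abort("`delta` must have one entry per channel")
    if (!all(is.finite(delta))) abort("`delta` must be finite")
    model$tuning[, k] <- model$tuning[, k] + delta
  } else {
    if (is.null(noise_scale) || noise_scale <= 0)
      abort("`noise_scale` must be a positive factor")
    model$noise_cov[[k]] <- model$noise_cov[[k]] * noise_scale
  }
  model
}

#' Sample channel responses for one condition
#'
#' Draws i.i.d. multivariate-Gaussian response vectors distributed as
#' `N(f(A_i B_j), Sigma(A_i B_j))`.
#'
#' @param model An [encoding_model()].
#' @param condition Condition as `c(i, j)`.
#' @param n Number of trials (>= 1).
#' @param seed Integer seed; identical seed and parameters give identical
#'   samples.
#' @return An `n x N` matrix of channel responses.
#' @export
sample_responses <- function(model, condition, n, seed) {
  stopifnot(inherits(model, "encoding_model"))
  if (n < 1) abort("`n` must be at least 1")
  f <- tuning_at(model, condition[1], condition[2])
  S <- noise_at(model, condition[1], condition[2])
  with_seed(seed, rmvnorm_psd(n, f, S))
}

#' Analytic check of encoding separability
#'
#' Encoding separability of the target dimension holds when both the tuning
#' vector and the channel-noise covariance of every target level are
#' invariant across levels of the irrelevant dimension.  The check is exact
#' (models are analytic objects): the reported gaps are sup-norm differences
#' across irrelevant-dimension levels, compared against an absolute
#' tolerance.
#'
#' @param model An [encoding_model()].
#' @param target_dim `"A"` (default) or `"B"`: the dimension whose encoding
#'   invariance is checked across the other dimension.
#' @param tol Absolute tolerance, default `1e-10`.
#' @return A list with `tuning_separable`, `noise_separable`,
#'   `encoding_separable`, `max_tuning_gap`, `max_cov_gap`.
#' @export
check_encoding_separability <- function(model, target_dim = c("A", "B"),
                                        tol = 1e-10) {
  stopifnot(inherits(model, "encoding_model"))
  target_dim <- match.arg(target_dim)
  g <- model$grid
  n_t <- if (target_dim == "A") g$levels_A else g$levels_B
  n_i <- if (target_dim == "A") g$levels_B else g$levels_A
  at <- function(t, v) if (target_dim == "A") list(t, v) else list(v, t)
  tun_gap <- 0
  cov_gap <- 0
  for (t in seq_len(n_t)) {
    for (v1 in seq_len(n_i - 1)) for (v2 in seq(v1 + 1, n_i)) {
      ix1 <- at(t, v1); ix2 <- at(t, v2)
      f1 <- tuning_at(model, ix1[[1]], ix1[[2]])
      f2 <- tuning_at(model, ix2[[1]], ix2[[2]])
      S1 <- noise_at(model, ix1[[1]], ix1[[2]])
      S2 <- noise_at(model, ix2[[1]], ix2[[2]])
      tun_gap <- max(tun_gap, max(abs(f1 - f2)))
      cov_gap <- max(cov_gap, max(abs(S1 - S2)))
    }
  }
  list(tuning_separable = tun_gap <= tol,
       noise_separable = cov_gap <= tol,
       encoding_separable = tun_gap <= tol && cov_gap <= tol,
       max_tuning_gap = tun_gap,
       max_cov_gap = cov_gap)
}
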