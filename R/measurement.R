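#' Linear measurement model
#'
#' Maps N channel responses to M indirect activity measures (voxels,
#' electrodes) as `a = B r + e`, with additive Gaussian measurement error
#' `e ~ N(0, Sigma_e)`.  The error model is stimulus-independent, which is
#' what licenses the convolution identity behind
#' [predicted_noisy_difference()].
#'
#' @param mixing `M x N` mixing matrix B.
#' @param error_cov `M x M` error covariance (or a scalar variance expanded
#'   to `sigma^2 * I`).
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(mixing, error_cov = 0) {
  mixing <- as.matrix(mixing)
  if (!all(is.finite(mixing))) abort("mixing matrix must be finite")
  M <- nrow(mixing)
  if (is.numeric(error_cov) && length(error_cov) == 1) {
    if (error_cov < 0) abort("scalar error variance must be non-negative")
    error_cov <- diag(error_cov, M)
  }
  error_cov <- as.matrix(error_cov)
  if (!all(dim(error_cov) == M))
    abort("error covariance must be M x M")
  if (!is_psd(error_cov))
    abort("error covariance must be symmetric positive semidefinite")
  structure(list(mixing = mixing, error_cov = unname(error_cov)),
            class = "measurement_model")
}

#' @export
print.measurement_model <- function(x, ...) {
  cat(sprintf("<measurement_model> %d measures from %d channels\n",
              nrow(x$mixing), ncol(x$mixing)))
  invisible(x)
}

#' Pass channel responses through a measurement model
#'
#' @param mm A [measurement_model()].
#' @param responses `n x N` channel-response matrix.
#' @param seed Integer seed for the measurement-error draws (may be omitted
#'   when the error covariance is all zero).
#' @return `n x M` matrix of activity patterns `a_t = B r_t + e_t`.
#' @export
measure <- function(mm, responses, seed = NULL) {
  stopifnot(inherits(mm, "measurement_model"))
  responses <- as.matrix(responses)
  if (ncol(responses) != ncol(mm$mixing))
    abort("response columns must match the mixing matrix")
  clean <- responses %*% t(mm$mixing)
  if (all(mm$error_cov == 0)) return(clean)
  err <- with_seed(seed,
                   rmvnorm_psd(nrow(responses), rep(0, nrow(mm$mixing)),
                               mm$error_cov))
  clean + err
}

#' Difference function between two decoding densities
#'
#' A difference function pairs a uniform evaluation grid with the pointwise
#' difference between two probability densities of decoded values; its L1
#' norm is the basis of the DDS statistic.
#'
#' @param grid Strictly increasing, uniformly spaced evaluation points.
#' @param values Difference values at the grid points.
#' @return An object of class `difference_function` (a tibble with columns
#'   `grid`, `value`).
#' @export
difference_function <- function(grid, values) {
  if (length(grid) != length(values))
    abort("grid and values must have equal length")
  if (length(grid) >= 2) {
    dx <- diff(grid)
    if (any(dx <= 0) || max(abs(dx - dx[1])) > 1e-8 * max(abs(dx)))
      abort("grid must be strictly increasing and uniformly spaced")
  }
  structure(tibble::tibble(grid = as.numeric(grid),
                           value = as.numeric(values)),
            class = c("difference_function", class(tibble::tibble())))
}

#' Predicted difference function under measurement error
#'
#' Decoding from noisy measurements convolves every decoding density with a
#' zero-mean Gaussian error kernel of variance `b' Sigma_e b`, so the
#' difference between two such densities is the clean difference convolved
#' with that same kernel.  The convolution is computed directly on the
#' (uniform) grid with a kernel truncated at +/- 6 SD and zero padding; it
#' preserves the integral of the difference function and can only attenuate
#' its sup-norm.
#'
#' @param clean A [difference_function()] on a uniform grid.
#' @param decoder A [linear_decoder()] with `trained_on = "measurements"`.
#' @param mm The [measurement_model()] supplying `Sigma_e`.
#' @return A `difference_function` on the same grid.
#' @export
predicted_noisy_difference <- function(clean, decoder, mm) {
  stopifnot(inherits(clean, "difference_function"),
            inherits(decoder, "linear_decoder"),
            inherits(mm, "measurement_model"))
  if (decoder$trained_on != "measurements")
    abort("the error kernel applies to a measurement-space decoder")
  b <- decoder$weights
  if (length(b) != nrow(mm$mixing))
    abort("decoder weight length must match the number of measures")
  v <- drop(t(b) %*% mm$error_cov %*% b)
  if (v <= 0) return(clean)
  dx <- clean$grid[2] - clean$grid[1]
  sd_k <- sqrt(v)
  half <- ceiling(6 * sd_k / dx)
  kern <- dnorm(seq(-half, half) * dx, sd = sd_k) * dx
  n <- nrow(clean)
  padded <- c(rep(0, half), clean$value, rep(0, half))
  out <- vapply(seq_len(n), function(k) {
    sum(padded[k:(k + 2 * half)] * rev(kern))
  }, numeric(1))
  difference_function(clean$grid, out)
}
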