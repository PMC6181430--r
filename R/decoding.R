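#' Linear decoder
#'
#' A linear decoder maps an activity vector to a scalar decoded value
#' `A_hat = beta + b' r`.  Decoders can be written down directly, fitted
#' from labelled activity with [fit_linear_classifier()], or constructed to
#' hide or expose a given tuning violation with
#' [counterexample_decoder()].
#'
#' @param weights Numeric weight vector `b`.
#' @param beta Scalar intercept, default 0.
#' @param trained_on `"channels"` or `"measurements"`: which representational
#'   stage the weights live in.
#' @return An object of class `linear_decoder`.
#' @export
linear_decoder <- function(weights, beta = 0,
                           trained_on = c("channels", "measurements")) {
  trained_on <- match.arg(trained_on)
  weights <- as.numeric(weights)
  if (!all(is.finite(weights)) || !is.finite(beta))
    abort("decoder weights and intercept must be finite")
  structure(list(weights = weights, beta = as.numeric(beta),
                 trained_on = trained_on),
            class = "linear_decoder")
}

#' @export
print.linear_decoder <- function(x, ...) {
  cat(sprintf("<linear_decoder> %d weights on %s (beta = %.4g)\n",
              length(x$weights), x$trained_on, x$beta))
  invisible(x)
}

#' Decode activity to scalar values
#'
#' @param decoder A [linear_decoder()].
#' @param activity An `n x K` activity matrix (or a length-K vector for a
#'   single trial); K must match the decoder's weight length.
#' @return A numeric vector of decoded values, one per row.
#' @examples
#' d <- linear_decoder(c(2, -1))
#' decode(d, c(3, 4))  # 2
#' @export
decode <- function(decoder, activity) {
  stopifnot(inherits(decoder, "linear_decoder"))
  if (is.null(dim(activity))) activity <- matrix(activity, nrow = 1)
  if (ncol(activity) != length(decoder$weights))
    abort("activity columns must match decoder weight length")
  drop(activity %*% decoder$weights) + decoder$beta
}

#' Closed-form decoding distribution
#'
#' With Gaussian channel noise and a linear decoder, the decoded value for
#' condition `A_i B_j` is Gaussian with mean `beta + b' f(A_i B_j)` and
#' variance `b' Sigma(A_i B_j) b`.  When channel noise is independent the
#' variance reduces to `sum_k b_k^2 sigma_k^2`.
#'
#' @param model An [encoding_model()].
#' @param decoder A [linear_decoder()] with `trained_on = "channels"`.
#' @param condition Optional `c(i, j)`; by default all conditions.
#' @return A tibble with columns `level_A`, `level_B`, `mean`, `var`.
#' @export
decoding_distribution <- function(model, decoder, condition = NULL) {
  stopifnot(inherits(model, "encoding_model"),
            inherits(decoder, "linear_decoder"))
  if (decoder$trained_on != "channels")
    abort("closed-form decoding distributions need a channel-space decoder")
  if (length(decoder$weights) != nrow(model$tuning))
    abort("decoder weight length must match the number of channels")
  cond <- conditions(model$grid)
  if (!is.null(condition))
    cond <- dplyr::filter(cond, .data$level_A == condition[1],
                          .data$level_B == condition[2])
  b <- decoder$weights
  dplyr::mutate(
    cond,
    mean = purrr::map2_dbl(.data$level_A, .data$level_B,
                           ~ decoder$beta + sum(b * tuning_at(model, .x, .y))),
    var = purrr::map2_dbl(.data$level_A, .data$level_B,
                          ~ drop(t(b) %*% noise_at(model, .x, .y) %*% b))
  )[, c("level_A", "level_B", "mean", "var")]
}

#' Fit a linear maximum-margin classifier and return it as a decoder
#'
#' Fits a soft-margin linear support vector machine to binary-labelled
#' activity patterns (pooling all trials handed in) and converts the
#' separating hyperplane into a [linear_decoder()]: weights are the
#' unit-normalized hyperplane normal and the intercept is set so decoded
#' values are signed distances to the decision boundary.  The solver is
#' deterministic given the data and settings.
#'
#' @param activity `n x K` activity matrix.
#' @param labels Binary labels (factor, character or numeric with exactly two
#'   distinct values); the higher/second level is mapped to positive decoded
#'   values.
#' @param cost Soft-margin cost parameter, default 1.
#' @param trained_on Tag recorded on the decoder.
#' @return A `linear_decoder` with extra fields `training_accuracy` and
#'   `levels`.
#' @export
fit_linear_classifier <- function(activity, labels, cost = 1,
                                  trained_on = c("channels", "measurements")) {
  trained_on <- match.arg(trained_on)
  activity <- as.matrix(activity)
  y <- factor(labels)
  if (nlevels(y) != 2) abort("exactly two classes are required")
  if (nrow(activity) < 4) abort("at least 4 training patterns are required")
  fit <- e1071::svm(activity, y, type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  nw <- sqrt(sum(w^2))
  if (nw == 0) abort("degenerate classifier: zero weight vector")
  # libsvm's decision value is w.x - rho with positive side = first factor
  # level; flip so the second level scores positive.
  sgn <- if (fit$labels[1] == 1) -1 else 1
  dec <- linear_decoder(sgn * w / nw, beta = -sgn * rho / nw, trained_on)
  dec$levels <- levels(y)
  dec$cost <- cost
  dec$training_accuracy <- mean(predict(fit, activity) == y)
  dec
}

#' Construct a decoder that hides or exposes a tuning violation
#'
#' For a tuning deviation `delta != 0` there are infinitely many weight
#' vectors `b != 0` with a prescribed inner product `b' delta = d`: with
#' `d = 0` the decoder hides the encoding violation (decoding separability
#' holds anyway) and with `d != 0` it exposes it as a mean shift of exactly
#' `d` between decoding distributions.  The construction takes the
#' minimum-norm particular solution `d * delta / ||delta||^2` plus a seeded
#' random component from the null space of `delta`, making the "infinitely
#' many" choice reproducible.
#'
#' @param delta Tuning deviation vector (non-zero).
#' @param d Target inner product `b' delta`.
#' @param seed Integer seed for the null-space component.
#' @param null_scale Magnitude of the null-space component relative to the
#'   particular solution (default 1).
#' @return A [linear_decoder()] whose weights satisfy
#'   `|b' delta - d| <= 1e-10`.
#' @export
counterexample_decoder <- function(delta, d = 0, seed = 1, null_scale = 1) {
  delta <- as.numeric(delta)
  nd2 <- sum(delta^2)
  if (nd2 == 0) {
    if (d != 0) abort("`b' delta = d` is infeasible for delta = 0, d != 0")
    abort("`delta` must be non-zero to encode a genuine violation")
  }
  part <- d * delta / nd2
  b <- with_seed(seed, {
    for (. in 1:100) {
      z <- rnorm(length(delta))
      null_comp <- z - sum(z * delta) / nd2 * delta
      nn <- sqrt(sum(null_comp^2))
      if (nn > 1e-8 || d != 0) break
    }
    scale_to <- if (nn > 1e-8) null_scale * max(sqrt(sum(part^2)), 1) else 0
    b <- part + if (nn > 1e-8) null_comp / nn * scale_to else 0
    # delta spans the space (N = 1): the particular solution alone
    if (sum(b^2) == 0) b <- part
    b
  })
  if (sum(b^2) == 0) abort("could not construct a non-zero decoder")
  linear_decoder(b, beta = 0, trained_on = "channels")
}
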