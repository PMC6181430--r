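#' Raw DDS statistic for a 2 x 2 design
#'
#' Sums, over both levels of the target dimension and all grid points, the
#' absolute difference between kernel density estimates of decoded values at
#' the two levels of the irrelevant dimension.  The evaluation grid is built
#' once from all four conditions' decoded values pooled (guaranteeing a
#' common support) and each KDE uses Scott's-rule bandwidth computed from
#' its own subsample.
#'
#' @param data A data frame of decoded trials with columns `level_A`,
#'   `level_B` (two levels each) and `decoded_value`.
#' @param target `"A"` or `"B"`: the dimension whose decoding invariance is
#'   tested across the other.
#' @param n_points Grid points for the KDEs, default 1000.
#' @return Non-negative scalar (raw density scale, no grid-spacing factor).
#' @seealso [dds_test()] for the permutation-standardized index.
#' @export
dds_statistic <- function(data, target = c("A", "B"), n_points = 1000) {
  target <- match.arg(target)
  parts <- dds_split(data, target)
  grid <- build_eval_grid(c(parts$x1, parts$x2), n_points)
  dds_perm_cpp(parts$x1, cbind(parts$lab1), parts$x2, cbind(parts$lab2),
               as.numeric(grid))[1]
}

# Split decoded trials into pooled values + 0/1 irrelevant-dimension labels
# per target level; validates the 2 x 2 layout.
dds_split <- function(data, target) {
  data <- tibble::as_tibble(data)
  need <- c("level_A", "level_B", "decoded_value")
  if (!all(need %in% names(data)))
    abort("`data` needs columns level_A, level_B, decoded_value")
  tcol <- if (target == "A") "level_A" else "level_B"
  icol <- if (target == "A") "level_B" else "level_A"
  tl <- sort(unique(data[[tcol]]))
  il <- sort(unique(data[[icol]]))
  if (length(tl) != 2 || length(il) != 2)
    abort("the DDS test requires a 2 x 2 design (two levels per dimension)")
  pick <- function(lv) {
    d <- data[data[[tcol]] == lv, ]
    lab <- as.integer(d[[icol]] == il[2])
    if (sum(lab == 0) < 2 || sum(lab == 1) < 2)
      abort("each of the four conditions needs at least 2 trials")
    list(x = d$decoded_value, lab = lab)
  }
  p1 <- pick(tl[1]); p2 <- pick(tl[2])
  list(x1 = p1$x, lab1 = p1$lab, x2 = p2$x, lab2 = p2$lab,
       target_levels = tl, irrelevant_levels = il)
}

#' Permutation-standardized DDS test of decoding separability
#'
#' Computes the raw DDS statistic and standardizes it against an empirical
#' distribution function (EDF) obtained by shuffling the
#' irrelevant-dimension label of every trial, separately within each level
#' of the target dimension (trials are exchangeable across those labels
#' under the null of decoding separability).  Two reporting scales are
#' returned: the percentile of the observed DDS in the EDF minus 50 (used
#' for maps; null-centered at 0) and the raw proportion (null-centered at
#' 0.5).  Percentile ties are resolved with the mid-rank convention.
#'
#' @inheritParams dds_statistic
#' @param n_shuffles Number of label shuffles for the EDF, default 200.
#' @param seed Integer seed for the shuffles.
#' @param include_observed If `TRUE`, the observed DDS is pooled into its
#'   own EDF before ranking (default `FALSE`: the EDF holds only the
#'   `n_shuffles` shuffled values).
#' @return An object of class `dds_test` with fields `raw`, `edf`,
#'   `proportion`, `percentile`, `standardized_percentile`, `n_shuffles`,
#'   `seed`, `target`, `n_trials`.
#' @examples
#' w <- make_world("separable", seed = 1)
#' trials <- generate_trials(w, n_per_condition = 50, seed = 2)
#' fit <- dds_test(trials, target = "A", seed = 3)
#' glance(fit)
#' @export
dds_test <- function(data, target = c("A", "B"), n_shuffles = 200, seed,
                     n_points = 1000, include_observed = FALSE) {
  target <- match.arg(target)
  if (n_shuffles < 1) abort("`n_shuffles` must be at least 1")
  fit <- with_seed(seed,
                   dds_test_impl(data, target, n_shuffles, n_points,
                                 include_observed = include_observed))
  structure(
    c(fit,
      list(standardized_percentile = fit$percentile - 50,
           n_shuffles = n_shuffles, seed = seed, target = target)),
    class = "dds_test")
}

#' @export
print.dds_test <- function(x, ...) {
  cat(sprintf(paste0(
    "<dds_test> target dimension %s, %d trials\n",
    "  raw DDS: %.4f  (EDF of %d shuffles: median %.4f)\n",
    "  standardized: proportion %.3f (null 0.5), percentile - 50 = %.1f\n"),
    x$target, x$n_trials, x$raw, x$n_shuffles, stats::median(x$edf),
    x$proportion, x$standardized_percentile))
  invisible(x)
}

#' @rdname dds_test
#' @param x A `dds_test` object.
#' @param ... Unused.
#' @method tidy dds_test
#' @export
tidy.dds_test <- function(x, ...) {
  tibble::tibble(
    statistic = c("raw_dds", "proportion", "percentile_minus_50"),
    value = c(x$raw, x$proportion, x$standardized_percentile)
  )
}

#' @rdname dds_test
#' @method glance dds_test
#' @export
glance.dds_test <- function(x, ...) {
  tibble::tibble(
    raw_dds = x$raw, proportion = x$proportion,
    percentile_minus_50 = x$standardized_percentile,
    n_shuffles = x$n_shuffles, n_trials = x$n_trials,
    target = x$target, seed = x$seed
  )
}

#' @rdname dds_test
#' @param object A `dds_test` object.
#' @method autoplot dds_test
#' @export
autoplot.dds_test <- function(object, ...) {
  df <- tibble::tibble(dds = object$edf)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dds)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$raw, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(
      x = "DDS under shuffled irrelevant-dimension labels",
      y = "count",
      title = sprintf("Observed DDS at the %.1f percentile of the null EDF",
                      object$percentile)) +
    ggplot2::theme_minimal()
}
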