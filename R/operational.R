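#' Classification accuracy table from closed-form decoding distributions
#'
#' Given Gaussian decoding distributions per condition and a partition of
#' the decoded-value line into response regions (one region per target
#' level), computes the probability of a correct classification
#' `P(l_i | A_i B_j)` as the probability mass of condition `(i, j)`'s
#' decoding distribution inside region `R_i`.  Under decoding separability
#' the table's rows are constant across the irrelevant dimension.
#'
#' @param dists A tibble as returned by [decoding_distribution()] (columns
#'   `level_A`, `level_B`, `mean`, `var`).
#' @param regions A list with one `c(lower, upper)` interval per target
#'   level; together the intervals must partition the real line (disjoint,
#'   contiguous, covering `(-Inf, Inf)`).
#' @param target `"A"` or `"B"`.
#' @return An object of class `accuracy_table`: a tibble with columns
#'   `level_target`, `level_irrelevant`, `accuracy` and attribute `chance`
#'   (`1 / number of target levels`).
#' @examples
#' # N(1,1) decoding distribution, region [0, Inf): P = pnorm(1)
#' @export
accuracy_table <- function(dists, regions, target = c("A", "B")) {
  target <- match.arg(target)
  tcol <- if (target == "A") "level_A" else "level_B"
  icol <- if (target == "A") "level_B" else "level_A"
  lv <- sort(unique(dists[[tcol]]))
  if (length(regions) != length(lv))
    abort("one response region per target level is required")
  m <- do.call(rbind, regions)
  o <- order(m[, 1])
  if (m[o[1], 1] != -Inf || m[o[length(o)], 2] != Inf ||
      (length(o) > 1 && any(m[o[-length(o)], 2] != m[o[-1], 1])))
    abort("regions must partition the real line (disjoint and covering)")
  tbl <- tibble::tibble(
    level_target = dists[[tcol]],
    level_irrelevant = dists[[icol]],
    accuracy = purrr::pmap_dbl(
      list(dists[[tcol]], dists$mean, dists$var),
      function(i, mu, v) {
        r <- regions[[match(i, lv)]]
        s <- sqrt(v)
        if (s == 0) return(as.numeric(mu >= r[1] && mu < r[2]))
        pnorm(r[2], mu, s) - pnorm(r[1], mu, s)
      })
  )
  structure(tbl, chance = 1 / length(lv),
            class = c("accuracy_table", class(tbl)))
}

#' Invariance and generalization verdicts for a classification table
#'
#' Classification accuracy *invariance* holds when, for every target level,
#' accuracy is identical (within `tol`) across levels of the irrelevant
#' dimension.  Classification accuracy *generalization* (a strictly weaker
#' property) holds when above-chance accuracy at the first irrelevant level
#' implies above-chance accuracy at every other level.  Invariance implies
#' generalization but not conversely.
#'
#' @param table An [accuracy_table()], or any data frame with columns
#'   `level_target`, `level_irrelevant`, `accuracy`.
#' @param chance Chance accuracy; defaults to the table's `chance`
#'   attribute.
#' @param tol Absolute tolerance for the invariance comparison; the default
#'   `1e-9` suits analytic tables (use a resampling criterion for empirical
#'   ones).
#' @return A list with logical `invariance` and `generalization` and the
#'   observed `max_gap`.
#' @export
accuracy_invariance <- function(table, chance = NULL, tol = 1e-9) {
  chance <- chance %||% attr(table, "chance")
  if (is.null(chance)) abort("`chance` accuracy is required")
  by_lvl <- split(table$accuracy, table$level_target)
  gaps <- vapply(by_lvl, function(a) diff(range(a)), numeric(1))
  gen <- vapply(by_lvl, function(a) {
    if (a[1] > chance) all(a > chance) else TRUE
  }, logical(1))
  list(invariance = max(gaps) <= tol,
       generalization = all(gen),
       max_gap = max(gaps))
}

#' Orthogonality of two weight vectors
#'
#' Measures the angle between the weight (or summary) vectors associated
#' with the two stimulus dimensions in a common space.  Both the cosine of
#' the angle and the Pearson correlation of the two vectors are reported:
#' the correlation equals the cosine of the angle between the *mean-centered*
#' vectors, so the two coincide only for centered vectors.
#'
#' @param w_A,w_B Non-zero numeric vectors of equal length.
#' @return A list with `cosine`, `angle_deg` and `pearson`.
#' @examples
#' orthogonality_index(c(1, 0, 0), c(0, 1, 0))  # cosine 0, angle 90
#' @export
orthogonality_index <- function(w_A, w_B) {
  w_A <- as.numeric(w_A); w_B <- as.numeric(w_B)
  if (length(w_A) != length(w_B)) abort("vectors must have equal length")
  nA <- sqrt(sum(w_A^2)); nB <- sqrt(sum(w_B^2))
  if (nA == 0 || nB == 0) abort("zero vectors have no direction")
  cosine <- sum(w_A * w_B) / (nA * nB)
  cosine <- max(-1, min(1, cosine))
  pearson <- if (length(w_A) > 1 && sd(w_A) > 0 && sd(w_B) > 0)
    cor(w_A, w_B) else NA_real_  # undefined for constant vectors
  list(cosine = cosine,
       angle_deg = acos(cosine) * 180 / pi,
       pearson = pearson)
}

#' Pattern-difference invariance test
#'
#' Tests whether the mean activity-pattern difference between the two levels
#' of the target dimension changes across levels of the irrelevant
#' dimension.  The interaction vector is
#' `[mean(A1B1) - mean(A2B1)] - [mean(A1B2) - mean(A2B2)]`; its Euclidean
#' norm is the test statistic, and the permutation p-value is obtained by
#' shuffling irrelevant-dimension labels within each target level.
#'
#' @param data A data frame with columns `level_A`, `level_B` (two levels
#'   each) and one numeric column per activity measure.
#' @param n_perm Number of permutations, default 1000.
#' @param seed Integer seed.
#' @param target `"A"` or `"B"`.
#' @return A list with `interaction_vector`, `statistic` (its norm) and
#'   `permutation_p`.
#' @export
pattern_difference_test <- function(data, n_perm = 1000, seed,
                                    target = c("A", "B")) {
  target <- match.arg(target)
  data <- tibble::as_tibble(data)
  tcol <- if (target == "A") "level_A" else "level_B"
  icol <- if (target == "A") "level_B" else "level_A"
  tl <- sort(unique(data[[tcol]])); il <- sort(unique(data[[icol]]))
  if (length(tl) != 2 || length(il) != 2)
    abort("the pattern-difference test requires a 2 x 2 design")
  meas <- as.matrix(data[, setdiff(names(data), c("level_A", "level_B",
                                                  "trial", "run"))])
  t_lab <- data[[tcol]]; i_lab <- data[[icol]]
  if (any(table(t_lab, i_lab) == 0)) abort("every condition needs trials")
  stat_for <- function(i_lab) {
    cm <- function(t, i) colMeans(meas[t_lab == t & i_lab == i, , drop = FALSE])
    (cm(tl[1], il[1]) - cm(tl[2], il[1])) -
      (cm(tl[1], il[2]) - cm(tl[2], il[2]))
  }
  iv <- stat_for(i_lab)
  obs <- sqrt(sum(iv^2))
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(s) {
    shuffled <- i_lab
    for (t in tl) {
      ix <- which(t_lab == t)
      shuffled[ix] <- i_lab[ix][sample.int(length(ix))]
    }
    sqrt(sum(stat_for(shuffled)^2))
  }, numeric(1)))
  list(interaction_vector = iv, statistic = obs,
       permutation_p = (1 + sum(perm >= obs)) / (1 + n_perm))
}
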