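#' Two-dimensional stimulus grid
#'
#' Defines the factorial stimulus set of a two-dimensional design: `levels_A`
#' levels on the target-candidate dimension A crossed with `levels_B` levels
#' on dimension B.  Conditions are ordered row-major over `(i, j)`, i.e.
#' `(1,1), (1,2), ..., (2,1), ...`; every tuning matrix and covariance list in
#' the package follows this ordering.
#'
#' @param levels_A,levels_B Number of levels on each dimension (both >= 2).
#' @param labels_A,labels_B Optional character labels per level.
#' @return An object of class `stimulus_grid`.
#' @examples
#' g <- stimulus_grid(2, 2, labels_A = c("id1", "id2"),
#'                    labels_B = c("neutral", "sad"))
#' conditions(g)
#' @export
stimulus_grid <- function(levels_A, levels_B,
                          labels_A = NULL, labels_B = NULL) {
  if (levels_A < 2 || levels_B < 2)
    abort("a stimulus grid needs at least 2 levels on each dimension")
  if (!is.null(labels_A) && length(labels_A) != levels_A)
    abort("`labels_A` must have one entry per level of A")
  if (!is.null(labels_B) && length(labels_B) != levels_B)
    abort("`labels_B` must have one entry per level of B")
  structure(
    list(levels_A = as.integer(levels_A), levels_B = as.integer(levels_B),
         labels_A = labels_A %||% paste0("A", seq_len(levels_A)),
         labels_B = labels_B %||% paste0("B", seq_len(levels_B))),
    class = "stimulus_grid"
  )
}

#' Enumerate the conditions of a stimulus grid
#'
#' @param grid A [stimulus_grid()].
#' @return A tibble with one row per condition in the package's row-major
#'   ordering, with columns `condition`, `level_A`, `level_B`.
#' @export
conditions <- function(grid) {
  stopifnot(inherits(grid, "stimulus_grid"))
  tibble::tibble(
    condition = seq_len(grid$levels_A * grid$levels_B),
    level_A = rep(seq_len(grid$levels_A), each = grid$levels_B),
    level_B = rep(seq_len(grid$levels_B), times = grid$levels_A)
  )
}

# Row-major linear index of condition (i, j); validates bounds.
condition_index <- function(grid, i, j) {
  if (i < 1 || i > grid$levels_A || j < 1 || j > grid$levels_B)
    abort(sprintf("condition (%d, %d) is outside the %dx%d grid",
                  i, j, grid$levels_A, grid$levels_B))
  (i - 1L) * grid$levels_B + j
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf("<stimulus_grid> %d x %d (A: %s; B: %s)\n",
              x$levels_A, x$levels_B,
              paste(x$labels_A, collapse = ", "),
              paste(x$labels_B, collapse = ", ")))
  invisible(x)
}
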