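#' Integer offsets of a voxel sphere
#'
#' All integer 3-D offsets with Euclidean norm at most `radius` (in voxel
#' units, center included).  The set is symmetric under negation.
#'
#' @param radius Sphere radius in voxels (>= 0).
#' @return An integer matrix with columns `dx`, `dy`, `dz`.
#' @examples
#' nrow(sphere_offsets(0))  # 1
#' nrow(sphere_offsets(3))  # 123
#' @export
sphere_offsets <- function(radius) {
  if (radius < 0) abort("`radius` must be non-negative")
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  storage.mode(g) <- "integer"
  rownames(g) <- NULL
  g
}

#' Volumetric dataset for searchlight analysis
#'
#' @param data 4-D numeric array `(x, y, z, trial)` of single-trial activity
#'   estimates.
#' @param mask 3-D binary array marking analysis voxels; defaults to
#'   all-ones.
#' @param trial_table Data frame with one row per trial and columns
#'   `level_A`, `level_B` (a `trial` column is added if absent).
#' @return An object of class `volume_dataset`.
#' @export
volume_dataset <- function(data, mask = NULL, trial_table) {
  if (length(dim(data)) != 4) abort("`data` must be a 4-D array")
  shape <- dim(data)[1:3]
  mask <- mask %||% array(1L, dim = shape)
  if (!all(dim(mask) == shape))
    abort("mask dimensions must match the spatial dimensions of `data`")
  trial_table <- tibble::as_tibble(trial_table)
  if (nrow(trial_table) != dim(data)[4])
    abort("trial table rows must match the number of trials")
  if (!all(c("level_A", "level_B") %in% names(trial_table)))
    abort("trial table needs columns level_A and level_B")
  if (!"trial" %in% names(trial_table))
    trial_table$trial <- seq_len(nrow(trial_table))
  structure(list(data = data, mask = (mask != 0), trial_table = trial_table),
            class = "volume_dataset")
}

#' @export
print.volume_dataset <- function(x, ...) {
  cat(sprintf("<volume_dataset> %s volume, %d trials, %d in-mask voxels\n",
              paste(dim(x$data)[1:3], collapse = " x "), dim(x$data)[4],
              sum(x$mask)))
  invisible(x)
}

# Per-center trial x voxel matrix (columns standardized), or NULL when the
# sphere holds < min_vox usable voxels.
extract_sphere <- function(ds, center, offs, min_vox = 2, flat = NULL) {
  shape <- dim(ds$data)[1:3]
  vox <- sweep(offs, 2, center, "+")
  keep <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
    vox[, 2] >= 1 & vox[, 2] <= shape[2] &
    vox[, 3] >= 1 & vox[, 3] <= shape[3]
  vox <- vox[keep, , drop = FALSE]
  keep <- ds$mask[vox]
  vox <- vox[keep, , drop = FALSE]
  if (nrow(vox) < min_vox) return(NULL)
  if (is.null(flat)) flat <- matrix(ds$data, prod(shape), dim(ds$data)[4])
  lin <- vox[, 1] + (vox[, 2] - 1) * shape[1] +
    (vox[, 3] - 1) * shape[1] * shape[2]
  m <- t(flat[lin, , drop = FALSE])
  sds <- apply(m, 2, sd)
  m <- m[, sds > 0, drop = FALSE]
  if (ncol(m) < min_vox) return(NULL)
  scale(m)
}

# Shared driver: applies `fn(sphere_matrix)` at every in-mask center.
# `fn` may return a named vector; one array per element is returned.
searchlight_apply <- function(ds, radius, fn, min_vox = 2, n_out = 1) {
  offs <- sphere_offsets(radius)
  shape <- dim(ds$data)[1:3]
  values <- replicate(n_out, array(NA_real_, dim = shape), simplify = FALSE)
  flat <- matrix(ds$data, prod(shape), dim(ds$data)[4])
  centers <- which(ds$mask, arr.ind = TRUE)
  for (k in seq_len(nrow(centers))) {
    m <- extract_sphere(ds, centers[k, ], offs, min_vox, flat = flat)
    if (is.null(m)) next
    v <- tryCatch(fn(m), error = function(e) rep(NA_real_, n_out))
    for (o in seq_len(n_out))
      values[[o]][centers[k, 1], centers[k, 2], centers[k, 3]] <- v[o]
  }
  values
}

#' Searchlight map of standardized DDS
#'
#' At every in-mask voxel, extracts the in-mask voxels within a sphere,
#' standardizes each voxel's values across trials, fits the linear
#' classifier on the target dimension pooling all trials, projects the data
#' onto the hyperplane normal to obtain decoded values, and runs the
#' permutation-standardized DDS test.  Centers whose sphere holds fewer
#' than 2 usable voxels, or whose data are degenerate, are left missing.
#'
#' @param ds A [volume_dataset()].
#' @param target `"A"` or `"B"`.
#' @param radius Searchlight radius in voxels, default 3.
#' @param n_shuffles Shuffles for the DDS standardization, default 200.
#' @param seed Integer seed (one stream drives all centers; identical seed
#'   and inputs give an identical map).
#' @param scale `"percentile_minus_50"` (maps; null 0) or `"proportion"`
#'   (null 0.5).
#' @param n_points KDE grid points, default 1000.
#' @param cost SVM soft-margin cost, default 1.
#' @return An object of class `searchlight_map` with fields `values` (3-D
#'   array, `NA` outside the mask), `mask` and `metadata`.
#' @export
searchlight_dds <- function(ds, target = c("A", "B"), radius = 3,
                            n_shuffles = 200, seed,
                            scale = c("percentile_minus_50", "proportion"),
                            n_points = 1000, cost = 1) {
  stopifnot(inherits(ds, "volume_dataset"))
  target <- match.arg(target)
  scale <- match.arg(scale)
  tt <- ds$trial_table
  labels <- if (target == "A") tt$level_A else tt$level_B
  res <- with_seed(seed, searchlight_apply(ds, radius, function(m) {
    dec <- fit_linear_classifier(m, labels, cost = cost)
    d <- tibble::tibble(level_A = tt$level_A, level_B = tt$level_B,
                        decoded_value = decode(dec, m))
    fit <- dds_test_impl(d, target, n_shuffles, n_points)
    v <- if (scale == "proportion") fit$proportion else fit$percentile - 50
    es <- sd(fit$edf)
    c(v, if (es > 0) (fit$raw - mean(fit$edf)) / es else 0)
  }, n_out = 2))
  structure(list(values = res[[1]], z = res[[2]], mask = ds$mask,
                 metadata = list(statistic = "dds", target = target,
                                 radius = radius, n_shuffles = n_shuffles,
                                 scale = scale, seed = seed)),
            class = "searchlight_map")
}

# dds_test without reseeding: consumes the caller's RNG stream.
dds_test_impl <- function(data, target, n_shuffles, n_points,
                          include_observed = FALSE) {
  parts <- dds_split(data, target)
  grid <- build_eval_grid(c(parts$x1, parts$x2), n_points)
  shuffle_cols <- function(lab) {
    n <- length(lab)
    m <- matrix(0L, n, n_shuffles + 1)
    m[, 1] <- lab
    for (s in seq_len(n_shuffles)) m[, s + 1] <- lab[sample.int(n)]
    m
  }
  res <- dds_perm_cpp(parts$x1, shuffle_cols(parts$lab1),
                      parts$x2, shuffle_cols(parts$lab2), as.numeric(grid))
  raw <- res[1]; edf <- res[-1]
  ref <- if (include_observed) c(edf, raw) else edf
  pct <- 100 * (sum(ref < raw) + 0.5 * sum(ref == raw)) / length(ref)
  list(raw = raw, edf = edf, proportion = pct / 100, percentile = pct,
       n_trials = length(parts$x1) + length(parts$x2), grid = grid)
}

#' Searchlight map of classifier-weight orthogonality
#'
#' At every center, fits the linear classifier once for each stimulus
#' dimension and records the Pearson correlation of the two weight vectors
#' (zero correlation = orthogonal weight vectors).
#'
#' @inheritParams searchlight_dds
#' @return A `searchlight_map` whose values are weight correlations.
#' @export
searchlight_orthogonality <- function(ds, radius = 3, cost = 1) {
  stopifnot(inherits(ds, "volume_dataset"))
  tt <- ds$trial_table
  values <- searchlight_apply(ds, radius, function(m) {
    wa <- fit_linear_classifier(m, tt$level_A, cost = cost)$weights
    wb <- fit_linear_classifier(m, tt$level_B, cost = cost)$weights
    orthogonality_index(wa, wb)$pearson
  })[[1]]
  structure(list(values = values, mask = ds$mask,
                 metadata = list(statistic = "orthogonality",
                                 radius = radius)),
            class = "searchlight_map")
}

#' Locate the peak of a searchlight map
#'
#' Returns the voxel coordinates of the map's maximum.  Rank-standardized
#' DDS values saturate at their ceiling (all shuffles below the observed
#' statistic), so ties at the maximum are broken with the continuous EDF
#' z-score `(raw - mean(EDF)) / sd(EDF)` when the map carries one.
#'
#' @param map A `searchlight_map`.
#' @return Integer vector `c(x, y, z)` of the peak center.
#' @export
map_peak <- function(map) {
  stopifnot(inherits(map, "searchlight_map"))
  v <- map$values
  mx <- max(v, na.rm = TRUE)
  at <- which(!is.na(v) & v == mx)
  if (length(at) > 1 && !is.null(map$z)) {
    z <- map$z[at]
    at <- at[which.max(z)]
  } else {
    at <- at[1]
  }
  as.integer(arrayInd(at, dim(v)))
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat(sprintf("<searchlight_map> %s, %d defined centers (of %d in mask)\n",
              x$metadata$statistic, sum(!is.na(x$values)), sum(x$mask)))
  invisible(x)
}

#' @rdname searchlight_dds
#' @param object A `searchlight_map`.
#' @param slice z-slice to display; defaults to the middle slice.
#' @param ... Unused.
#' @method autoplot searchlight_map
#' @export
autoplot.searchlight_map <- function(object, slice = NULL, ...) {
  slice <- slice %||% ceiling(dim(object$values)[3] / 2)
  sl <- object$values[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- sl[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s map, z = %d",
                                  object$metadata$statistic, slice),
                  fill = "value") +
    ggplot2::theme_minimal()
}

#' Group-level sign-flip permutation test on subject maps
#'
#' One-sample nonparametric inference on per-subject searchlight maps: the
#' voxelwise statistic is the mean across subjects of the (optionally
#' re-centered) map values, and its null distribution is built by randomly
#' flipping the sign of whole subject maps.  Family-wise error is
#' controlled with the distribution of the maximum statistic across voxels.
#' When `2^S <= n_perm` the flips are enumerated exhaustively (the identity
#' flip included), giving exact p-values.
#'
#' @param maps List of `searchlight_map` objects (or 3-D arrays) on a
#'   common lattice, one per subject (>= 2).
#' @param n_perm Number of random sign flips, default 5000.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param center Null value subtracted from every map before testing
#'   (e.g. 0.5 for proportion-scale DDS maps), default 0.
#' @param seed Integer seed (unused when flips are exhaustive).
#' @return A list with `stat` (3-D array of mean statistics),
#'   `p_uncorrected`, `p_fwe` (3-D arrays), `max_stat_95` (the FWE
#'   threshold at alpha = 0.05) and `n_perm_used`.
#' @export
group_sign_flip_test <- function(maps, n_perm = 5000,
                                 alternative = c("greater", "less",
                                                 "two.sided"),
                                 center = 0, seed = 1) {
  alternative <- match.arg(alternative)
  arrs <- lapply(maps, function(m)
    if (inherits(m, "searchlight_map")) m$values else m)
  dims <- lapply(arrs, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1)
    abort("all subject maps must share the same lattice")
  S <- length(arrs)
  if (S < 2) abort("at least 2 subjects are required")
  X <- do.call(rbind, lapply(arrs, as.vector)) - center   # S x V
  keep <- colSums(is.na(X)) == 0
  Xk <- X[, keep, drop = FALSE]
  side <- function(v) switch(alternative,
                             greater = v, less = -v, two.sided = abs(v))
  obs <- side(colMeans(Xk))
  exhaustive <- 2^S <= n_perm
  flips <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), S)))
  } else {
    with_seed(seed,
              matrix(sample(c(1, -1), n_perm * S, replace = TRUE), n_perm, S))
  }
  n_used <- nrow(flips)
  count <- numeric(length(obs))
  max_stats <- numeric(n_used)
  for (p in seq_len(n_used)) {
    stat_p <- side(colMeans(Xk * flips[p, ]))
    count <- count + (stat_p >= obs)
    max_stats[p] <- max(stat_p)
  }
  p_unc <- if (exhaustive) count / n_used else (count + 1) / (n_used + 1)
  p_fwe <- vapply(obs, function(o) {
    k <- sum(max_stats >= o)
    if (exhaustive) k / n_used else (k + 1) / (n_used + 1)
  }, numeric(1))
  to_arr <- function(v) {
    a <- array(NA_real_, dim = dims[[1]])
    a[keep] <- v
    a
  }
  list(stat = to_arr(colMeans(Xk)),
       p_uncorrected = to_arr(p_unc),
       p_fwe = to_arr(p_fwe),
       max_stat_95 = stats::quantile(max_stats, 0.95, names = FALSE),
       n_perm_used = n_used, exhaustive = exhaustive,
       alternative = alternative)
}
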