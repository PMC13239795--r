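# Local hotspot detection: k-nearest-neighbour spatial weights (binary, with
# the self term included in the Gi* sum -- the "star" convention) and the
# Getis-Ord Gi* standard deviate with analytic normal inference.

#' Build k-nearest-neighbour spatial weights
#'
#' For each unit, finds its `k` nearest other units by Euclidean centroid
#' distance in the projected plane. Distance ties at the k-th rank are broken
#' by ascending unit index, so the neighbour sets are deterministic. Each
#' neighbour carries weight 1, and the unit itself enters the Gi* sum with
#' weight 1 (star convention); the weight structure is symmetric only by
#' coincidence.
#'
#' @param points two-column matrix or data.frame of unit centroids (x, y).
#' @param k neighbours per unit, `1 <= k < n`.
#' @param chunk internal block size for the chunked distance computation.
#' @return A `knn_weights` object: `n`, `k`, and the `n x k` integer
#'   `neighbor_index` matrix (self excluded).
#' @export
build_knn <- function(points, k, chunk = 512L) {
  pts <- as.matrix(points[, 1:2])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  dup <- duplicated(pts)
  if (any(dup)) {
    i <- which(dup)[1]
    j <- which(pts[, 1] == pts[i, 1] & pts[, 2] == pts[i, 2])[1]
    stop(sprintf("duplicate coordinates at units %d and %d", j, i))
  }
  nbr <- matrix(0L, n, k)
  x <- pts[, 1]; y <- pts[, 2]
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    idx <- s:e
    D <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    D[cbind(seq_along(idx), idx)] <- Inf      # exclude self
    for (r in seq_along(idx)) {
      d <- D[r, ]
      th <- sort(d, partial = k)[k]
      cand <- which(d <= th)                  # >= k entries; extras are ties
      o <- cand[order(d[cand])]               # radix order: stable index ties
      nbr[idx[r], ] <- o[seq_len(k)]
    }
  }
  structure(list(n = n, k = k, neighbor_index = nbr, points = pts),
            class = "knn_weights")
}

#' @rdname build_knn
#' @param weights a `knn_weights` built with a larger `k`.
#' @return `knn_subset()` returns the same weight set truncated to the `k`
#'   nearest neighbours, avoiding a rebuild during k-sensitivity analyses.
#' @export
knn_subset <- function(weights, k) {
  stopifnot(inherits(weights, "knn_weights"), k <= weights$k, k >= 1L)
  structure(list(n = weights$n, k = as.integer(k),
                 neighbor_index = weights$neighbor_index[, seq_len(k),
                                                         drop = FALSE],
                 points = weights$points),
            class = "knn_weights")
}

#' @export
print.knn_weights <- function(x, ...) {
  cat(sprintf("knn_weights: %d units, k = %d (binary, self-inclusive in Gi*)\n",
              x$n, x$k))
  invisible(x)
}

#' Getis-Ord Gi* local statistic
#'
#' For each unit i, with j ranging over all n units including i and binary
#' weights w_ij = 1 for i's k neighbours and for i itself (so
#' W_i = S_1i = k + 1):
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar{x} W_i}{s \sqrt{(n S_{1i} - W_i^2)/(n-1)}}}
#' with \eqn{\bar{x} = \sum_j x_j / n} and
#' \eqn{s = \sqrt{\sum_j x_j^2 / n - \bar{x}^2}}. Under spatial randomness
#' the deviate is asymptotically standard normal; the two-sided p-value uses
#' that approximation (no conditional permutation inference).
#'
#' A constant field (`s = 0`) is rejected. Units whose neighbourhood spans
#' the whole set (`n S_1i - W_i^2 <= 0`) are flagged undefined. Units with
#' missing scores should be dropped (with re-indexing) before building the
#' weights; `gi_star()` refuses missing values.
#'
#' @param values per-unit score, length `n`.
#' @param weights a `knn_weights` from [build_knn()].
#' @param alpha two-sided significance level for the hot/cold classification.
#' @return A `gi_star_result`: `z`, `p_two_sided`, `class` (factor
#'   hotspot/coldspot/null), logical `undefined`, plus `k` and `alpha`.
#' @export
gi_star <- function(values, weights, alpha = 0.05) {
  stopifnot(inherits(weights, "knn_weights"))
  x <- as.numeric(values)
  n <- weights$n
  if (length(x) != n) stop("values length does not match the weight set")
  if (anyNA(x))
    stop("missing scores: drop missing units and rebuild the weights")
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  if (s <= 0) stop("zero-variance score field: Gi* is undefined")
  Wi <- weights$k + 1
  S1 <- weights$k + 1
  vr <- n * S1 - Wi^2
  num <- rowSums(matrix(x[weights$neighbor_index], n, weights$k)) + x -
    xbar * Wi
  undefined <- rep(vr <= 0, n)
  z <- if (vr <= 0) rep(NA_real_, n) else
    num / (s * sqrt(vr / (n - 1)))
  p <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(1 - alpha / 2)
  cls <- factor(ifelse(is.na(z), NA,
                       ifelse(z >= zc, "hotspot",
                              ifelse(z <= -zc, "coldspot", "null"))),
                levels = c("hotspot", "coldspot", "null"))
  structure(list(z = z, p_two_sided = p, class = cls, undefined = undefined,
                 k = weights$k, alpha = alpha, n = n),
            class = "gi_star_result")
}

#' @export
print.gi_star_result <- function(x, ...) {
  cat(sprintf("gi_star_result: %d units, k = %d, alpha = %g\n", x$n, x$k,
              x$alpha))
  if (all(x$undefined)) {
    cat("  all units undefined (neighbourhood spans the whole set)\n")
  } else {
    cat(sprintf("  z range [%.2f, %.2f]; ", min(x$z, na.rm = TRUE),
                max(x$z, na.rm = TRUE)))
    print(table(x$class))
  }
  invisible(x)
}

#' Classify units into hotspot / coldspot / null and report shares
#'
#' A unit is a hotspot if `z >= z_crit`, a coldspot if `z <= -z_crit`, else
#' null, with `z_crit` the two-sided normal critical value at `alpha`
#' (1.959964 at the default 0.05; no multiplicity adjustment by default).
#' Shares are fractions of classified (defined) units and sum to 1.
#'
#' @param result a `gi_star_result` from [gi_star()].
#' @param alpha significance level.
#' @param fdr if `TRUE`, classify on Benjamini-Hochberg adjusted p-values
#'   instead of raw z thresholds.
#' @return List with per-unit `class` and named numeric `shares`
#'   (`hotspot`, `coldspot`, `null`).
#' @export
classify_spots <- function(result, alpha = 0.05, fdr = FALSE) {
  stopifnot(inherits(result, "gi_star_result"))
  z <- result$z
  if (fdr) {
    padj <- stats::p.adjust(result$p_two_sided, "BH")
    sig <- !is.na(padj) & padj <= alpha
    cls <- ifelse(is.na(z), NA,
                  ifelse(sig & z > 0, "hotspot",
                         ifelse(sig & z < 0, "coldspot", "null")))
  } else {
    zc <- stats::qnorm(1 - alpha / 2)
    cls <- ifelse(is.na(z), NA,
                  ifelse(z >= zc, "hotspot",
                         ifelse(z <= -zc, "coldspot", "null")))
  }
  cls <- factor(cls, levels = c("hotspot", "coldspot", "null"))
  tab <- table(cls)
  shares <- as.numeric(tab) / sum(tab)
  names(shares) <- names(tab)
  list(class = cls, shares = shares)
}

#' Combine hazard layers into a single co-exposure score
#'
#' Default combination for the hotspot scan: each hazard layer is
#' z-standardized (sample standard deviation) and the unweighted mean across
#' layers is returned. Alternatively a single hazard passes through
#' unchanged. All layers must share one grid.
#'
#' @param layers named list of [raster_layer()]s (or matrices on one grid).
#' @param combine `"sum_of_standardized"` (mean of per-layer z-scores, the
#'   default) or `"single_variable"`.
#' @param which layer name used when `combine = "single_variable"`.
#' @return A [raster_layer()] of the combined score.
#' @export
coexposure_score <- function(layers, combine = c("sum_of_standardized",
                                                 "single_variable"),
                             which = names(layers)[1]) {
  combine <- match.arg(combine)
  stopifnot(length(layers) >= 1)
  grids <- lapply(layers, function(l)
    if (inherits(l, "raster_layer")) l$grid else NULL)
  g <- grids[[1]]
  if (is.null(g)) stop("layers must be raster_layer objects")
  if (!all(vapply(grids, function(gg) same_grid(gg, g), TRUE)))
    stop("grid mismatch across hazard layers")
  if (combine == "single_variable")
    return(raster_layer(layers[[which]]$values, g,
                        paste0("coexposure_", which)))
  mats <- lapply(layers, function(l) {
    v <- l$values
    s <- stats::sd(as.vector(v), na.rm = TRUE)
    if (is.na(s) || s == 0)
      stop(sprintf("layer '%s' is constant; cannot standardize", l$name))
    (v - mean(v, na.rm = TRUE)) / s
  })
  raster_layer(Reduce(`+`, mats) / length(mats), g, "coexposure_score")
}
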