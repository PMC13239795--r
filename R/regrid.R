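# Grid harmonization by separable kernel resampling. The Lanczos kernel
# L(x) = sinc(x) sinc(x/a) for |x| < a (else 0) is applied independently in
# x and y on cell-center offsets measured in source-cell units, with weights
# renormalized to sum to one within the truncated support. Inputs are assumed
# co-projected; only affine grid alignment is performed.

lanczos_kernel <- function(x, a) {
  out <- numeric(length(x))
  inside <- abs(x) < a
  tiny <- abs(x) < 1e-12
  xi <- x[inside & !tiny]
  out[inside & !tiny] <- a * sin(pi * xi) * sin(pi * xi / a) / (pi^2 * xi^2)
  out[tiny] <- 1
  out
}

# one-axis weight matrix (n_target x n_source) mapping source cell centers to
# target cell centers; positions measured along increasing coordinate
axis_weights <- function(src_origin, src_cell, n_src, tgt_origin, tgt_cell,
                         n_tgt, kernel, a) {
  tc <- tgt_origin + (seq_len(n_tgt) - 0.5) * tgt_cell
  u <- (tc - src_origin) / src_cell - 0.5      # 0-based source index coords
  W <- matrix(0, n_tgt, n_src)
  for (i in seq_len(n_tgt)) {
    if (kernel == "nearest") {
      j <- min(max(round(u[i]), 0), n_src - 1)
      W[i, j + 1] <- 1
      next
    }
    half <- if (kernel == "lanczos") a else 1    # bilinear = hat kernel
    j0 <- max(ceiling(u[i] - half), 0)
    j1 <- min(floor(u[i] + half), n_src - 1)
    if (j1 < j0) {                                # fall back to nearest
      j <- min(max(round(u[i]), 0), n_src - 1)
      W[i, j + 1] <- 1
      next
    }
    j <- j0:j1
    d <- u[i] - j
    w <- if (kernel == "lanczos") lanczos_kernel(d, a) else pmax(0, 1 - abs(d))
    s <- sum(w)
    if (abs(s) < 1e-12) {                          # degenerate truncation
      j <- min(max(round(u[i]), 0), n_src - 1)
      W[i, j + 1] <- 1
    } else {
      W[i, j + 1] <- w / s
    }
  }
  W
}

#' Resample a raster onto a target grid
#'
#' Separable kernel resampling between co-projected regular grids. Each
#' target cell value is a kernel-weighted combination of source cells, with
#' weights renormalized to sum to one within the (possibly edge-truncated)
#' support, so constant fields are preserved exactly. Missing source cells
#' are excluded with renormalization; a target cell whose retained absolute
#' weight falls below `min_weight` is set missing. A target grid identical
#' to the source grid returns the input unchanged.
#'
#' @param values source value matrix (or [raster_layer()]).
#' @param source,target [grid_spec()]s; `source` may be omitted when
#'   `values` is a `raster_layer`.
#' @param kernel `"lanczos"` (default), `"bilinear"` or `"nearest"`.
#'   Categorical rasters should use `"nearest"`; interpolating class codes is
#'   meaningless.
#' @param lanczos_a number of kernel lobes (default 3, the common Lanczos3).
#' @param min_weight missing-data cutoff on retained weight (default 0.5).
#' @return Value matrix on the target grid (a `raster_layer` if the input
#'   was one).
#' @export
resample_grid <- function(values, source = NULL, target,
                          kernel = c("lanczos", "bilinear", "nearest"),
                          lanczos_a = 3L, min_weight = 0.5) {
  kernel <- match.arg(kernel)
  was_layer <- inherits(values, "raster_layer")
  if (was_layer) {
    source <- values$grid
    nm <- values$name
    values <- values$values
  }
  stopifnot(inherits(source, "grid_spec"), inherits(target, "grid_spec"))
  if (lanczos_a < 1L) stop("lanczos_a must be a positive integer")
  if (source$cell_size <= 0 || target$cell_size <= 0)
    stop("non-positive cell sizes")
  es <- grid_extent(source); et <- grid_extent(target)
  if (et["xmin"] >= es["xmax"] || et["xmax"] <= es["xmin"] ||
      et["ymin"] >= es["ymax"] || et["ymax"] <= es["ymin"])
    stop("target grid does not overlap the source extent")
  check_conforms(values, source, "source raster")

  if (same_grid(source, target)) {
    out <- values
  } else {
    # columns: along x (west->east); rows: along y, stored north->south, so
    # row r center is at origin_y + (n_rows - r + 0.5) * cell; flip to build
    # weights on an increasing axis, then index back
    Wc <- axis_weights(source$origin_x, source$cell_size, source$n_cols,
                       target$origin_x, target$cell_size, target$n_cols,
                       kernel, lanczos_a)
    Wr_s <- axis_weights(source$origin_y, source$cell_size, source$n_rows,
                         target$origin_y, target$cell_size, target$n_rows,
                         kernel, lanczos_a)
    # Wr_s maps south->north indices; convert to matrix-row (north->south)
    Wr <- Wr_s[rev(seq_len(target$n_rows)), rev(seq_len(source$n_rows)),
               drop = FALSE]
    if (anyNA(values)) {
      Z <- values; Z[is.na(Z)] <- 0
      O <- 1 - is.na(values)
      V <- Wr %*% Z %*% t(Wc)
      K <- Wr %*% O %*% t(Wc)
      out <- V / K
      out[abs(K) < min_weight] <- NA_real_
    } else {
      out <- Wr %*% values %*% t(Wc)
    }
  }
  if (was_layer) raster_layer(out, target, nm) else out
}

#' Align a stack of rasters onto a common target grid
#'
#' Applies [resample_grid()] to each raster in a list; rasters already on the
#' target grid pass through unchanged. Entries may be `raster_layer`s or
#' `list(values =, grid =)` pairs.
#'
#' @param rasters list of rasters on possibly mixed grids.
#' @param target target [grid_spec()].
#' @param ... passed to [resample_grid()].
#' @return List of value matrices (or `raster_layer`s) on `target`.
#' @export
align_stack <- function(rasters, target, ...) {
  lapply(rasters, function(r) {
    if (inherits(r, "raster_layer")) {
      resample_grid(r, target = target, ...)
    } else {
      resample_grid(r$values, source = r$grid, target = target, ...)
    }
  })
}
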