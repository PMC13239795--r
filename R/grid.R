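#' Define a regular planar grid
#'
#' A `grid_spec` describes a cell-aligned regular raster grid in a projected
#' planar coordinate system: lower-left corner, square cell size, and the
#' number of columns and rows. All raster layers of an analysis that share a
#' `grid_spec` are cell-aligned, so per-cell operations can be composed
#' without resampling. Raster values are stored as an `n_rows x n_cols`
#' matrix whose first row is the northern edge of the grid.
#'
#' @param origin_x,origin_y coordinates of the lower-left grid corner, in
#'   the units of the projected system (metres for the defaults used here).
#' @param cell_size side length of a (square) grid cell, same units.
#' @param n_cols,n_rows grid dimensions, positive integers.
#' @param crs_label opaque label for the projected reference system; it is
#'   carried through to outputs but never interpreted.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 0, 1000, 10, 10)
#' head(cell_centers(g))
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, cell_size = 1000,
                      n_cols = 10, n_rows = 10, crs_label = "local-planar") {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  if (n_cols < 1L || n_rows < 1L) stop("n_cols and n_rows must be >= 1")
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 n_cols = n_cols, n_rows = n_rows,
                 crs_label = as.character(crs_label)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows, cell %g, origin (%g, %g), crs '%s'\n",
              x$n_cols, x$n_rows, x$cell_size, x$origin_x, x$origin_y,
              x$crs_label))
  invisible(x)
}

#' @rdname grid_spec
#' @param g,a,b `grid_spec` objects.
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$n_cols == b$n_cols && a$n_rows == b$n_rows
}

#' @rdname grid_spec
#' @return `cell_centers()` returns a data.frame with one row per cell in
#'   matrix storage order (column-major over the value matrix: row index
#'   varies fastest, rows running north to south), giving matrix row/col and
#'   projected x/y of each cell center.
#' @export
cell_centers <- function(g) {
  stopifnot(inherits(g, "grid_spec"))
  row <- rep(seq_len(g$n_rows), times = g$n_cols)
  col <- rep(seq_len(g$n_cols), each = g$n_rows)
  data.frame(row = row, col = col,
             x = g$origin_x + (col - 0.5) * g$cell_size,
             y = g$origin_y + (g$n_rows - row + 0.5) * g$cell_size)
}

# x/y extent of the grid (outer edges)
grid_extent <- function(g) {
  c(xmin = g$origin_x, xmax = g$origin_x + g$n_cols * g$cell_size,
    ymin = g$origin_y, ymax = g$origin_y + g$n_rows * g$cell_size)
}

check_conforms <- function(values, g, what = "raster") {
  if (!is.matrix(values) || nrow(values) != g$n_rows || ncol(values) != g$n_cols)
    stop(sprintf("%s does not conform to its grid (%d x %d expected)",
                 what, g$n_rows, g$n_cols))
  invisible(TRUE)
}

#' A single raster layer bound to its grid
#'
#' Light container pairing a value matrix with its [grid_spec()]. Used for
#' derived surfaces (cumulative exposure, trend slopes, Gi* z-scores, risk
#' codes) handed between pipeline stages.
#'
#' @param values numeric matrix, `n_rows x n_cols`, row 1 = northern edge.
#' @param grid a [grid_spec()].
#' @param name short name of the quantity stored.
#' @export
raster_layer <- function(values, grid, name = "layer") {
  stopifnot(inherits(grid, "grid_spec"))
  check_conforms(values, grid, name)
  structure(list(values = values, grid = grid, name = name),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_layer '%s' on %d x %d grid: ", x$name,
              x$grid$n_rows, x$grid$n_cols))
  if (length(v)) {
    cat(sprintf("range [%.4g, %.4g], mean %.4g, %d missing\n",
                min(v), max(v), mean(v), sum(is.na(x$values))))
  } else cat("all missing\n")
  invisible(x)
}

#' A dated stack of daily gridded values
#'
#' The in-memory form of a daily field series: one variable on one grid over
#' an ordered set of calendar dates. Values are stored as a 3-d array
#' `[n_rows, n_cols, n_dates]`; missing values are `NA`.
#'
#' @param grid a [grid_spec()].
#' @param variable one of `"tmax_F"`, `"pm25_ugm3"`, `"bc_ugm3"`.
#' @param dates `Date` vector, strictly increasing.
#' @param values numeric array `[n_rows, n_cols, length(dates)]`.
#' @export
daily_field_series <- function(grid, variable, dates, values) {
  stopifnot(inherits(grid, "grid_spec"))
  variable <- match.arg(variable, c("tmax_F", "pm25_ugm3", "bc_ugm3"))
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("empty date range")
  if (any(diff(as.integer(dates)) <= 0)) stop("dates must be strictly increasing")
  d <- dim(values)
  if (length(d) != 3L || d[1] != grid$n_rows || d[2] != grid$n_cols ||
      d[3] != length(dates))
    stop("values array does not conform to grid x dates")
  structure(list(grid = grid, variable = variable, dates = dates,
                 values = values),
            class = "daily_field_series")
}

#' @export
print.daily_field_series <- function(x, ...) {
  cat(sprintf("daily_field_series '%s': %d x %d grid, %d days (%s .. %s)\n",
              x$variable, x$grid$n_rows, x$grid$n_cols, length(x$dates),
              format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}
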