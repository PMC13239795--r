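# File formats. Rasters travel as ESRI ASCII grids (plain text, grid
# metadata in the header, rows north to south -- matching the in-memory
# convention) with a CSV band index for stacks; tract polygons as GeoJSON
# with a CSV attribute table; configuration as YAML; reports as JSON. All
# formats round-trip losslessly at full double precision.

#' Read and write single rasters as ESRI ASCII grids
#'
#' The header carries the [grid_spec()] (lower-left corner, cell size,
#' dimensions); `NA` maps to the declared nodata value. Values are written
#' at full precision (`%.17g`) so round-trips are value-identical.
#'
#' @param values numeric matrix (row 1 = northern edge) or
#'   [raster_layer()].
#' @param grid a [grid_spec()] (ignored if `values` is a `raster_layer`).
#' @param path file path.
#' @param nodata nodata sentinel written to the header.
#' @return `read_ascii_grid()` returns a [raster_layer()].
#' @export
write_ascii_grid <- function(values, grid = NULL, path, nodata = -9999) {
  if (inherits(values, "raster_layer")) {
    grid <- values$grid
    values <- values$values
  }
  stopifnot(inherits(grid, "grid_spec"))
  check_conforms(values, grid)
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10f", grid$origin_x),
               sprintf("yllcorner %.10f", grid$origin_y),
               sprintf("cellsize %.10f", grid$cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs_label label restored on the grid read back.
#' @export
read_ascii_grid <- function(path, crs_label = "local-planar") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- t(vapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
    numeric(hdr$ncols), USE.NAMES = FALSE))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, hdr$ncols,
                 hdr$nrows, crs_label)
  raster_layer(vals, g, sub("\\.[^.]*$", "", basename(path)))
}

#' Read and write dated raster stacks
#'
#' A stack is a directory of one ESRI ASCII grid per band plus an
#' `index.csv` mapping bands to ISO-8601 dates (daily series) or month
#' abbreviations (normals), and a `meta.json` with the variable name and
#' reference-system label. Every band must carry a date (or month) tag;
#' undated bands and bands on inconsistent grids are rejected.
#'
#' @param x a [daily_field_series()] or named list of monthly normal
#'   matrices.
#' @param dir directory to create/read.
#' @param grid required when writing a normals list.
#' @return `read_raster_stack()` returns a `daily_field_series` or a named
#'   list of normal matrices with attribute `"grid"`, depending on the
#'   stored index.
#' @export
write_raster_stack <- function(x, dir, grid = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "daily_field_series")) {
    idx <- data.frame(band = seq_along(x$dates),
                      date = format(x$dates, "%Y-%m-%d"),
                      file = sprintf("band_%05d.asc", seq_along(x$dates)))
    for (b in idx$band)
      write_ascii_grid(x$values[, , b], x$grid, file.path(dir, idx$file[b]))
    meta <- list(kind = "daily", variable = x$variable,
                 crs_label = x$grid$crs_label)
  } else {
    stopifnot(is.list(x), !is.null(names(x)), inherits(grid, "grid_spec"))
    idx <- data.frame(band = seq_along(x), month = names(x),
                      file = sprintf("band_%05d.asc", seq_along(x)))
    for (b in idx$band)
      write_ascii_grid(x[[b]], grid, file.path(dir, idx$file[b]))
    meta <- list(kind = "normals", variable = "tmax_normal_F",
                 crs_label = grid$crs_label)
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_raster_stack
#' @export
read_raster_stack <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"),
                         stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  layers <- lapply(idx$file, function(f)
    read_ascii_grid(file.path(dir, f), crs_label = meta$crs_label))
  g <- layers[[1]]$grid
  for (l in layers) if (!same_grid(l$grid, g))
    stop("inconsistent grids across bands in ", dir)
  if (identical(meta$kind, "daily")) {
    if (!"date" %in% names(idx) || any(is.na(idx$date) | idx$date == ""))
      stop("band missing a date tag in ", dir)
    vals <- array(NA_real_, c(g$n_rows, g$n_cols, nrow(idx)))
    for (b in seq_len(nrow(idx))) vals[, , b] <- layers[[b]]$values
    daily_field_series(g, meta$variable, as.Date(idx$date), vals)
  } else {
    if (!"month" %in% names(idx) || any(is.na(idx$month) | idx$month == ""))
      stop("band missing a month tag in ", dir)
    out <- lapply(layers, function(l) l$values)
    names(out) <- idx$month
    attr(out, "grid") <- g
    out
  }
}

#' Long-CSV encoding of a daily field series
#'
#' Alternative plain-text encoding of a stack as `date,row,col,value`
#' records with a JSON header line carrying the grid. Useful for
#' interchange with tabular tools; parses to an object equal to the
#' ASCII-grid stack encoding of the same series.
#'
#' @param series a [daily_field_series()].
#' @param path CSV path.
#' @export
write_series_csv <- function(series, path) {
  g <- series$grid
  hdr <- jsonlite::toJSON(list(variable = series$variable,
                               origin_x = g$origin_x, origin_y = g$origin_y,
                               cell_size = g$cell_size, n_cols = g$n_cols,
                               n_rows = g$n_rows, crs_label = g$crs_label),
                          auto_unbox = TRUE, digits = NA)
  nd <- length(series$dates)
  np <- g$n_rows * g$n_cols
  df <- data.frame(date = rep(format(series$dates, "%Y-%m-%d"), each = np),
                   row = rep(rep(seq_len(g$n_rows), times = g$n_cols), nd),
                   col = rep(rep(seq_len(g$n_cols), each = g$n_rows), nd),
                   value = as.vector(series$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# ")) stop("missing grid header line in ", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", first))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  g <- grid_spec(meta$origin_x, meta$origin_y, meta$cell_size, meta$n_cols,
                 meta$n_rows, meta$crs_label)
  dates <- sort(unique(as.Date(df$date)))
  vals <- array(NA_real_, c(g$n_rows, g$n_cols, length(dates)))
  di <- match(as.Date(df$date), dates)
  vals[cbind(df$row, df$col, di)] <- df$value
  daily_field_series(g, meta$variable, dates, vals)
}

#' Write and read tract tables as GeoJSON
#'
#' Each tract is a Polygon feature (closed counter-clockwise rectangle ring)
#' whose properties carry the tract id, rural-urban code and the 12
#' vulnerability percentages. A `crs_label` member is stored at the
#' collection level.
#'
#' @param tracts a `tract_table`.
#' @param path GeoJSON path.
#' @export
write_tracts_geojson <- function(tracts, path) {
  vars <- intersect(c("tract_id", "ruca_code", VULN_VARS), names(tracts))
  feats <- lapply(seq_len(nrow(tracts)), function(i) {
    ring <- list(c(tracts$xmin[i], tracts$ymin[i]),
                 c(tracts$xmax[i], tracts$ymin[i]),
                 c(tracts$xmax[i], tracts$ymax[i]),
                 c(tracts$xmin[i], tracts$ymax[i]),
                 c(tracts$xmin[i], tracts$ymin[i]))
    props <- as.list(tracts[i, vars, drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection",
             crs_label = attr(tracts, "crs_label"),
             features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}

#' @rdname write_tracts_geojson
#' @export
read_tracts_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(fc$features, function(f) {
    co <- f$geometry$coordinates[[1]]
    xs <- vapply(co, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(co, function(p) as.numeric(p[[2]]), numeric(1))
    p <- f$properties
    p$ruca_code <- if (is.null(p$ruca_code)) NA_integer_ else
      as.integer(p$ruca_code)
    c(list(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys),
           centroid_x = mean(range(xs)), centroid_y = mean(range(ys))), p)
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  ord <- c("tract_id", "xmin", "xmax", "ymin", "ymax", "centroid_x",
           "centroid_y", "ruca_code", intersect(VULN_VARS, names(out)))
  out <- out[, ord]
  attr(out, "crs_label") <- fc$crs_label
  class(out) <- c("tract_table", "data.frame")
  out
}
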