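# Bivariate risk classification: collapse the three per-cell hazard tertiles
# to a single hazard level, join fine-grid cells to tracts, cross hazard
# level with the tract vulnerability tertile (the IPCC hazard x vulnerability
# framing), and summarize by rural-urban class.

HAZARD_LEVELS <- c("low", "moderate", "high")
TERTILE_LEVELS <- c("Low", "Moderate", "High")

#' Collapse a triple of hazard tertiles to one hazard level
#'
#' The 27 possible (PM2.5, black carbon, temperature) tertile triples map to
#' three levels: `high` if two or more hazards are in the High tertile,
#' `moderate` if exactly one is, `low` if none is (hazards only in the Low
#' or Moderate tertiles). Vectorized over triples.
#'
#' @param pm25,bc,temp character vectors with values in
#'   `c("Low", "Moderate", "High")` (NA propagates).
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
collapse_hazard <- function(pm25, bc, temp) {
  chk <- function(v) {
    if (!all(v %in% c(TERTILE_LEVELS, NA)))
      stop("invalid tertile label: ",
           paste(unique(setdiff(v, TERTILE_LEVELS)), collapse = ", "))
    v
  }
  nhigh <- (chk(pm25) == "High") + (chk(bc) == "High") + (chk(temp) == "High")
  factor(ifelse(is.na(nhigh), NA,
                ifelse(nhigh >= 2, "high",
                       ifelse(nhigh == 1, "moderate", "low"))),
         levels = HAZARD_LEVELS)
}

# ray-casting point-in-polygon; boundary points count as inside
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    # on-edge check
    if ((px - xi) * (yj - yi) == (py - yi) * (xj - xi) &&
        px >= min(xi, xj) && px <= max(xi, xj) &&
        py >= min(yi, yj) && py <= max(yi, yj)) return(TRUE)
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

#' Join fine-grid cells to tracts by centroid containment
#'
#' Each cell inherits the tract whose polygon contains its centroid. A
#' centroid touching the boundary of several tracts is assigned to the
#' lowest `tract_id` among them (deterministic); centroids outside all
#' tracts are flagged unassigned (`NA`) and excluded from risk classes
#' downstream.
#'
#' @param grid fine [grid_spec()] whose cell centroids are joined.
#' @param tracts a `tract_table` (rectangular tessellation) or any
#'   data.frame with `tract_id`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @return Character vector, one tract_id (or `NA`) per cell in matrix
#'   storage order.
#' @export
join_cells_to_tracts <- function(grid, tracts) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(tracts$xmin >= tracts$xmax) || any(tracts$ymin >= tracts$ymax))
    stop("invalid (degenerate) polygon for tract(s): ",
         paste(tracts$tract_id[tracts$xmin >= tracts$xmax |
                                 tracts$ymin >= tracts$ymax],
               collapse = ", "))
  cc <- cell_centers(grid)
  ord <- order(tracts$tract_id)
  assigned <- rep(NA_character_, nrow(cc))
  # rectangles: containment is interval arithmetic; scanning tracts in
  # ascending tract_id order makes boundary ties fall to the lowest id
  for (t in ord) {
    hit <- is.na(assigned) &
      cc$x >= tracts$xmin[t] & cc$x <= tracts$xmax[t] &
      cc$y >= tracts$ymin[t] & cc$y <= tracts$ymax[t]
    assigned[hit] <- tracts$tract_id[t]
  }
  assigned
}

#' Cross hazard level with vulnerability tertile into risk classes
#'
#' Builds the 3x3 bivariate risk legend per fine-grid cell: the collapsed
#' hazard level crossed with the vulnerability tertile of the cell's tract.
#' The risk code is a two-digit integer (tens digit = hazard level 1-3, ones
#' digit = vulnerability tertile 1-3, so codes run 11..33); `high_risk` is
#' the corner class, hazard `high` and vulnerability `High`. Cells without
#' an assigned tract are excluded and counted.
#'
#' @param hazard_level factor from [collapse_hazard()], one value per cell.
#' @param cell_tract tract_id per cell from [join_cells_to_tracts()].
#' @param vuln_tertiles a `tertile_field` over tracts (from
#'   [tertile_classify()] on the vulnerability index scores), plus
#' @param tract_id the tract ids in the order of `vuln_tertiles` values.
#' @param grid optional fine [grid_spec()] to attach a risk-code raster.
#' @return A `risk_map`: per-cell data.frame `cells` (`tract_id`,
#'   `hazard_level`, `vulnerability_tertile`, `risk_code`, `high_risk`),
#'   `n_unassigned`, per-tract `tract_summary` (share of high-risk cells,
#'   modal risk code), and optionally a `risk_raster` layer.
#' @export
classify_risk <- function(hazard_level, cell_tract, vuln_tertiles, tract_id,
                          grid = NULL) {
  stopifnot(inherits(vuln_tertiles, "tertile_field"))
  n <- length(hazard_level)
  if (length(cell_tract) != n) stop("cell/tract join length mismatch")
  vt <- stats::setNames(as.integer(vuln_tertiles$codes), tract_id)
  vcode <- vt[cell_tract]                        # NA for unassigned cells
  hcode <- as.integer(factor(hazard_level, levels = HAZARD_LEVELS))
  risk_code <- ifelse(is.na(hcode) | is.na(vcode), NA_integer_,
                      10L * hcode + vcode)
  high_risk <- !is.na(risk_code) & risk_code == 33L
  cells <- data.frame(
    cell = seq_len(n), tract_id = cell_tract,
    hazard_level = factor(HAZARD_LEVELS[hcode], levels = HAZARD_LEVELS),
    vulnerability_tertile = factor(TERTILE_LEVELS[vcode],
                                   levels = TERTILE_LEVELS),
    risk_code = risk_code, high_risk = high_risk,
    stringsAsFactors = FALSE)
  assigned <- !is.na(cells$risk_code)
  agg <- stats::aggregate(cbind(high_risk, assigned = 1L) ~ tract_id,
                          data = cells[assigned, , drop = FALSE], FUN = sum)
  modal <- vapply(split(cells$risk_code[assigned],
                        cells$tract_id[assigned]), function(v)
                          as.integer(names(which.max(table(v)))), 1L)
  tract_summary <- data.frame(
    tract_id = agg$tract_id,
    n_cells = agg$assigned,
    n_high_risk = agg$high_risk,
    high_risk_share = agg$high_risk / agg$assigned,
    modal_risk_code = modal[agg$tract_id],
    stringsAsFactors = FALSE)
  rr <- NULL
  if (!is.null(grid)) {
    m <- matrix(as.numeric(risk_code), grid$n_rows, grid$n_cols)
    rr <- raster_layer(m, grid, "risk_code")
  }
  structure(list(cells = cells, n_unassigned = sum(!assigned),
                 tract_summary = tract_summary, risk_raster = rr),
            class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  cells <- x$cells[!is.na(x$cells$risk_code), ]
  cat(sprintf("risk_map: %d classified cells (%d unassigned/missing)\n",
              nrow(cells), x$n_unassigned))
  cat(sprintf("  high-risk cells: %d (%.1f%%)\n", sum(cells$high_risk),
              100 * mean(cells$high_risk)))
  print(table(hazard = cells$hazard_level,
              vulnerability = cells$vulnerability_tertile))
  invisible(x)
}

RUCA_CLASSES <- c("metropolitan", "micropolitan", "small town", "rural",
                  "uncoded")

# primary RUCA code 1-10 -> aggregated class
ruca_aggregate <- function(code) {
  if (any(!is.na(code) & (code < 1 | code > 10)))
    stop("RUCA codes must lie in 1..10 (or be missing)")
  cls <- ifelse(is.na(code), "uncoded",
                ifelse(code <= 3, "metropolitan",
                       ifelse(code <= 6, "micropolitan",
                              ifelse(code <= 9, "small town", "rural"))))
  factor(cls, levels = RUCA_CLASSES)
}

#' Cross-tabulate risk classes by rural-urban class
#'
#' Aggregates primary rural-urban commuting-area codes (1-3 metropolitan,
#' 4-6 micropolitan, 7-9 small town, 10 rural, missing = uncoded) and
#' cross-tabulates cell risk classes against them.
#'
#' @param risk a `risk_map` from [classify_risk()].
#' @param tracts table with `tract_id` and `ruca_code`.
#' @return A `ruca_summary`: `counts` (ruca class x risk code table),
#'   `high_risk_share` per ruca class, `n_cells` per ruca class.
#' @export
summarize_by_ruca <- function(risk, tracts) {
  stopifnot(inherits(risk, "risk_map"))
  bad <- !is.na(tracts$ruca_code) &
    (tracts$ruca_code < 1 | tracts$ruca_code > 10)
  if (any(bad))
    stop("RUCA code out of range for tract(s): ",
         paste(tracts$tract_id[bad], collapse = ", "))
  ru <- stats::setNames(ruca_aggregate(tracts$ruca_code), tracts$tract_id)
  cells <- risk$cells[!is.na(risk$cells$risk_code), ]
  cls <- ru[cells$tract_id]
  counts <- table(ruca = cls, risk_code = cells$risk_code)
  hshare <- tapply(cells$high_risk, cls, mean)
  ncell <- tapply(cells$high_risk, cls, length)
  structure(list(counts = counts,
                 high_risk_share = hshare,
                 n_cells = ncell),
            class = "ruca_summary")
}

#' @export
print.ruca_summary <- function(x, ...) {
  cat("ruca_summary (cells per rural-urban class and risk code):\n")
  print(x$counts)
  cat("\nhigh-risk share by class:\n")
  print(round(x$high_risk_share, 4))
  invisible(x)
}
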