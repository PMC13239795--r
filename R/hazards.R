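# Hazard metrics: daily exceedance ("anomaly") counting against monthly
# climate normals or fixed concentration thresholds, per-pixel linear trends
# in annual anomaly frequency, cumulative exposure, and the Low/Moderate/High
# tertile classification used throughout the analysis.

#' Define an anomaly (exceedance) rule
#'
#' An anomaly is a day whose value strictly exceeds its comparator: the
#' pixel's monthly climate normal (`kind = "above_monthly_normal"`) or a
#' fixed concentration threshold (`kind = "above_fixed_threshold"`).
#' Boundary values equal to the comparator do not count.
#'
#' @param kind comparator type.
#' @param threshold fixed threshold in µg/m³ (fixed kind only; the
#'   conventional values are 35 for PM2.5 and 1 for black carbon).
#' @param months restrict counting to these months (integers 1-12), or
#'   `NULL` for all days. Temperature anomalies are conventionally restricted
#'   to the meteorological summer `c(6, 7, 8)`.
#' @param max_missing_frac a pixel-year with more than this fraction of
#'   missing qualifying days is flagged missing.
#' @export
anomaly_rule <- function(kind = c("above_monthly_normal",
                                  "above_fixed_threshold"),
                         threshold = NULL, months = NULL,
                         max_missing_frac = 0.1) {
  kind <- match.arg(kind)
  if (kind == "above_fixed_threshold") {
    if (is.null(threshold) || threshold <= 0)
      stop("a positive threshold is required for the fixed-threshold rule")
  } else threshold <- NULL
  if (!is.null(months)) {
    months <- as.integer(months)
    stopifnot(all(months %in% 1:12))
  }
  structure(list(kind = kind, threshold = threshold, months = months,
                 max_missing_frac = max_missing_frac),
            class = "anomaly_rule")
}

#' Count anomaly days per pixel and year
#'
#' Applies an [anomaly_rule()] to a [daily_field_series()]: for every pixel
#' and study year, counts the days (restricted to `rule$months` if set) whose
#' value strictly exceeds the comparator -- the pixel's normal for the day's
#' month, or the fixed threshold. A pixel-year with more than
#' `rule$max_missing_frac` of its qualifying days missing is set to `NA`.
#'
#' @param series a [daily_field_series()].
#' @param rule an [anomaly_rule()].
#' @param normals named list of monthly normal rasters on the same grid
#'   (names `"Jun"`, `"Jul"`, `"Aug"` or month numbers); required iff the
#'   rule compares against monthly normals.
#' @return An `anomaly_counts` object: `grid`, `years`, integer array
#'   `counts[n_rows, n_cols, n_years]`, and the `rule`.
#' @export
count_anomalies <- function(series, rule, normals = NULL) {
  stopifnot(inherits(series, "daily_field_series"),
            inherits(rule, "anomaly_rule"))
  g <- series$grid
  lt <- as.POSIXlt(series$dates)
  mon <- lt$mon + 1L
  yr <- lt$year + 1900L
  keep <- if (is.null(rule$months)) rep(TRUE, length(mon)) else
    mon %in% rule$months
  if (!any(keep)) stop("no days match the rule's month restriction")

  if (rule$kind == "above_monthly_normal") {
    if (is.null(normals)) stop("monthly normals are required for this rule")
    names(normals) <- normalize_month_names(names(normals))
    need <- unique(mon[keep])
    miss <- setdiff(as.character(need), names(normals))
    if (length(miss))
      stop("normals missing for month(s): ", paste(miss, collapse = ", "))
    for (nm in names(normals)) check_conforms(normals[[nm]], g, "normals")
    if (!all(vapply(normals, function(m) nrow(m) == g$n_rows &&
                      ncol(m) == g$n_cols, TRUE)))
      stop("normals grid mismatch")
  } else if (!is.null(normals)) {
    stop("normals must be absent for the fixed-threshold rule")
  }

  years <- sort(unique(yr[keep]))
  counts <- array(NA_integer_, c(g$n_rows, g$n_cols, length(years)))
  for (iy in seq_along(years)) {
    idx <- which(keep & yr == years[iy])
    exceed <- matrix(0L, g$n_rows, g$n_cols)
    nmiss <- matrix(0L, g$n_rows, g$n_cols)
    for (d in idx) {
      v <- series$values[, , d]
      cmp <- if (rule$kind == "above_fixed_threshold") rule$threshold else
        normals[[as.character(mon[d])]]
      e <- v > cmp
      na <- is.na(e)
      e[na] <- FALSE
      exceed <- exceed + e
      nmiss <- nmiss + na
    }
    exceed[nmiss > rule$max_missing_frac * length(idx)] <- NA_integer_
    counts[, , iy] <- exceed
  }
  structure(list(grid = g, years = years, counts = counts, rule = rule,
                 variable = series$variable),
            class = "anomaly_counts")
}

# accept "Jun"/"Jul"/"Aug" or "6"/"7"/... as normals names; return month numbers
normalize_month_names <- function(nms) {
  if (is.null(nms)) stop("normals must be a named list (month names)")
  out <- ifelse(nms %in% names(SUMMER_MONTHS),
                as.character(SUMMER_MONTHS[nms]), nms)
  if (any(is.na(suppressWarnings(as.integer(out)))))
    stop("unrecognized month name in normals: ", paste(nms, collapse = ", "))
  out
}

#' @export
print.anomaly_counts <- function(x, ...) {
  cat(sprintf("anomaly_counts (%s, %s): %d x %d grid, years %d-%d\n",
              x$variable, x$rule$kind, x$grid$n_rows, x$grid$n_cols,
              min(x$years), max(x$years)))
  invisible(x)
}

#' Reshape anomaly counts into regression-ready annual series
#'
#' Identity reshaping of an `anomaly_counts` array into a pixels-by-years
#' matrix (pixels in matrix storage order), the form consumed by
#' [fit_pixel_trend()]. Totals are conserved; missing pixel-years stay `NA`
#' and pixels carrying any missing year are flagged.
#'
#' @param counts an `anomaly_counts` object from [count_anomalies()].
#' @return List with `years`, matrix `freq` (`n_pixels x n_years`), and
#'   logical `has_missing` per pixel.
#' @export
annual_frequency <- function(counts) {
  stopifnot(inherits(counts, "anomaly_counts"))
  np <- counts$grid$n_rows * counts$grid$n_cols
  freq <- matrix(counts$counts, np, length(counts$years))
  colnames(freq) <- counts$years
  list(years = counts$years, freq = freq,
       has_missing = rowSums(is.na(freq)) > 0)
}

#' Fit per-pixel linear trends in annual anomaly frequency
#'
#' Ordinary least squares per pixel with year as the predictor and the
#' annual anomaly count as the outcome. Years are mean-centered internally
#' (the slope is invariant to centering); the p-value comes from the
#' two-sided t-test of the slope. Pixels with fewer than 3 non-missing years
#' get a slope but no inference; below `min_years` everything is missing.
#'
#' @param counts an `anomaly_counts` object, or the list from
#'   [annual_frequency()].
#' @param min_years minimum non-missing years for a slope (default 2).
#' @param fdr if `TRUE`, add Benjamini-Hochberg adjusted p-values
#'   (`p_adj`); off by default.
#' @return A `trend_grid`: matrices `slope`, `intercept` (value at the mean
#'   year), `p_value`, `se`, and `n_years`, on the counts' grid. For
#'   vector input (no grid), the same fields as vectors.
#' @export
fit_pixel_trend <- function(counts, min_years = 2L, fdr = FALSE) {
  if (inherits(counts, "anomaly_counts")) {
    af <- annual_frequency(counts)
    grid <- counts$grid
  } else {
    af <- counts
    grid <- NULL
  }
  y <- af$freq
  yrs <- as.numeric(af$years)
  np <- nrow(y)
  slope <- intercept <- pval <- se <- rep(NA_real_, np)
  nyr <- integer(np)

  ok <- !is.na(y)
  nyr <- rowSums(ok)
  complete <- nyr == length(yrs)

  fit_rows <- function(Y, x) {
    # vectorized OLS on rows of Y against x (no missing values)
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    b <- as.vector(Y %*% xc) / sxx
    a <- rowMeans(Y)
    res <- Y - outer(a, rep(1, length(x))) - outer(b, xc)
    df <- length(x) - 2L
    s2 <- rowSums(res^2) / max(df, 1L)
    seb <- sqrt(s2 / sxx)
    p <- if (df >= 1L) 2 * stats::pt(-abs(b / seb), df) else rep(NA_real_, nrow(Y))
    list(slope = b, intercept = a, se = seb, p = p)
  }

  if (any(complete) && length(yrs) >= 2L) {
    f <- fit_rows(y[complete, , drop = FALSE], yrs)
    slope[complete] <- f$slope; intercept[complete] <- f$intercept
    se[complete] <- f$se; pval[complete] <- f$p
  }
  partial <- which(!complete & nyr >= max(2L, min_years))
  for (i in partial) {
    sel <- ok[i, ]
    f <- fit_rows(y[i, sel, drop = FALSE], yrs[sel])
    slope[i] <- f$slope; intercept[i] <- f$intercept
    se[i] <- f$se; pval[i] <- f$p
  }
  pval[nyr < 3L] <- NA_real_                    # inference needs >= 3 years
  padj <- if (fdr) stats::p.adjust(pval, "BH") else NULL

  shape <- function(v) if (is.null(grid)) v else
    matrix(v, grid$n_rows, grid$n_cols)
  structure(list(grid = grid, slope = shape(slope),
                 intercept = shape(intercept), se = shape(se),
                 p_value = shape(pval),
                 p_adj = if (is.null(padj)) NULL else shape(padj),
                 n_years = shape(nyr), years = af$years),
            class = "trend_grid")
}

#' @export
print.trend_grid <- function(x, ...) {
  s <- x$slope[!is.na(x$slope)]
  cat(sprintf("trend_grid over %d years: mean slope %.3f (range %.3f .. %.3f), %d missing\n",
              length(x$years), mean(s), min(s), max(s), sum(is.na(x$slope))))
  invisible(x)
}

#' Cumulative exposure over the study period
#'
#' Per-pixel sum of annual anomaly counts over all years. Missing pixel-years
#' are excluded from the sum; a companion coverage raster reports how many
#' years contributed per pixel (pixels with zero coverage are `NA`).
#'
#' @param counts an `anomaly_counts` object.
#' @return List of two [raster_layer()]s: `total` and `coverage`.
#' @export
cumulative_exposure <- function(counts) {
  stopifnot(inherits(counts, "anomaly_counts"))
  total <- apply(counts$counts, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  })
  cover <- apply(!is.na(counts$counts), c(1, 2), sum)
  list(total = raster_layer(total, counts$grid,
                            paste0("cumulative_", counts$variable)),
       coverage = raster_layer(cover, counts$grid, "coverage_years"))
}

#' Classify values onto the Low/Moderate/High tertile scale
#'
#' Breakpoints are the 1/3 and 2/3 quantiles (linear interpolation between
#' order statistics, the standard type-7 definition) of all non-missing
#' units. A unit is `Low` if its value is `<= q33`, `Moderate` if in
#' `(q33, q67]`, else `High`; ties at a breakpoint fall to the lower class,
#' so degenerate distributions (e.g. a mass of zeros) collapse classes --
#' mirroring the convention that the low category absorbs null exposure --
#' and emit a warning.
#'
#' @param score numeric vector, matrix or [raster_layer()] of the scored
#'   quantity.
#' @param score_name label carried into the result.
#' @return A `tertile_field`: `labels` (ordered factor, same shape as the
#'   input), `breaks = c(q33, q67)`, `score_name`, and integer `codes`
#'   (1/2/3, `NA` for missing).
#' @export
tertile_classify <- function(score, score_name = deparse(substitute(score))) {
  grid <- NULL
  if (inherits(score, "raster_layer")) {
    grid <- score$grid
    score_name <- score$name
    score <- score$values
  }
  v <- as.vector(score)
  if (sum(!is.na(v)) < 3L)
    stop("tertile classification needs at least 3 non-missing units")
  q <- stats::quantile(v, probs = c(1, 2) / 3, na.rm = TRUE, type = 7,
                       names = FALSE)
  if (q[1] == q[2])
    warning("degenerate tertiles: q33 == q67; classes collapse under the ",
            "ties-to-lower rule")
  code <- ifelse(is.na(v), NA_integer_,
                 ifelse(v <= q[1], 1L, ifelse(v <= q[2], 2L, 3L)))
  lab <- factor(c("Low", "Moderate", "High")[code],
                levels = c("Low", "Moderate", "High"), ordered = TRUE)
  if (is.matrix(score)) {
    dim(code) <- dim(score)
    lab <- matrix(as.character(lab), nrow(score), ncol(score))
  }
  structure(list(labels = lab, codes = code, breaks = c(q33 = q[1], q67 = q[2]),
                 score_name = score_name, grid = grid),
            class = "tertile_field")
}

#' @export
print.tertile_field <- function(x, ...) {
  tab <- table(factor(c("Low", "Moderate", "High")[x$codes],
                      levels = c("Low", "Moderate", "High")))
  cat(sprintf("tertile_field '%s': q33 = %.4g, q67 = %.4g\n", x$score_name,
              x$breaks[1], x$breaks[2]))
  print(tab)
  invisible(x)
}
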