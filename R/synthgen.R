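# Seeded synthetic scenario generator. Emulates the statistical structure of
# the analysis inputs -- smooth monthly temperature normals, daily maxima with
# AR(1) noise and a calibrated warming drift, log-normal pollutant fields with
# Gaussian spatial blobs, and a tract table whose 12 vulnerability percentages
# come from a one-factor model calibrated to a target PC1 explained variance.
# Everything is a pure function of (scenario, seed).

VULN_VARS <- c(
  # race/ethnicity
  "pct_african_american", "pct_hispanic", "pct_asian",
  "pct_alaska_pacific_islander",
  # access to care / transportation
  "pct_no_health_insurance", "pct_no_vehicle",
  # financial vulnerability
  "pct_federal_assistance", "pct_households_poverty", "pct_unemployed",
  # other
  "pct_language_barrier", "pct_foreign_born", "pct_single_parent")

SUMMER_MONTHS <- c(Jun = 6L, Jul = 7L, Aug = 8L)

# run expr with a private, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  expr
}

# fixed per-stream offsets so adding a generator never perturbs existing ones
child_seed <- function(scenario, stream) {
  offs <- c(normals = 101L, temperature = 202L, pm25 = 303L, bc = 404L,
            tracts = 505L, misc = 606L)
  (as.integer(scenario$seed) + offs[[stream]]) %% .Machine$integer.max
}

#' Define a synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generators: the coarse (~4 km
#' analogue) and fine (~1 km analogue) grids, the study years, monthly summer
#' temperature normals and the injected warming slope, pollutant baselines and
#' blob amplitudes, and the one-factor vulnerability model with its target
#' leading-eigenvalue share. Defaults describe the package's reference study
#' conditions; see the methods vignette for the rationale behind each value.
#'
#' @param seed master integer seed; per-stream child seeds are derived from it
#'   by fixed offsets.
#' @param grid_coarse,grid_fine [grid_spec()]s with an integer resolution
#'   ratio and a shared origin/extent.
#' @param years inclusive range of study years.
#' @param normals_base named vector of mean summer normals (deg F), names
#'   among `"Jun","Jul","Aug"`.
#' @param normals_amplitude amplitude (deg F) of the smooth spatial structure
#'   of the normals; 0 gives spatially constant normals.
#' @param temp_sd marginal standard deviation (deg F) of the daily AR(1)
#'   deviation from the normal.
#' @param ar_coef AR(1) coefficient of the day-to-day temperature noise.
#' @param base_exceed_prob probability that a day exceeds its normal in the
#'   middle study year (0.5 = days split evenly around the normal).
#' @param warming_slope injected trend, in anomaly-days per year, of the
#'   expected annual exceedance count.
#' @param hot_region optional `list(xmin, xmax, ymin, ymax, offset)` adding a
#'   constant temperature offset (deg F) inside a rectangle.
#' @param pollutant_base named vector `c(pm25=, bc=)`, median (µg/m³) of the
#'   log-normal baseline concentration; must be positive.
#' @param pollutant_sdlog log-scale standard deviation of the baseline.
#' @param pollutant_blob_amplitude named vector `c(pm25=, bc=)`, peak added
#'   concentration (µg/m³) of the Gaussian spatial blob.
#' @param blob_radius e-folding radius (map units) of the Gaussian blobs.
#' @param pollutant_trend named vector `c(pm25=, bc=)`, additive drift in
#'   µg/m³ per year.
#' @param urban_core `c(x, y)` of the designated urban core (defaults to the
#'   grid center); pollutant blobs, the hot region and the rural-urban
#'   gradient are anchored there.
#' @param n_tracts number of tracts in the rectangular tessellation (>= 4).
#' @param factor_loadings length-12 loading pattern in `[0, 1]` (relative,
#'   rescaled during calibration).
#' @param target_pc1_variance fraction of variance, in `(1/12, 1)`, that the
#'   leading principal component of the log10-transformed standardized tract
#'   table should explain.
#' @param factor_spatial_weight weight in `[0, 1)` of the urban-core gradient
#'   in the latent vulnerability factor (0 = spatially unstructured).
#' @param vuln_noise_sd unique-variance multiplier for the 12 indicators;
#'   1 keeps unit total variance, 0 gives noiseless rank-1 indicators.
#' @param n_uncoded_tracts number of tracts left without a rural-urban code.
#' @return An object of class `risk_scenario`.
#' @examples
#' sc <- risk_scenario(seed = 1, years = 2012:2014, n_tracts = 16,
#'                     grid_coarse = grid_spec(0, 0, 4000, 5, 5),
#'                     grid_fine = grid_spec(0, 0, 1000, 20, 20))
#' nrm <- generate_normals(sc)
#' dim(nrm$Jun)
#' @export
risk_scenario <- function(seed = 1L,
                          grid_coarse = grid_spec(0, 0, 4000, 25, 25),
                          grid_fine = grid_spec(0, 0, 1000, 100, 100),
                          years = 2012:2024,
                          normals_base = c(Jun = 85, Jul = 90, Aug = 88),
                          normals_amplitude = 3,
                          temp_sd = 5,
                          ar_coef = 0.5,
                          base_exceed_prob = 0.5,
                          warming_slope = 1.0,
                          hot_region = NULL,
                          pollutant_base = c(pm25 = 8, bc = 0.4),
                          pollutant_sdlog = 0.5,
                          pollutant_blob_amplitude = c(pm25 = 25, bc = 0.9),
                          blob_radius = 15000,
                          pollutant_trend = c(pm25 = 0, bc = 0),
                          urban_core = NULL,
                          n_tracts = 400,
                          factor_loadings = rep(1, 12),
                          target_pc1_variance = 0.23,
                          factor_spatial_weight = 0.5,
                          vuln_noise_sd = 1,
                          n_uncoded_tracts = 0) {
  stopifnot(inherits(grid_coarse, "grid_spec"), inherits(grid_fine, "grid_spec"))
  if (length(years) == 0L) stop("years must be non-empty")
  years <- sort(unique(as.integer(years)))
  if (!all(names(normals_base) %in% names(SUMMER_MONTHS)))
    stop("unknown month in normals_base: only Jun, Jul, Aug are supported")
  ratio <- grid_coarse$cell_size / grid_fine$cell_size
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("coarse/fine cell size ratio must be an integer")
  if (length(factor_loadings) != 12L)
    stop("factor_loadings must have length 12")
  if (any(factor_loadings < 0 | factor_loadings > 1))
    stop("factor_loadings must lie in [0, 1]")
  if (target_pc1_variance <= 1 / 12 || target_pc1_variance >= 1)
    stop("target_pc1_variance must lie in (1/12, 1) for a one-factor model")
  if (factor_spatial_weight < 0 || factor_spatial_weight >= 1)
    stop("factor_spatial_weight must lie in [0, 1)")
  if (is.null(urban_core)) {
    ext <- grid_extent(grid_fine)
    urban_core <- c(x = mean(ext[c("xmin", "xmax")]),
                    y = mean(ext[c("ymin", "ymax")]))
  }
  if (!is.null(hot_region))
    stopifnot(all(c("xmin", "xmax", "ymin", "ymax", "offset") %in%
                    names(hot_region)))
  sc <- list(seed = as.integer(seed), grid_coarse = grid_coarse,
             grid_fine = grid_fine, years = years,
             normals_base = normals_base,
             normals_amplitude = normals_amplitude, temp_sd = temp_sd,
             ar_coef = ar_coef, base_exceed_prob = base_exceed_prob,
             warming_slope = warming_slope, hot_region = hot_region,
             pollutant_base = pollutant_base,
             pollutant_sdlog = pollutant_sdlog,
             pollutant_blob_amplitude = pollutant_blob_amplitude,
             blob_radius = blob_radius, pollutant_trend = pollutant_trend,
             urban_core = urban_core, n_tracts = as.integer(n_tracts),
             factor_loadings = as.numeric(factor_loadings),
             target_pc1_variance = target_pc1_variance,
             factor_spatial_weight = factor_spatial_weight,
             vuln_noise_sd = vuln_noise_sd,
             n_uncoded_tracts = as.integer(n_uncoded_tracts))
  class(sc) <- "risk_scenario"
  sc
}

#' @export
print.risk_scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "risk_scenario (seed %d)\n",
    "  coarse %dx%d @ %g, fine %dx%d @ %g\n",
    "  years %d-%d, warming slope %g anomaly-days/yr\n",
    "  %d tracts, target PC1 variance %.2f\n"),
    x$seed, x$grid_coarse$n_rows, x$grid_coarse$n_cols,
    x$grid_coarse$cell_size, x$grid_fine$n_rows, x$grid_fine$n_cols,
    x$grid_fine$cell_size, min(x$years), max(x$years), x$warming_slope,
    x$n_tracts, x$target_pc1_variance))
  invisible(x)
}

# smooth low-order polynomial + fixed sinusoid around a base level
smooth_field <- function(grid, base, amplitude) {
  if (amplitude == 0) return(matrix(base, grid$n_rows, grid$n_cols))
  cc <- cell_centers(grid)
  ext <- grid_extent(grid)
  X <- matrix((cc$x - ext["xmin"]) / (ext["xmax"] - ext["xmin"]) * 2 - 1,
              grid$n_rows, grid$n_cols)
  Y <- matrix((cc$y - ext["ymin"]) / (ext["ymax"] - ext["ymin"]) * 2 - 1,
              grid$n_rows, grid$n_cols)
  a <- stats::runif(5, -1, 1)
  poly <- a[1] * X + a[2] * Y + a[3] * X * Y + a[4] * X^2 + a[5] * Y^2
  sinu <- 0.5 * sin(pi * X) * cos(pi * Y)
  base + amplitude * (poly / 2 + sinu)
}

#' Generate smooth monthly temperature normals
#'
#' Produces one raster of long-term monthly mean daily-maximum temperature
#' (deg F) per requested summer month on the scenario's coarse grid: a smooth
#' low-order spatial polynomial plus a fixed sinusoid around the scenario's
#' monthly base level. Deterministic given the scenario seed.
#'
#' @param scenario a [risk_scenario()].
#' @param months character subset of `names(scenario$normals_base)`.
#' @return Named list (by month abbreviation) of value matrices on
#'   `scenario$grid_coarse`.
#' @export
generate_normals <- function(scenario, months = names(scenario$normals_base)) {
  stopifnot(inherits(scenario, "risk_scenario"))
  bad <- setdiff(months, names(SUMMER_MONTHS))
  if (length(bad)) stop("unknown month(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(months, names(scenario$normals_base))
  if (length(bad)) stop("no normals base level for: ", paste(bad, collapse = ", "))
  with_seed(child_seed(scenario, "normals"), {
    out <- lapply(months, function(m)
      smooth_field(scenario$grid_coarse, scenario$normals_base[[m]],
                   scenario$normals_amplitude))
    names(out) <- months
    out
  })
}

# calendar dates of the meteorological summer (Jun 1 .. Aug 31) of each year
summer_dates <- function(years) {
  as.Date(unlist(lapply(years, function(y)
    seq(as.Date(sprintf("%d-06-01", y)), as.Date(sprintf("%d-08-31", y)),
        by = "day"))), origin = "1970-01-01")
}

# per-year drift (deg F) such that the expected exceedance count over the
# normals changes linearly by warming_slope anomaly-days per year
warming_drift <- function(scenario, n_days_per_year = 92) {
  yrs <- scenario$years
  tmid <- mean(yrs)
  p <- scenario$base_exceed_prob +
    scenario$warming_slope * (yrs - tmid) / n_days_per_year
  if (any(p <= 0 | p >= 1))
    stop("warming_slope too steep for the year range: exceedance probability ",
         "leaves (0,1)")
  if (scenario$temp_sd == 0) {
    if (scenario$warming_slope != 0)
      stop("cannot calibrate a nonzero warming_slope with temp_sd = 0")
    return(stats::setNames(rep(0, length(yrs)), yrs))
  }
  stats::setNames(scenario$temp_sd * stats::qnorm(p), yrs)
}

#' Generate daily maximum temperature fields
#'
#' Simulates summer (June-August) daily maximum temperature on the coarse
#' grid: the monthly normal, plus AR(1) day-to-day noise, plus a year-indexed
#' drift calibrated so the expected count of days exceeding the normal rises
#' by `warming_slope` anomaly-days per year, plus an optional constant offset
#' inside the scenario's hot region.
#'
#' @param scenario a [risk_scenario()].
#' @return A [daily_field_series()] with variable `"tmax_F"`.
#' @export
generate_daily_temperature <- function(scenario) {
  stopifnot(inherits(scenario, "risk_scenario"))
  g <- scenario$grid_coarse
  if (!all(c("Jun", "Jul", "Aug") %in% names(scenario$normals_base)))
    stop("daily temperature needs normals for Jun, Jul and Aug")
  normals <- generate_normals(scenario, c("Jun", "Jul", "Aug"))
  dates <- summer_dates(scenario$years)
  mon <- as.POSIXlt(dates)$mon + 1L
  yr <- as.POSIXlt(dates)$year + 1900L
  drift <- warming_drift(scenario)
  npix <- g$n_rows * g$n_cols
  nd <- length(dates)
  phi <- scenario$ar_coef
  sdm <- scenario$temp_sd

  vals <- matrix(0, npix, nd)
  with_seed(child_seed(scenario, "temperature"), {
    e_prev <- NULL
    prev_year <- NA_integer_
    for (d in seq_len(nd)) {
      if (is.na(prev_year) || yr[d] != prev_year) {
        e <- stats::rnorm(npix, 0, sdm)          # stationary start each summer
      } else {
        e <- phi * e_prev + stats::rnorm(npix, 0, sdm * sqrt(1 - phi^2))
      }
      vals[, d] <- e
      e_prev <- e
      prev_year <- yr[d]
    }
  })
  mono <- c(`6` = "Jun", `7` = "Jul", `8` = "Aug")
  for (d in seq_len(nd)) {
    vals[, d] <- vals[, d] + as.vector(normals[[mono[[as.character(mon[d])]]]]) +
      drift[[as.character(yr[d])]]
  }
  if (!is.null(scenario$hot_region)) {
    hr <- scenario$hot_region
    cc <- cell_centers(g)
    inside <- cc$x >= hr$xmin & cc$x <= hr$xmax &
      cc$y >= hr$ymin & cc$y <= hr$ymax
    vals[inside, ] <- vals[inside, ] + hr$offset
  }
  daily_field_series(g, "tmax_F", dates,
                     array(vals, c(g$n_rows, g$n_cols, nd)))
}

#' Generate daily pollutant concentration fields
#'
#' Simulates daily mean PM2.5 and black carbon concentration on the fine
#' grid: an i.i.d. log-normal baseline (median `pollutant_base`, log-sd
#' `pollutant_sdlog`) plus a static Gaussian spatial blob anchored at the
#' scenario's urban core, plus an optional linear year drift. Expected
#' threshold-exceedance counts are monotone in the blob amplitude, and the
#' fields are deterministic given the scenario seed.
#'
#' @param scenario a [risk_scenario()].
#' @return Named list `list(pm25 = , bc = )` of [daily_field_series()]
#'   objects on `scenario$grid_fine`.
#' @export
generate_daily_pollutants <- function(scenario) {
  stopifnot(inherits(scenario, "risk_scenario"))
  if (any(scenario$pollutant_base <= 0))
    stop("pollutant_base must be positive")
  g <- scenario$grid_fine
  dates <- summer_dates(scenario$years)
  yr <- as.POSIXlt(dates)$year + 1900L
  tmid <- mean(scenario$years)
  npix <- g$n_rows * g$n_cols
  nd <- length(dates)
  cc <- cell_centers(g)
  d2 <- (cc$x - scenario$urban_core[["x"]])^2 +
    (cc$y - scenario$urban_core[["y"]])^2
  blob_shape <- exp(-d2 / (2 * scenario$blob_radius^2))

  one <- function(which, stream) {
    base <- scenario$pollutant_base[[which]]
    amp <- scenario$pollutant_blob_amplitude[[which]]
    trend <- scenario$pollutant_trend[[which]]
    vals <- with_seed(child_seed(scenario, stream),
                      matrix(stats::rlnorm(npix * nd, meanlog = log(base),
                                           sdlog = scenario$pollutant_sdlog),
                             npix, nd))
    vals <- vals + amp * blob_shape            # recycled down columns
    if (trend != 0)
      vals <- vals + rep(trend * (yr - tmid), each = npix)
    vals[vals < 0] <- 0
    daily_field_series(g, if (which == "pm25") "pm25_ugm3" else "bc_ugm3",
                       dates, array(vals, c(g$n_rows, g$n_cols, nd)))
  }
  list(pm25 = one("pm25", "pm25"), bc = one("bc", "bc"))
}

# split 1..n into k contiguous near-equal bands; returns band index per unit
band_index <- function(n, k) {
  bounds <- round(seq(0, n, length.out = k + 1))
  rep(seq_len(k), times = diff(bounds))
}

# rescale a one-factor loading pattern so the top eigenvalue of the implied
# correlation matrix R = diag(1 - l^2) + l l' equals 12 * target
calibrate_loadings <- function(pattern, target) {
  p <- length(pattern)
  if (all(abs(pattern - pattern[1]) < 1e-12)) {
    lam2 <- (p * target - 1) / (p - 1)
    return(rep(sqrt(lam2), p))
  }
  top_share <- function(s) {
    l <- s * pattern
    R <- diag(1 - l^2) + tcrossprod(l)
    eigen(R, symmetric = TRUE, only.values = TRUE)$values[1] / p
  }
  upper <- 0.999 / max(pattern)
  if (top_share(upper) < target)
    stop("target_pc1_variance unreachable for this loading pattern")
  s <- stats::uniroot(function(s) top_share(s) - target, c(1e-6, upper),
                      tol = 1e-10)$root
  s * pattern
}

#' Generate the synthetic tract table
#'
#' Tessellates the fine grid into rectangular tracts and draws the 12
#' pediatric vulnerability percentages from a one-factor linear model
#' calibrated so that the leading principal component of the
#' log10-transformed, standardized table explains approximately
#' `target_pc1_variance`. The latent factor optionally carries an urban-core
#' gradient so vulnerability clusters near the core like it does in real
#' tract data. Rural-urban codes 1-10 are assigned by centroid distance bands
#' from the core (1-3 near the core, 10 at the periphery).
#'
#' @param scenario a [risk_scenario()].
#' @return A `tract_table`: a data.frame with `tract_id`, rectangle bounds,
#'   centroid coordinates, `ruca_code` and the 12 percentage columns (all in
#'   `[0, 100]`). The realized latent factor and the calibrated standardized
#'   loadings are attached as attributes `"latent_factor"` and
#'   `"loadings_std"`.
#' @export
generate_tracts <- function(scenario) {
  stopifnot(inherits(scenario, "risk_scenario"))
  n <- scenario$n_tracts
  if (n < 4L) stop("n_tracts must be at least 4 (tertiles undefined below)")
  g <- scenario$grid_fine
  # near-square factorization n = a (row bands) x b (col bands)
  divs <- which(n %% seq_len(floor(sqrt(n))) == 0)
  a <- max(divs); b <- n %/% a
  if (a > g$n_rows || b > g$n_cols)
    stop("n_tracts does not tessellate the fine grid")
  rb <- round(seq(0, g$n_rows, length.out = a + 1))
  cb <- round(seq(0, g$n_cols, length.out = b + 1))
  if (any(diff(rb) < 1) || any(diff(cb) < 1))
    stop("n_tracts does not tessellate the fine grid")
  ext <- grid_extent(g)
  # tract t = (row band i, col band j); rows count from the north
  ij <- expand.grid(i = seq_len(a), j = seq_len(b))
  ymax <- ext[["ymax"]] - rb[ij$i] * g$cell_size
  ymin <- ext[["ymax"]] - rb[ij$i + 1] * g$cell_size
  xmin <- ext[["xmin"]] + cb[ij$j] * g$cell_size
  xmax <- ext[["xmin"]] + cb[ij$j + 1] * g$cell_size
  cx <- (xmin + xmax) / 2
  cy <- (ymin + ymax) / 2

  lam <- calibrate_loadings(scenario$factor_loadings,
                            scenario$target_pc1_variance)
  dcore <- sqrt((cx - scenario$urban_core[["x"]])^2 +
                  (cy - scenario$urban_core[["y"]])^2)
  w <- scenario$factor_spatial_weight
  tab <- with_seed(child_seed(scenario, "tracts"), {
    u <- as.numeric(scale(-dcore))             # high near the urban core
    f <- w * u + sqrt(1 - w^2) * stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * 12), n, 12)
    z <- f %*% t(lam) +
      eps * rep(scenario$vuln_noise_sd * sqrt(pmax(0, 1 - lam^2)), each = n)
    x <- 10^(1 + 0.25 * z) - 1
    x[x < 0] <- 0; x[x > 100] <- 100
    colnames(x) <- VULN_VARS
    uncoded <- if (scenario$n_uncoded_tracts > 0)
      sample(n, scenario$n_uncoded_tracts) else integer(0)
    list(x = x, f = f, uncoded = uncoded)
  })
  ruca <- pmin(10L, 1L + as.integer(floor(dcore / max(dcore) * 10)))
  ruca[tab$uncoded] <- NA_integer_
  out <- data.frame(tract_id = sprintf("T%04d", seq_len(n)),
                    xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                    centroid_x = cx, centroid_y = cy,
                    ruca_code = ruca, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(tab$x))
  attr(out, "latent_factor") <- tab$f
  attr(out, "loadings_std") <- lam
  attr(out, "target_pc1_variance") <- scenario$target_pc1_variance
  attr(out, "crs_label") <- g$crs_label
  class(out) <- c("tract_table", "data.frame")
  out
}

#' @export
print.tract_table <- function(x, ...) {
  cat(sprintf("tract_table: %d tracts, 12 vulnerability variables, %d uncoded\n",
              nrow(x), sum(is.na(x$ruca_code))))
  invisible(x)
}
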