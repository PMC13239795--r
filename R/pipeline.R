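# Pipeline orchestration: a validated configuration, per-stage caching with
# content digests, JSON-lines logging, and the end-to-end run from synthetic
# scenario generation through the bivariate risk map.

#' Build a validated pipeline configuration
#'
#' Collects every pipeline parameter: the synthetic scenario (or paths to
#' externally supplied inputs), anomaly thresholds, hotspot neighbourhood
#' sizes, significance level, bootstrap size, index methods, master seed and
#' the tertile/harmonization ordering switch. The resolved configuration is
#' written as YAML beside every run's outputs, and round-trips losslessly
#' through [write_config()]/[read_config()].
#'
#' @param scenario a [risk_scenario()] (the default synthetic input), or
#'   `NULL` when all inputs come from `paths`.
#' @param paths optional named list of input paths (raster stacks / tract
#'   GeoJSON) overriding the synthetic scenario.
#' @param pm25_threshold,bc_threshold fixed anomaly thresholds in µg/m³.
#' @param temp_months months of the temperature anomaly rule.
#' @param pollutant_months months of the pollutant rules (`NULL` = all
#'   days).
#' @param k hotspot neighbourhood size; `k_sensitivity` additional sizes
#'   compared in the sensitivity report.
#' @param alpha two-sided significance level for hot/cold classification.
#' @param bootstrap_B bootstrap replicates for the explained-variance CI
#'   (0 = skip).
#' @param methods index methods passed to [vuln_index()].
#' @param seed master seed (propagated to every seeded stage).
#' @param tertile_order `"harmonize_then_tertile"` (default) or
#'   `"tertile_then_harmonize"`.
#' @export
pipeline_config <- function(scenario = risk_scenario(),
                            paths = NULL,
                            pm25_threshold = 35, bc_threshold = 1,
                            temp_months = c(6L, 7L, 8L),
                            pollutant_months = NULL,
                            k = 20L, k_sensitivity = c(15L, 25L),
                            alpha = 0.05, bootstrap_B = 200L,
                            methods = c("pca", "efa"),
                            seed = NULL,
                            tertile_order = c("harmonize_then_tertile",
                                              "tertile_then_harmonize")) {
  tertile_order <- match.arg(tertile_order)
  if (is.null(seed)) seed <- if (!is.null(scenario)) scenario$seed else 1L
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "risk_scenario"))
    scenario$seed <- as.integer(seed)
  }
  stopifnot(pm25_threshold > 0, bc_threshold > 0, k >= 1L,
            alpha > 0, alpha < 1)
  structure(list(scenario = scenario, paths = paths,
                 pm25_threshold = pm25_threshold,
                 bc_threshold = bc_threshold,
                 temp_months = as.integer(temp_months),
                 pollutant_months = if (is.null(pollutant_months)) NULL else
                   as.integer(pollutant_months),
                 k = as.integer(k),
                 k_sensitivity = as.integer(k_sensitivity),
                 alpha = alpha, bootstrap_B = as.integer(bootstrap_B),
                 methods = methods, seed = as.integer(seed),
                 tertile_order = tertile_order),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$scenario <- if (is.null(x$scenario)) NULL else {
    sc <- unclass(x$scenario)
    sc$grid_coarse <- unclass(sc$grid_coarse)
    sc$grid_fine <- unclass(sc$grid_fine)
    sc$normals_base <- as.list(sc$normals_base)
    sc$pollutant_base <- as.list(sc$pollutant_base)
    sc$pollutant_blob_amplitude <- as.list(sc$pollutant_blob_amplitude)
    sc$pollutant_trend <- as.list(sc$pollutant_trend)
    sc$urban_core <- as.list(sc$urban_core)
    sc
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sc <- NULL
  if (!is.null(x$scenario)) {
    s <- x$scenario
    sc <- risk_scenario(
      seed = s$seed,
      grid_coarse = do.call(grid_spec, s$grid_coarse),
      grid_fine = do.call(grid_spec, s$grid_fine),
      years = s$years,
      normals_base = unlist(s$normals_base),
      normals_amplitude = s$normals_amplitude,
      temp_sd = s$temp_sd, ar_coef = s$ar_coef,
      base_exceed_prob = s$base_exceed_prob,
      warming_slope = s$warming_slope,
      hot_region = s$hot_region,
      pollutant_base = unlist(s$pollutant_base),
      pollutant_sdlog = s$pollutant_sdlog,
      pollutant_blob_amplitude = unlist(s$pollutant_blob_amplitude),
      blob_radius = s$blob_radius,
      pollutant_trend = unlist(s$pollutant_trend),
      urban_core = unlist(s$urban_core),
      n_tracts = s$n_tracts,
      factor_loadings = s$factor_loadings,
      target_pc1_variance = s$target_pc1_variance,
      factor_spatial_weight = s$factor_spatial_weight,
      vuln_noise_sd = s$vuln_noise_sd,
      n_uncoded_tracts = s$n_uncoded_tracts)
  }
  pipeline_config(scenario = sc, paths = x$paths,
                  pm25_threshold = x$pm25_threshold,
                  bc_threshold = x$bc_threshold,
                  temp_months = x$temp_months,
                  pollutant_months = x$pollutant_months,
                  k = x$k, k_sensitivity = x$k_sensitivity,
                  alpha = x$alpha, bootstrap_B = x$bootstrap_B,
                  methods = x$methods, seed = x$seed,
                  tertile_order = x$tertile_order)
}

# content digest of an R object (serialization md5); used to key stage caches
digest_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, compress = FALSE, version = 3)
  unname(tools::md5sum(tf))
}

# stage runner with rds caching: recomputes when the cache file is absent or
# its stored input digest no longer matches
run_stage <- function(name, deps, compute, cache_dir, log) {
  path <- file.path(cache_dir, paste0(name, ".rds"))
  dg <- digest_obj(deps)
  if (file.exists(path)) {
    st <- readRDS(path)
    if (identical(st$digest, dg)) {
      log(name, "cached", st$out_digest)
      return(st$value)
    }
  }
  t0 <- Sys.time()
  value <- compute()
  odg <- digest_obj(value)
  saveRDS(list(digest = dg, out_digest = odg, value = value), path,
          compress = FALSE)
  log(name, sprintf("computed in %.1fs", as.numeric(Sys.time() - t0,
                                                    units = "secs")), odg)
  value
}

#' Run the full risk-mapping pipeline
#'
#' Executes generation (for a synthetic scenario), anomaly counting, trend
#' fitting, harmonization onto the fine grid, co-exposure hotspot detection,
#' vulnerability-index construction, and the bivariate risk classification.
#' Every stage logs its parameters, seed and a content digest of its output
#' to `log.jsonl` in `out_dir`; stage results are cached as RDS under
#' `out_dir/cache`, so rerunning with an unchanged configuration only
#' recomputes stages whose cache was removed or whose inputs changed. The
#' resolved configuration is written as `config.yaml` beside the outputs,
#' together with CSV/JSON reports and ESRI ASCII rasters of the main
#' surfaces.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param write_rasters write the ASCII-grid raster outputs (default TRUE).
#' @return An object of class `ped_risk` bundling the stage results; see
#'   `print`/`summary` methods.
#' @export
run_pipeline <- function(config, out_dir = tempfile("pedrisk_"),
                         write_rasters = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$scenario))
    stop("external-input runs need a scenario-free loader; supply a scenario")
  sc <- config$scenario
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.jsonl")
  stages_run <- character(0)
  log <- function(stage, status, dg = NULL) {
    stages_run <<- c(stages_run, paste0(stage, ":", status))
    line <- jsonlite::toJSON(list(stage = stage, status = status,
                                  seed = config$seed, digest = dg),
                             auto_unbox = TRUE, null = "null")
    cat(line, "\n", sep = "", file = logf, append = TRUE)
  }
  write_config(config, file.path(out_dir, "config.yaml"))

  scdg <- digest_obj(unclass(sc))

  counts_temp <- run_stage("counts_temp", list(scdg, config$temp_months),
                           function() {
    normals <- generate_normals(sc)
    temp <- generate_daily_temperature(sc)
    rule <- anomaly_rule("above_monthly_normal", months = config$temp_months)
    count_anomalies(temp, rule, normals)
  }, cache_dir, log)

  counts_pol <- run_stage("counts_pollutants",
                          list(scdg, config$pm25_threshold,
                               config$bc_threshold, config$pollutant_months),
                          function() {
    pol <- generate_daily_pollutants(sc)
    list(pm25 = count_anomalies(pol$pm25,
           anomaly_rule("above_fixed_threshold",
                        threshold = config$pm25_threshold,
                        months = config$pollutant_months)),
         bc = count_anomalies(pol$bc,
           anomaly_rule("above_fixed_threshold",
                        threshold = config$bc_threshold,
                        months = config$pollutant_months)))
  }, cache_dir, log)

  cdg <- digest_obj(list(a = counts_temp$counts, b = counts_pol$pm25$counts,
                         c = counts_pol$bc$counts))

  trends <- run_stage("trends", cdg, function() {
    list(temp = fit_pixel_trend(counts_temp),
         pm25 = fit_pixel_trend(counts_pol$pm25),
         bc = fit_pixel_trend(counts_pol$bc))
  }, cache_dir, log)

  hazards_fine <- run_stage("hazards_fine", list(cdg, config$tertile_order),
                            function() {
    cum <- list(temp = cumulative_exposure(counts_temp)$total,
                pm25 = cumulative_exposure(counts_pol$pm25)$total,
                bc = cumulative_exposure(counts_pol$bc)$total)
    fine <- sc$grid_fine
    if (config$tertile_order == "harmonize_then_tertile") {
      cum_fine <- lapply(cum, resample_grid, target = fine,
                         kernel = "lanczos")
      tert <- lapply(cum_fine, tertile_classify)
    } else {
      tert_coarse <- lapply(cum, tertile_classify)
      cum_fine <- lapply(cum, resample_grid, target = fine,
                         kernel = "lanczos")
      tert <- lapply(names(cum), function(nm) {
        tl <- raster_layer(matrix(as.numeric(tert_coarse[[nm]]$codes),
                                  cum[[nm]]$grid$n_rows,
                                  cum[[nm]]$grid$n_cols),
                           cum[[nm]]$grid, paste0("tertile_", nm))
        codes <- resample_grid(tl, target = fine, kernel = "nearest")
        tc <- tert_coarse[[nm]]
        tc$codes <- matrix(as.integer(codes$values), fine$n_rows,
                           fine$n_cols)
        tc$labels <- matrix(c("Low", "Moderate", "High")[tc$codes],
                            fine$n_rows, fine$n_cols)
        tc$grid <- fine
        tc
      })
      names(tert) <- names(cum)
    }
    list(cumulative = cum, cumulative_fine = cum_fine, tertiles = tert)
  }, cache_dir, log)

  hotspots <- run_stage("hotspots", list(digest_obj(lapply(
    hazards_fine$cumulative_fine, function(l) l$values)),
    config$k, config$k_sensitivity, config$alpha), function() {
    score <- coexposure_score(hazards_fine$cumulative_fine)
    cc <- cell_centers(sc$grid_fine)
    ks <- sort(unique(c(config$k, config$k_sensitivity)))
    kw_max <- build_knn(cc[, c("x", "y")], max(ks))
    per_k <- lapply(ks, function(k) {
      g <- gi_star(as.vector(score$values), knn_subset(kw_max, k),
                   alpha = config$alpha)
      c(list(result = g), classify_spots(g, alpha = config$alpha))
    })
    names(per_k) <- paste0("k", ks)
    main <- per_k[[paste0("k", config$k)]]
    list(score = score, main = main, per_k = per_k, k = config$k)
  }, cache_dir, log)

  tracts <- run_stage("tracts", scdg, function() generate_tracts(sc),
                      cache_dir, log)

  index <- run_stage("vulnindex", list(digest_obj(as.data.frame(tracts)),
                                       config$methods, config$bootstrap_B,
                                       config$seed), function() {
    vuln_index(tracts, methods = config$methods,
               bootstrap_B = config$bootstrap_B, seed = config$seed)
  }, cache_dir, log)

  risk <- run_stage("riskmap", list(digest_obj(index$scores),
                                    digest_obj(lapply(hazards_fine$tertiles,
                                                      `[[`, "codes"))),
                    function() {
    fine <- sc$grid_fine
    tt <- hazards_fine$tertiles
    hz <- collapse_hazard(as.vector(tt$pm25$labels), as.vector(tt$bc$labels),
                          as.vector(tt$temp$labels))
    cell_tract <- join_cells_to_tracts(fine, tracts)
    vt <- tertile_classify(index$scores, "vulnerability_index")
    rm <- classify_risk(hz, cell_tract, vt, tracts$tract_id, grid = fine)
    list(risk = rm, ruca = summarize_by_ruca(rm, tracts),
         vuln_tertiles = vt, hazard_level = hz)
  }, cache_dir, log)

  # reports and rasters
  scores_df <- data.frame(tract_id = tracts$tract_id,
                          vuln_score = index$scores,
                          vuln_tertile = as.character(
                            risk$vuln_tertiles$labels))
  utils::write.csv(scores_df, file.path(out_dir, "vulnerability_scores.csv"),
                   row.names = FALSE)
  ld <- coef(index, "pca")
  utils::write.csv(data.frame(variable = rownames(ld), round(ld, 6)),
                   file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
  shares <- hotspots$main$shares
  utils::write.csv(data.frame(class = names(shares), share = shares),
                   file.path(out_dir, "hotspot_shares.csv"),
                   row.names = FALSE)
  utils::write.csv(risk$risk$tract_summary,
                   file.path(out_dir, "tract_risk_summary.csv"),
                   row.names = FALSE)
  ruca_df <- as.data.frame(risk$ruca$counts)
  utils::write.csv(ruca_df, file.path(out_dir, "ruca_summary.csv"),
                   row.names = FALSE)
  sel <- index$selection
  writeLines(jsonlite::toJSON(list(
    chosen = sel$chosen, criterion = as.list(sel$criterion),
    not_run = sel$not_run,
    spearman = sel$spearman), auto_unbox = TRUE, digits = NA, na = "null"),
    file.path(out_dir, "selection_report.json"))
  if (write_rasters) {
    write_ascii_grid(raster_layer(
      matrix(hotspots$main$result$z, sc$grid_fine$n_rows,
             sc$grid_fine$n_cols), sc$grid_fine, "gi_star_z"),
      path = file.path(out_dir, "gi_star_z.asc"))
    write_ascii_grid(risk$risk$risk_raster,
                     path = file.path(out_dir, "risk_code.asc"))
    write_tracts_geojson(tracts, file.path(out_dir, "tracts.geojson"))
  }

  structure(list(config = config, out_dir = out_dir,
                 counts = list(temp = counts_temp, pm25 = counts_pol$pm25,
                               bc = counts_pol$bc),
                 trends = trends, hazards = hazards_fine,
                 hotspots = hotspots, tracts = tracts, index = index,
                 risk = risk, stages_run = stages_run),
            class = "ped_risk")
}

#' @export
print.ped_risk <- function(x, ...) {
  cat("Pediatric co-exposure risk analysis\n")
  cat(sprintf("  fine grid %d x %d, %d tracts, years %d-%d (seed %d)\n",
              x$config$scenario$grid_fine$n_rows,
              x$config$scenario$grid_fine$n_cols, nrow(x$tracts),
              min(x$config$scenario$years), max(x$config$scenario$years),
              x$config$seed))
  sh <- x$hotspots$main$shares
  cat(sprintf("  hotspot/coldspot/null shares (k=%d): %.1f%% / %.1f%% / %.1f%%\n",
              x$hotspots$k, 100 * sh["hotspot"], 100 * sh["coldspot"],
              100 * sh["null"]))
  print(x$index)
  cells <- x$risk$risk$cells
  ok <- !is.na(cells$risk_code)
  cat(sprintf("  high-risk cells: %d of %d (%.1f%%)\n",
              sum(cells$high_risk[ok]), sum(ok),
              100 * mean(cells$high_risk[ok])))
  invisible(x)
}

#' @export
summary.ped_risk <- function(object, ...) {
  x <- object
  ok <- !is.na(x$risk$risk$cells$risk_code)
  out <- list(
    shares = x$hotspots$main$shares,
    pc1_variance = x$index$results$pca$variance_explained[1],
    pc1_ci = x$index$results$pca$ci,
    chosen = x$index$selection$chosen,
    mean_trend = vapply(x$trends, function(t)
      mean(t$slope, na.rm = TRUE), numeric(1)),
    hazard_table = table(x$risk$hazard_level),
    high_risk_share = mean(x$risk$risk$cells$high_risk[ok]),
    ruca_high_risk = x$risk$ruca$high_risk_share)
  class(out) <- "summary.ped_risk"
  out
}

#' @export
print.summary.ped_risk <- function(x, ...) {
  cat("Co-exposure hotspot shares:\n"); print(round(x$shares, 3))
  cat(sprintf("\nPC1 variance explained: %.3f", x$pc1_variance))
  if (!is.null(x$pc1_ci))
    cat(sprintf(" [%.3f, %.3f]", x$pc1_ci[1], x$pc1_ci[2]))
  cat(sprintf("\nchosen latent: %s\n", x$chosen))
  cat("\nMean annual trend in anomaly days (per hazard):\n")
  print(round(x$mean_trend, 3))
  cat("\nCollapsed hazard levels (cells):\n"); print(x$hazard_table)
  cat(sprintf("\nHigh-risk cell share: %.3f\n", x$high_risk_share))
  cat("\nHigh-risk share by rural-urban class:\n")
  print(round(x$ruca_high_risk, 3))
  invisible(x)
}

#' @export
plot.ped_risk <- function(x, what = c("risk", "gi_star", "score"), ...) {
  what <- match.arg(what)
  g <- x$config$scenario$grid_fine
  m <- switch(what,
              risk = x$risk$risk$risk_raster$values,
              gi_star = matrix(x$hotspots$main$result$z, g$n_rows, g$n_cols),
              score = x$hotspots$score$values)
  graphics::image(seq_len(g$n_cols), seq_len(g$n_rows),
                  t(m[rev(seq_len(g$n_rows)), , drop = FALSE]),
                  col = grDevices::hcl.colors(
                    if (what == "risk") 9 else 25,
                    if (what == "risk") "YlOrRd" else "Blue-Red 3",
                    rev = what == "risk"),
                  xlab = "col", ylab = "row", main = paste("ped_risk:", what))
  invisible(x)
}
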