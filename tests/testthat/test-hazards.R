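# anomaly counting, annual series, trends, cumulative exposure, tertiles

one_pixel_series <- function(dates, values, variable = "pm25_ugm3") {
  g <- grid_spec(0, 0, 1000, 1, 1)
  daily_field_series(g, variable, as.Date(dates),
                     array(values, c(1, 1, length(values))))
}

test_that("exceedance is strictly greater-than and month-matched", {
  s <- one_pixel_series(c("2020-07-01", "2020-07-02", "2020-07-03",
                          "2020-07-04"), c(34.9, 35.0, 35.1, 40.0))
  cnt <- count_anomalies(s, anomaly_rule("above_fixed_threshold",
                                         threshold = 35))
  expect_identical(as.integer(cnt$counts), 2L)

  s2 <- one_pixel_series(c("2020-06-01", "2020-07-01"), c(31, 32), "tmax_F")
  nrm <- list(Jun = matrix(30, 1, 1), Jul = matrix(33, 1, 1))
  cnt2 <- count_anomalies(s2, anomaly_rule("above_monthly_normal",
                                           months = 6:8), nrm)
  expect_identical(as.integer(cnt2$counts), 1L)
})

test_that("counting matches the brute-force day loop on random series", {
  set.seed(0)
  g <- grid_spec(0, 0, 1000, 10, 10)
  dates <- seq(as.Date("2021-06-01"), as.Date("2021-08-31"), by = "day")
  vals <- array(rnorm(10 * 10 * 92, mean = 33, sd = 4), c(10, 10, 92))
  s <- daily_field_series(g, "pm25_ugm3", dates, vals)
  cnt <- count_anomalies(s, anomaly_rule("above_fixed_threshold",
                                         threshold = 35))
  expect_identical(cnt$counts,
                   oracle_count_anomalies(s, NULL, threshold = 35))

  st <- daily_field_series(g, "tmax_F", dates, vals + 55)
  nrm <- list(Jun = matrix(88, 10, 10), Jul = matrix(rnorm(100, 88), 10, 10),
              Aug = matrix(87, 10, 10))
  cntn <- count_anomalies(st, anomaly_rule("above_monthly_normal",
                                           months = 6:8), nrm)
  expect_identical(cntn$counts,
                   oracle_count_anomalies(st, 6:8, normals = nrm))
})

test_that("count_anomalies validates its inputs", {
  s <- one_pixel_series("2020-07-01", 10)
  expect_error(count_anomalies(s, anomaly_rule("above_monthly_normal")),
               "normals are required")
  expect_error(count_anomalies(s, anomaly_rule("above_fixed_threshold",
                                               threshold = 35),
                               normals = list(Jul = matrix(1, 1, 1))),
               "absent")
  expect_error(anomaly_rule("above_fixed_threshold", threshold = 0),
               "positive threshold")
  nrm_bad <- list(Jun = matrix(30, 2, 2))
  s2 <- one_pixel_series("2020-06-05", 31, "tmax_F")
  expect_error(count_anomalies(s2, anomaly_rule("above_monthly_normal"),
                               nrm_bad), "conform|mismatch")
  expect_error(count_anomalies(s2, anomaly_rule("above_monthly_normal",
                                                months = 7:8),
                               list(Jul = matrix(1, 1, 1))),
               "no days match")
})

test_that("missing days propagate by the >10% rule and flags surface", {
  g <- grid_spec(0, 0, 1000, 1, 1)
  dates <- seq(as.Date("2022-07-01"), by = "day", length.out = 20)
  v <- rep(50, 20)
  v[1:3] <- NA                               # 15% missing -> flagged
  s <- daily_field_series(g, "pm25_ugm3", dates, array(v, c(1, 1, 20)))
  cnt <- count_anomalies(s, anomaly_rule("above_fixed_threshold",
                                         threshold = 35))
  expect_true(is.na(cnt$counts[1, 1, 1]))

  v[1:3] <- NA; v2 <- v; v2[2:3] <- 60       # 5% missing -> counted
  s2 <- daily_field_series(g, "pm25_ugm3", dates, array(v2, c(1, 1, 20)))
  cnt2 <- count_anomalies(s2, anomaly_rule("above_fixed_threshold",
                                           threshold = 35))
  expect_identical(as.integer(cnt2$counts), 19L)

  af <- annual_frequency(cnt)
  expect_true(af$has_missing[1])
})

test_that("annual_frequency conserves totals", {
  sc <- tiny_scenario(6)
  cnt <- count_anomalies(generate_daily_temperature(sc),
                         anomaly_rule("above_monthly_normal", months = 6:8),
                         generate_normals(sc))
  af <- annual_frequency(cnt)
  expect_identical(dim(af$freq),
                   c(sc$grid_coarse$n_rows * sc$grid_coarse$n_cols,
                     length(cnt$years)))
  expect_equal(sum(af$freq), sum(cnt$counts))
  expect_equal(colSums(af$freq), colSums(cnt$counts, dims = 2),
               ignore_attr = TRUE)
})

test_that("pixel trends: exact lines, constants, invariances", {
  tg <- fit_pixel_trend(list(years = 2010:2013,
                             freq = matrix(c(2, 4, 6, 8), 1, 4)))
  expect_equal(as.numeric(tg$slope), 2, tolerance = 1e-12)
  expect_lt(as.numeric(tg$p_value), 1e-10)

  tg0 <- fit_pixel_trend(list(years = 2010:2015, freq = matrix(5, 1, 6)))
  expect_equal(as.numeric(tg0$slope), 0)

  set.seed(1)
  y <- matrix(rpois(50 * 13, 20), 50, 13)
  a <- fit_pixel_trend(list(years = 2012:2024, freq = y))
  b <- fit_pixel_trend(list(years = 2012:2024 + 1000, freq = y))
  expect_equal(a$slope, b$slope, tolerance = 1e-10)
  d <- fit_pixel_trend(list(years = 2012:2024, freq = 3 * y))
  expect_equal(d$slope, 3 * a$slope, tolerance = 1e-10)
})

test_that("trends handle missing pixel-years and all-missing pixels", {
  y <- rbind(c(1, 2, NA, 4, 5),
             c(NA, NA, NA, NA, NA),
             c(1, NA, NA, NA, 2))
  tr <- fit_pixel_trend(list(years = 2011:2015, freq = y))
  expect_false(is.na(tr$slope[1]))
  expect_false(is.na(tr$p_value[1]))
  expect_true(is.na(tr$slope[2]))
  expect_false(is.na(tr$slope[3]))           # slope at 2 points
  expect_true(is.na(tr$p_value[3]))          # inference needs >= 3
})

test_that("cumulative exposure sums counts and reports coverage", {
  g <- grid_spec(0, 0, 1000, 2, 2)
  counts <- array(c(3L, 1L, 0L, 2L, 5L, NA, 0L, 4L), c(2, 2, 2))
  obj <- structure(list(grid = g, years = 2012:2013, counts = counts,
                        rule = anomaly_rule("above_fixed_threshold",
                                            threshold = 35),
                        variable = "pm25_ugm3"), class = "anomaly_counts")
  ce <- cumulative_exposure(obj)
  expect_equal(ce$total$values, matrix(c(8, 1, 0, 6), 2, 2))
  expect_equal(ce$coverage$values, matrix(c(2, 1, 2, 2), 2, 2))
  set.seed(2)
  counts2 <- array(rpois(2 * 2 * 5, 3), c(2, 2, 5))
  obj$counts <- counts2; obj$years <- 2012:2016
  expect_equal(cumulative_exposure(obj)$total$values,
               apply(counts2, c(1, 2), sum))
})

test_that("tertile classification follows the interpolated-quantile contract", {
  t1 <- tertile_classify(1:9)
  expect_equal(unname(t1$breaks), c(11 / 3, 19 / 3), tolerance = 1e-12)
  expect_equal(as.vector(table(factor(t1$labels,
                                      c("Low", "Moderate", "High")))),
               c(3, 3, 3))

  t2 <- tertile_classify(c(0, 0, 0, 0, 5, 9))
  expect_equal(unname(t2$breaks), c(0, 5 / 3), tolerance = 1e-12)
  expect_equal(as.vector(table(factor(t2$labels,
                                      c("Low", "Moderate", "High")))),
               c(4, 0, 2))

  expect_warning(t3 <- tertile_classify(rep(7, 5)), "degenerate")
  expect_true(all(t3$labels == "Low"))
  expect_error(tertile_classify(c(1, 2)), "at least 3")
})

test_that("tertiles of n distinct values are balanced within one unit", {
  set.seed(3)
  for (n in c(7, 30, 100)) {
    v <- sample(seq_len(1000), n)
    tt <- tertile_classify(v)
    sizes <- table(factor(tt$labels, c("Low", "Moderate", "High")))
    expect_lte(max(abs(sizes - n / 3)), 1)
  }
})
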