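# hazard collapse, spatial join, bivariate risk classes, rural-urban summary

test_that("hazard collapse follows the >=2-high / exactly-one-high rule", {
  expect_equal(as.character(collapse_hazard("High", "High", "Low")), "high")
  expect_equal(as.character(collapse_hazard("High", "Moderate", "Low")),
               "moderate")
  expect_equal(as.character(collapse_hazard("Moderate", "Moderate",
                                            "Moderate")), "low")
  expect_error(collapse_hazard("High", "HIGH", "Low"), "invalid tertile")
})

test_that("the 27-triple enumeration partitions as 7/12/8", {
  lv <- c("Low", "Moderate", "High")
  grid27 <- expand.grid(pm = lv, bc = lv, t = lv,
                        stringsAsFactors = FALSE)
  got <- collapse_hazard(grid27$pm, grid27$bc, grid27$t)
  # independent enumeration oracle: count High labels per triple directly
  nhigh <- rowSums(grid27 == "High")
  oracle <- ifelse(nhigh >= 2, "high", ifelse(nhigh == 1, "moderate", "low"))
  expect_equal(as.character(got), oracle)
  expect_equal(as.vector(table(factor(got, c("high", "moderate", "low")))),
               c(7, 12, 8))
})

test_that("cells join to containing tracts; outsiders are flagged", {
  g <- grid_spec(0, 0, 1000, 4, 4)
  tracts <- data.frame(tract_id = c("T01", "T02"),
                       xmin = c(0, 2000), xmax = c(2000, 4000),
                       ymin = c(0, 0), ymax = c(4000, 4000))
  j <- join_cells_to_tracts(g, tracts)
  cc <- cell_centers(g)
  expect_equal(j[cc$x < 2000], rep("T01", 8))
  expect_equal(j[cc$x > 2000], rep("T02", 8))

  # outside: tracts that only cover half the grid
  half <- data.frame(tract_id = "T01", xmin = 0, xmax = 4000,
                     ymin = 2000, ymax = 4000)
  j2 <- join_cells_to_tracts(g, half)
  expect_equal(sum(is.na(j2)), 8)
  expect_error(join_cells_to_tracts(g, data.frame(tract_id = "B",
                                                  xmin = 5, xmax = 5,
                                                  ymin = 0, ymax = 1)),
               "invalid.*B")
})

test_that("joined cells satisfy the point-in-polygon oracle", {
  sc <- tiny_scenario(11, n_tracts = 16)
  tr <- generate_tracts(sc)
  j <- join_cells_to_tracts(sc$grid_fine, tr)
  cc <- cell_centers(sc$grid_fine)
  expect_false(any(is.na(j)))                 # tessellation covers the grid
  set.seed(0)
  for (i in sample(length(j), 60)) {
    t <- match(j[i], tr$tract_id)
    ring_x <- c(tr$xmin[t], tr$xmax[t], tr$xmax[t], tr$xmin[t])
    ring_y <- c(tr$ymin[t], tr$ymin[t], tr$ymax[t], tr$ymax[t])
    expect_true(oracle_point_in_poly(cc$x[i], cc$y[i], ring_x, ring_y))
  }
})

test_that("boundary centroids go to the lowest tract id", {
  g <- grid_spec(0, 500, 1000, 2, 1)          # centroids at y = 1000
  tracts <- data.frame(tract_id = c("T9", "T1"),
                       xmin = c(0, 0), xmax = c(2000, 2000),
                       ymin = c(1000, 0), ymax = c(2000, 1000))
  j <- join_cells_to_tracts(g, tracts)        # touches both: T1 < T9 wins
  expect_equal(j, c("T1", "T1"))
})

test_that("risk classes cross hazard and vulnerability with conservation", {
  hz <- factor(c("high", "high", "low", "moderate", NA, "high"),
               levels = c("low", "moderate", "high"))
  ct <- c("A", "B", "A", "B", "A", NA)
  vt <- tertile_classify(c(A = 9, B = 5, C = 1))
  rm <- classify_risk(hz, ct, vt, c("A", "B", "C"))
  cells <- rm$cells
  expect_true(cells$high_risk[1])             # (high, High)
  expect_false(cells$high_risk[4])
  expect_equal(cells$risk_code[3], 13L)       # low hazard, High vulnerability
  expect_equal(rm$n_unassigned, 2)            # NA hazard + NA tract
  expect_equal(sum(!is.na(cells$risk_code)) + rm$n_unassigned, 6)
  expect_true(all(stats::na.omit(cells$risk_code) %in%
                    as.vector(outer(1:3 * 10, 1:3, `+`))))
})

test_that("high_risk is monotone under single-hazard upgrades", {
  lv <- c("Low", "Moderate", "High")
  combos <- expand.grid(pm = lv, bc = lv, t = lv, stringsAsFactors = FALSE)
  hz <- collapse_hazard(combos$pm, combos$bc, combos$t)
  rank3 <- function(x) match(x, c("low", "moderate", "high"))
  for (i in seq_len(27)) {
    for (var in 1:3) {
      cur <- combos[i, ]
      pos <- match(cur[[var]], lv)
      if (pos == 3) next
      up <- cur
      up[[var]] <- lv[pos + 1]
      hz_up <- collapse_hazard(up$pm, up$bc, up$t)
      expect_gte(rank3(as.character(hz_up)), rank3(as.character(hz[i])))
    }
  }
})

test_that("tract summaries are order-invariant and share-correct", {
  set.seed(12)
  n <- 60
  hz <- factor(sample(c("low", "moderate", "high"), n, replace = TRUE),
               levels = c("low", "moderate", "high"))
  ct <- sample(c("A", "B", "C"), n, replace = TRUE)
  vt <- tertile_classify(c(A = 9, B = 5, C = 1))
  rm1 <- classify_risk(hz, ct, vt, c("A", "B", "C"))
  perm <- sample(n)
  rm2 <- classify_risk(hz[perm], ct[perm], vt, c("A", "B", "C"))
  s1 <- rm1$tract_summary[order(rm1$tract_summary$tract_id), ]
  s2 <- rm2$tract_summary[order(rm2$tract_summary$tract_id), ]
  expect_equal(s1$high_risk_share, s2$high_risk_share)
  expect_equal(s1$high_risk_share[s1$tract_id == "A"],
               mean(hz[ct == "A"] == "high"))
})

test_that("ruca summaries aggregate codes and conserve counts", {
  hz <- factor(rep(c("high", "low"), 10), levels = c("low", "moderate",
                                                     "high"))
  ct <- rep(c("A", "B"), each = 10)
  vt <- tertile_classify(c(A = 9, B = 5, C = 1))
  rm <- classify_risk(hz, ct, vt, c("A", "B", "C"))
  tr1 <- data.frame(tract_id = c("A", "B", "C"), ruca_code = c(1L, 1L, 1L))
  ru <- summarize_by_ruca(rm, tr1)
  expect_equal(sum(ru$counts["metropolitan", ]), 20)
  expect_equal(sum(ru$counts), sum(!is.na(rm$cells$risk_code)))

  tr2 <- data.frame(tract_id = c("A", "B", "C"),
                    ruca_code = c(2L, 10L, NA))
  ru2 <- summarize_by_ruca(rm, tr2)
  expect_equal(sum(ru2$counts["metropolitan", ]), 10)
  expect_equal(sum(ru2$counts["rural", ]), 10)
  expect_error(summarize_by_ruca(rm, data.frame(tract_id = "A",
                                                ruca_code = 11L)),
               "out of range.*A")
})

test_that("an urban-core scenario concentrates high risk in metro tracts", {
  sc <- risk_scenario(seed = 0, years = 2012:2016, n_tracts = 100,
                      grid_coarse = grid_spec(0, 0, 4000, 10, 10),
                      grid_fine = grid_spec(0, 0, 1000, 40, 40),
                      hot_region = list(xmin = 12000, xmax = 28000,
                                        ymin = 12000, ymax = 28000,
                                        offset = 4))
  tr <- generate_tracts(sc)
  nrm <- generate_normals(sc)
  cnt_t <- count_anomalies(generate_daily_temperature(sc),
                           anomaly_rule("above_monthly_normal", months = 6:8),
                           nrm)
  pol <- generate_daily_pollutants(sc)
  cnt_p <- count_anomalies(pol$pm25, anomaly_rule("above_fixed_threshold",
                                                  threshold = 35))
  cnt_b <- count_anomalies(pol$bc, anomaly_rule("above_fixed_threshold",
                                                threshold = 1))
  fine <- sc$grid_fine
  cum <- lapply(list(temp = cnt_t, pm25 = cnt_p, bc = cnt_b),
                function(cn) resample_grid(cumulative_exposure(cn)$total,
                                           target = fine))
  tert <- lapply(cum, tertile_classify)
  hz <- collapse_hazard(as.vector(tert$pm25$labels),
                        as.vector(tert$bc$labels),
                        as.vector(tert$temp$labels))
  j <- join_cells_to_tracts(fine, tr)
  fit <- vuln_index(tr, methods = "pca")
  vt <- tertile_classify(fit$scores)
  rmres <- classify_risk(hz, j, vt, tr$tract_id, grid = fine)
  ru <- summarize_by_ruca(rmres, tr)
  expect_gt(ru$high_risk_share[["metropolitan"]],
            ru$high_risk_share[["rural"]])
})
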