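# KNN weights and the Getis-Ord Gi* statistic

test_that("knn neighbours follow forced geometry and the k = n-1 limit", {
  g <- grid_spec(0, 0, 1, 3, 3)
  cc <- cell_centers(g)
  kw <- build_knn(cc[, c("x", "y")], 2)
  # unit 1 is the NW corner cell; its two edge-adjacent cells win over the
  # diagonal (distance 1 beats sqrt(2))
  corner <- which(cc$row == 1 & cc$col == 1)
  adj <- which((cc$row == 2 & cc$col == 1) | (cc$row == 1 & cc$col == 2))
  expect_setequal(kw$neighbor_index[corner, ], adj)

  kw8 <- build_knn(cc[, c("x", "y")], 8)
  for (i in 1:9)
    expect_setequal(kw8$neighbor_index[i, ], setdiff(1:9, i))

  expect_error(build_knn(cc[, c("x", "y")], 9), "k must satisfy")
  expect_error(build_knn(rbind(c(0, 0), c(1, 1), c(0, 0)), 1),
               "duplicate coordinates")
})

test_that("knn matches the exhaustive distance-sort oracle", {
  set.seed(0)
  pts <- cbind(runif(200), runif(200))
  kw <- build_knn(pts, 20)
  D <- as.matrix(dist(pts))
  diag(D) <- Inf
  for (i in 1:200)
    expect_setequal(kw$neighbor_index[i, ], order(D[i, ])[1:20])
})

test_that("gi_star matches the dense double-loop oracle", {
  g <- grid_spec(0, 0, 1000, 20, 20)
  cc <- cell_centers(g)
  set.seed(0)
  x <- rnorm(400)
  kw <- build_knn(cc[, c("x", "y")], 20)
  z <- gi_star(x, kw)$z
  expect_lt(max(abs(z - oracle_gi_star(x, kw$neighbor_index))), 1e-10)
})

test_that("gi_star rejects constants and flags full neighbourhoods", {
  g <- grid_spec(0, 0, 1, 3, 3)
  cc <- cell_centers(g)
  kw <- build_knn(cc[, c("x", "y")], 8)
  expect_error(gi_star(rep(4, 9), kw), "zero-variance")
  r <- gi_star(c(1:8, 20), kw)
  expect_true(all(r$undefined))
  expect_true(all(is.na(r$z)))
})

test_that("gi_star is location- and positive-scale-invariant", {
  set.seed(2)
  pts <- cbind(runif(150), runif(150))
  x <- rnorm(150)
  kw <- build_knn(pts, 12)
  z0 <- gi_star(x, kw)$z
  expect_lt(max(abs(gi_star(x + 100, kw)$z - z0)), 1e-10)
  expect_lt(max(abs(gi_star(x * 7.5, kw)$z - z0)), 1e-10)
  expect_error(gi_star(c(x[-1], NA), kw), "missing")
})

test_that("numerators sum to zero under symmetric weights", {
  # points on a ring with k = 2: each unit's neighbours are its two ring
  # neighbours, a symmetric weight structure
  n <- 24
  th <- 2 * pi * (seq_len(n) - 1) / n
  pts <- cbind(cos(th), sin(th))
  kw <- build_knn(pts, 2)
  set.seed(3)
  x <- rnorm(n)
  xbar <- mean(x)
  num <- rowSums(matrix(x[kw$neighbor_index], n, 2)) + x - xbar * 3
  expect_lt(abs(sum(num)), 1e-10)
})

test_that("spot classification uses the two-sided normal threshold", {
  fake <- structure(list(z = c(2.5, -2.5, 0, 1.95, 1.97),
                         p_two_sided = 2 * pnorm(-abs(c(2.5, -2.5, 0, 1.95,
                                                        1.97))),
                         undefined = rep(FALSE, 5), k = 5, alpha = 0.05,
                         n = 5),
                    class = "gi_star_result")
  cs <- classify_spots(fake)
  expect_equal(as.character(cs$class),
               c("hotspot", "coldspot", "null", "null", "hotspot"))
  expect_equal(sum(cs$shares), 1)
})

test_that("a planted high blob is recovered as a hotspot with stable area", {
  for (s in 0:4) {
    set.seed(s)
    g <- grid_spec(0, 0, 1000, 60, 60)
    m <- matrix(rnorm(3600), 60, 60)
    blob <- matrix(FALSE, 60, 60)
    blob[25:36, 25:36] <- TRUE                 # 4% of the area, +5 sigma
    m[blob] <- m[blob] + 5
    cc <- cell_centers(g)
    kw <- build_knn(cc[, c("x", "y")], 20)
    r <- gi_star(as.vector(m), kw)
    cls <- classify_spots(r)$class
    hot <- cls == "hotspot"
    expect_true(all(hot[as.vector(blob)]))
    # far field mostly null
    far <- as.vector(row(m) < 15 | row(m) > 46 | col(m) < 15 | col(m) > 46)
    expect_gt(mean(cls[far] == "null"), 0.8)
    # hot share within 0.20 (absolute) of the planted area share
    expect_lt(abs(mean(hot) - mean(blob)), 0.20)
  }
})

test_that("co-exposure scores combine standardized layers", {
  g <- grid_spec(0, 0, 1000, 10, 10)
  set.seed(6)
  a <- matrix(rnorm(100), 10, 10)
  az <- (a - mean(a)) / sd(a)
  la <- raster_layer(az, g, "a")
  sc <- coexposure_score(list(t1 = la, t2 = la, t3 = la))
  expect_equal(sc$values, az, tolerance = 1e-12)

  sc1 <- coexposure_score(list(x = la, y = raster_layer(matrix(rnorm(100),
                                                               10, 10),
                                                        g, "y")),
                          combine = "single_variable", which = "x")
  expect_identical(sc1$values, az)

  expect_error(coexposure_score(list(la, raster_layer(matrix(1, 10, 10), g,
                                                      "const"))),
               "constant")
  g2 <- grid_spec(0, 0, 500, 10, 10)
  expect_error(coexposure_score(list(la, raster_layer(az, g2, "b"))),
               "mismatch")

  # variance of the mean of three independent unit-variance fields ~ 1/3
  set.seed(7)
  layers <- lapply(1:3, function(i) {
    v <- matrix(rnorm(10000), 100, 100)
    raster_layer(v, grid_spec(0, 0, 1000, 100, 100), paste0("l", i))
  })
  v <- var(as.vector(coexposure_score(layers)$values))
  expect_lt(abs(v - 1 / 3), 0.05)
})

test_that("knn_subset truncates to the nearest neighbours", {
  set.seed(8)
  pts <- cbind(runif(80), runif(80))
  k25 <- build_knn(pts, 25)
  k10 <- build_knn(pts, 10)
  expect_identical(knn_subset(k25, 10)$neighbor_index, k10$neighbor_index)
})
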