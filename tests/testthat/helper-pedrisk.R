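# shared fixtures: small scenarios and independent brute-force oracles

tiny_scenario <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    seed = seed,
    grid_coarse = grid_spec(0, 0, 4000, 5, 5),
    grid_fine = grid_spec(0, 0, 1000, 20, 20),
    years = 2012:2014,
    n_tracts = 16), list(...))
  do.call(risk_scenario, args)
}

# independent day-loop oracle for anomaly counting: literal per-pixel,
# per-day scan with explicit comparators
oracle_count_anomalies <- function(series, months, threshold = NULL,
                                   normals = NULL) {
  lt <- as.POSIXlt(series$dates)
  mon <- lt$mon + 1L
  yr <- lt$year + 1900L
  keep <- if (is.null(months)) rep(TRUE, length(mon)) else mon %in% months
  years <- sort(unique(yr[keep]))
  g <- series$grid
  out <- array(0L, c(g$n_rows, g$n_cols, length(years)))
  mn <- c("6" = "Jun", "7" = "Jul", "8" = "Aug")
  for (r in seq_len(g$n_rows)) for (cl in seq_len(g$n_cols)) {
    for (d in which(keep)) {
      cmp <- if (!is.null(threshold)) threshold else
        normals[[mn[[as.character(mon[d])]]]][r, cl]
      v <- series$values[r, cl, d]
      if (!is.na(v) && v > cmp) {
        iy <- match(yr[d], years)
        out[r, cl, iy] <- out[r, cl, iy] + 1L
      }
    }
  }
  out
}

# dense double-loop implementation of the Gi* standard deviate
oracle_gi_star <- function(x, neighbor_index) {
  n <- length(x)
  k <- ncol(neighbor_index)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    w <- numeric(n)
    w[i] <- 1
    w[neighbor_index[i, ]] <- 1
    Wi <- sum(w)
    S1 <- sum(w^2)
    z[i] <- (sum(w * x) - xbar * Wi) / (s * sqrt((n * S1 - Wi^2) / (n - 1)))
  }
  z
}

# ray-casting point-in-polygon oracle (closed ring; boundary counts inside)
oracle_point_in_poly <- function(px, py, ring_x, ring_y) {
  n <- length(ring_x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring_x[i]; yi <- ring_y[i]; xj <- ring_x[j]; yj <- ring_y[j]
    if ((px - xi) * (yj - yi) == (py - yi) * (xj - xi) &&
        px >= min(xi, xj) && px <= max(xi, xj) &&
        py >= min(yi, yj) && py <= max(yi, yj)) return(TRUE)
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# wrap a raw score vector as a minimal latent_index for selection tests
latent_index_result_for_test <- function(scores, method) {
  sc <- matrix(as.numeric(scores), ncol = 1, dimnames = list(NULL, "L1"))
  structure(list(method = method, scores = sc, loadings = NULL,
                 variance_explained = NULL, ci = NULL, fit_metric = NULL),
            class = "latent_index")
}

# one-factor percentage table with known loading, in the generator's scale
make_factor_table <- function(n, loading, seed, two_factor = FALSE) {
  set.seed(seed)
  if (two_factor) {
    f <- cbind(rnorm(n), rnorm(n))
    L <- cbind(c(rep(loading, 6), rep(0, 6)), c(rep(0, 6), rep(loading, 6)))
    noise <- sweep(matrix(rnorm(n * 12), n, 12), 2,
                   sqrt(1 - rowSums(L^2)), "*")
    z <- f %*% t(L) + noise
  } else {
    f <- rnorm(n)
    z <- loading * f %*% t(rep(1, 12)) +
      matrix(rnorm(n * 12), n, 12) * sqrt(1 - loading^2)
  }
  x <- 10^(1 + 0.25 * z) - 1
  x[x < 0] <- 0
  x[x > 100] <- 100
  colnames(x) <- pedrisk:::VULN_VARS
  x
}
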