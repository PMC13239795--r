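# vulnerability index: preprocessing, PCA, EFA, bootstrap, adapters, selection

test_that("preprocessing applies log10(x+1) then exact standardization", {
  set.seed(1)
  x <- matrix(runif(50 * 12) * 100, 50, 12)
  colnames(x) <- pedrisk:::VULN_VARS
  x[1, 1] <- 0
  x[2, 2] <- 99
  m <- preprocess_vulnerability(x)
  y <- log10(x + 1)
  expect_equal(unname(y[1, 1]), 0)
  expect_equal(unname(y[2, 2]), 2)
  expect_equal(m$transformed,
               scale(y, center = m$center, scale = m$scale),
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(m$transformed))), 1e-12)
  expect_lt(max(abs(apply(m$transformed, 2, sd) - 1)), 1e-12)
  # monotone transform: perfect rank correlation with the raw columns
  for (j in 1:12)
    expect_equal(cor(m$transformed[, j], x[, j], method = "spearman"), 1)

  xb <- x; xb[3, 4] <- 101
  expect_error(preprocess_vulnerability(xb), "0, 100")
  xc <- x; xc[, 5] <- 40
  expect_error(preprocess_vulnerability(xc), "zero-variance.*insurance")
})

test_that("PCA scores are the projection and variance fractions sum to one", {
  x <- make_factor_table(300, 0.6, seed = 2)
  m <- preprocess_vulnerability(x)
  fit <- pca_index(m, 12)
  expect_equal(sum(fit$eigenvalues) / 12, 1, tolerance = 1e-10)
  expect_equal(sum(fit$variance_explained), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$scores - m$transformed %*% fit$loadings)), 1e-10)
  expect_gte(fit$loadings["pct_households_poverty", 1], 0)
  # loadings are unit-norm
  expect_equal(colSums(fit$loadings^2), rep(1, 12), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PC1 concentrates on a correlated pair amid independent noise", {
  set.seed(3)
  n <- 400
  base <- rnorm(n)
  x <- cbind(50 + 10 * base, 50 + 10 * base + rnorm(n, sd = 0.5),
             matrix(runif(n * 10) * 100, n, 10))
  x[x < 0] <- 0; x[x > 100] <- 100
  colnames(x) <- pedrisk:::VULN_VARS
  fit <- pca_index(preprocess_vulnerability(x), 2)
  mag <- abs(fit$loadings[, 1])
  expect_setequal(names(sort(mag, decreasing = TRUE))[1:2],
                  pedrisk:::VULN_VARS[1:2])
})

test_that("EFA recovers a single factor with loadings 0.7 and high MSA", {
  for (s in 0:4) {
    x <- make_factor_table(1000, 0.7, seed = s)
    e <- efa_index(preprocess_vulnerability(x), 1)
    expect_lt(max(abs(e$loadings - 0.7)), 0.05)
    expect_gt(min(e$msa), 0.6)
    expect_true(e$adequate)
  }
})

test_that("oblimin leaves orthogonal factors nearly uncorrelated", {
  x <- make_factor_table(1000, 0.7, seed = 5, two_factor = TRUE)
  e <- efa_index(preprocess_vulnerability(x), 2)
  expect_lt(abs(e$Phi[1, 2]), 0.1)
  # each block loads on its own factor
  L <- abs(e$loadings)
  expect_gt(min(pmax(L[1:6, 1], L[1:6, 2])), 0.5)
})

test_that("independent columns yield near-zero communality and low MSA", {
  set.seed(6)
  x <- matrix(runif(1000 * 12) * 100, 1000, 12)
  colnames(x) <- pedrisk:::VULN_VARS
  e <- efa_index(preprocess_vulnerability(x), 1)
  expect_lt(mean(1 - e$uniquenesses), 0.1)
  expect_lt(min(e$msa), 0.6)
  expect_false(e$adequate)
})

test_that("bootstrap CI contains its point estimate and narrows with n", {
  x <- make_factor_table(200, 0.5, seed = 7)
  ci <- bootstrap_variance_ci(x, "PCA", B = 200, seed = 1)
  expect_gte(ci$point, ci$ci["lower"])
  expect_lte(ci$point, ci$ci["upper"])
  expect_error(bootstrap_variance_ci(x, "PCA", B = 50), "at least 100")

  widths <- sapply(1:5, function(s) {
    small <- bootstrap_variance_ci(make_factor_table(100, 0.5, seed = s),
                                   "PCA", B = 200, seed = s)
    large <- bootstrap_variance_ci(make_factor_table(1600, 0.5, seed = s),
                                   "PCA", B = 200, seed = s)
    c(diff(small$ci), diff(large$ci))
  })
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
})

test_that("disabled backends degrade to a not-run record", {
  x <- make_factor_table(100, 0.5, seed = 8)
  m <- preprocess_vulnerability(x)
  withr::local_options(pedrisk.disable_backends = c("tsne", "umap"))
  r <- embed_adapter(m, "tsne")
  expect_s3_class(r, "latent_not_run")
  fit <- vuln_index(x, methods = c("pca", "tsne"))
  expect_true("TSNE" %in% fit$selection$not_run)
  expect_equal(fit$selection$chosen_method, "PCA")
})

test_that("the native autoencoder reconstructs rank-1 data and is seeded", {
  sc <- risk_scenario(seed = 1, n_tracts = 100, vuln_noise_sd = 0,
                      factor_spatial_weight = 0,
                      grid_fine = grid_spec(0, 0, 1000, 20, 20),
                      grid_coarse = grid_spec(0, 0, 4000, 5, 5))
  m <- preprocess_vulnerability(generate_tracts(sc))
  a1 <- embed_adapter(m, "ae", seed = 0)
  expect_lt(a1$fit_metric[["reconstruction_mse"]], 0.01)
  expect_equal(ncol(a1$scores), 2)
  a2 <- embed_adapter(m, "ae", seed = 0)
  expect_identical(a1$scores, a2$scores)
})

test_that("selection prefers consistent correlation over a single-variable latent", {
  set.seed(9)
  n <- 500
  f <- rnorm(n)
  x <- make_factor_table(n, 0.55, seed = 9)
  m <- preprocess_vulnerability(x)
  # latent A: monotone transform of variable 1 only; latent B: the common factor
  latA <- latent_index_result_for_test(exp(m$transformed[, 1]), "A")
  latB <- latent_index_result_for_test(m$transformed %*% rep(1, 12), "B")
  sel <- select_latent(list(latA, latB), x)
  expect_equal(sel$chosen_method, "B")
  expect_lt(sel$criterion["A_L1"], sel$criterion["B_L1"])

  # sign invariance of the criterion
  latBneg <- latent_index_result_for_test(-(m$transformed %*% rep(1, 12)), "B")
  sel2 <- select_latent(list(latA, latBneg), x)
  expect_equal(unname(sel2$criterion["B_L1"]), unname(sel$criterion["B_L1"]),
               tolerance = 1e-12)
  # monotone-transform invariance (Spearman property)
  latBcube <- latent_index_result_for_test((m$transformed %*% rep(1, 12))^3,
                                           "B")
  sel3 <- select_latent(list(latA, latBcube), x)
  expect_equal(unname(sel3$criterion["B_L1"]), unname(sel$criterion["B_L1"]),
               tolerance = 1e-12)

  # zero-variance latent excluded
  latZ <- latent_index_result_for_test(rep(1, n), "Z")
  sel4 <- select_latent(list(latZ, latB), x)
  expect_true(is.na(sel4$criterion["Z_L1"]))
  expect_equal(sel4$chosen_method, "B")
})

test_that("vuln_index wraps fit, selection and prediction coherently", {
  sc <- risk_scenario(seed = 4, n_tracts = 100,
                      grid_fine = grid_spec(0, 0, 1000, 20, 20),
                      grid_coarse = grid_spec(0, 0, 4000, 5, 5))
  tr <- generate_tracts(sc)
  fit <- vuln_index(tr, methods = c("pca", "efa"), bootstrap_B = 100,
                    seed = 2)
  expect_s3_class(fit, "vuln_index")
  expect_length(fit$scores, 100)
  expect_equal(dim(coef(fit, "pca")), c(12, 2))
  expect_equal(predict(fit), fit$scores)
  pr <- predict(fit, newdata = tr)
  if (fit$selection$chosen_method == "PCA")
    expect_equal(pr, unname(fit$scores), tolerance = 1e-10)
  expect_output(print(fit), "vulnerability index")
  expect_output(print(summary(fit)), "Selection criterion")
  ci <- fit$results$pca$ci
  expect_true(ci[1] <= fit$results$pca$variance_explained[1] &&
                fit$results$pca$variance_explained[1] <= ci[2])
})
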