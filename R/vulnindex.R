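# Pediatric vulnerability index construction: preprocessing of the
# 12-variable percentage table, PCA and exploratory factor analysis
# (minimum-residual extraction, oblimin rotation by gradient projection,
# Kaiser-Meyer-Olkin sampling adequacy), bootstrap confidence intervals for
# explained variance, pluggable embedding adapters, and Spearman-based
# selection of the final latent variable.

#' Preprocess the vulnerability percentage table
#'
#' Applies `log10(x + 1)` per cell (percentages in `[0, 100]` map to
#' `[0, ~2]`; the offset keeps zero percentages defined) and then centers and
#' unit-scales each column. The transform is monotone, so rank-based
#' statistics are unchanged.
#'
#' @param raw data.frame or matrix with the 12 vulnerability variable
#'   columns, values in `[0, 100]`. Non-variable columns of a `tract_table`
#'   are ignored.
#' @return A `vuln_matrix`: `raw` (the variable columns), `transformed`
#'   (standardized log-scale matrix), `center`, `scale`.
#' @export
preprocess_vulnerability <- function(raw) {
  x <- extract_vuln_columns(raw)
  if (nrow(x) < 3L) stop("at least 3 rows are required")
  if (ncol(x) != 12L) stop("expected 12 vulnerability variable columns")
  if (any(is.na(x))) stop("missing values are not supported")
  if (any(x < 0 | x > 100)) stop("values must lie in [0, 100]")
  y <- log10(x + 1)
  ctr <- colMeans(y)
  scl <- apply(y, 2, stats::sd)
  if (any(scl == 0)) {
    bad <- colnames(x)[scl == 0]
    stop("zero-variance column(s) after transform: ",
         paste(bad, collapse = ", "))
  }
  z <- sweep(sweep(y, 2, ctr), 2, scl, "/")
  structure(list(raw = x, transformed = z, center = ctr, scale = scl),
            class = "vuln_matrix")
}

extract_vuln_columns <- function(raw) {
  if (is.matrix(raw)) return(raw)
  if (all(VULN_VARS %in% names(raw))) return(as.matrix(raw[, VULN_VARS]))
  num <- vapply(raw, is.numeric, TRUE)
  drop <- names(raw) %in% c("xmin", "xmax", "ymin", "ymax", "centroid_x",
                            "centroid_y", "ruca_code")
  as.matrix(raw[, num & !drop, drop = FALSE])
}

#' @export
print.vuln_matrix <- function(x, ...) {
  cat(sprintf("vuln_matrix: %d tracts x %d variables (log10(x+1), standardized)\n",
              nrow(x$transformed), ncol(x$transformed)))
  invisible(x)
}

latent_index_result <- function(method, scores, loadings = NULL,
                                variance_explained = NULL, ci = NULL,
                                fit_metric = NULL, extra = list()) {
  structure(c(list(method = method, scores = scores, loadings = loadings,
                   variance_explained = variance_explained, ci = ci,
                   fit_metric = fit_metric), extra),
            class = "latent_index")
}

#' @export
print.latent_index <- function(x, ...) {
  cat(sprintf("latent_index [%s]: %d tracts, %d latent(s)\n", x$method,
              nrow(x$scores), ncol(x$scores)))
  if (!is.null(x$variance_explained)) {
    cat(sprintf("  variance explained (1st): %.3f", x$variance_explained[1]))
    if (!is.null(x$ci))
      cat(sprintf(" [%.3f, %.3f]", x$ci[1], x$ci[2]))
    cat("\n")
  }
  if (!is.null(x$fit_metric))
    cat(sprintf("  fit metric (%s): %.4g\n", names(x$fit_metric)[1],
                x$fit_metric[[1]]))
  invisible(x)
}

# orient component/factor signs so "households in poverty" loads >= 0
orient_signs <- function(loadings, scores) {
  anchor <- if ("pct_households_poverty" %in% rownames(loadings))
    "pct_households_poverty" else rownames(loadings)[1]
  for (cpt in seq_len(ncol(loadings))) {
    if (loadings[anchor, cpt] < 0) {
      loadings[, cpt] <- -loadings[, cpt]
      scores[, cpt] <- -scores[, cpt]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component index
#'
#' Eigendecomposition of the column covariance of the standardized matrix
#' (equivalently, the correlation matrix of the log-scale table). The
#' variance explained by component c is its eigenvalue divided by the number
#' of variables; loadings are unit-norm eigenvectors, with component signs
#' oriented so the loading on households-in-poverty is non-negative.
#'
#' @param m a `vuln_matrix` from [preprocess_vulnerability()].
#' @param n_components components to retain (default 2; `12` gives the full
#'   decomposition).
#' @return A `latent_index` with `scores`, `loadings`,
#'   `variance_explained` (per retained component), `eigenvalues` (all),
#'   and the achieved `rank`.
#' @export
pca_index <- function(m, n_components = 2L) {
  stopifnot(inherits(m, "vuln_matrix"))
  z <- m$transformed
  p <- ncol(z)
  if (nrow(z) < p)
    warning("fewer rows than variables; covariance is rank-deficient")
  S <- stats::cov(z)
  e <- eigen(S, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-10)
  nc <- min(n_components, p)
  L <- e$vectors[, seq_len(nc), drop = FALSE]
  rownames(L) <- colnames(z)
  colnames(L) <- paste0("PC", seq_len(nc))
  sc <- z %*% L
  o <- orient_signs(L, sc)
  latent_index_result("PCA", o$scores, o$loadings,
                      variance_explained = e$values[seq_len(nc)] / p,
                      extra = list(eigenvalues = e$values, rank = rank))
}

# ---- exploratory factor analysis: minres + oblimin + KMO ------------------

# minimum-residual extraction: optimize uniquenesses so the rank-k
# approximation reproduces the off-diagonal correlations
efa_minres_extract <- function(R, k, max_iter = 1000L) {
  p <- ncol(R)
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  lam_of <- function(psi) {
    S <- R; diag(S) <- 1 - psi
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  }
  obj <- function(psi) {
    S <- R; diag(S) <- 1 - psi
    E <- S - tcrossprod(lam_of(psi))
    (sum(E^2) - sum(diag(E)^2)) / 2
  }
  opt <- stats::optim(start, obj, method = "L-BFGS-B", lower = 0.001,
                      upper = 1, control = list(maxit = max_iter))
  lam <- lam_of(opt$par)
  rownames(lam) <- colnames(R)
  heywood <- rowSums(lam^2) > 1
  if (any(heywood)) {
    lam[heywood, ] <- lam[heywood, ] / sqrt(rowSums(lam[heywood, ,
                                                        drop = FALSE]^2))
  }
  list(loadings = lam, uniquenesses = opt$par, residual_norm = opt$value,
       converged = opt$convergence == 0, heywood = heywood)
}

# quartimin (oblimin, gamma = 0) criterion and gradient for GP rotation
quartimin_crit <- function(L) {
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  L2 <- L^2
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, G = L * X)
}

# oblique gradient-projection rotation (Jennrich's algorithm)
rotate_oblimin <- function(A, max_iter = 500L, tol = 1e-6) {
  k <- ncol(A)
  if (k < 2L)
    return(list(loadings = A, Phi = diag(k), converged = TRUE, iter = 0L))
  Tm <- diag(k)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- quartimin_crit(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% Ti)
  for (it in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G))
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in 1:20) {
      X <- Tm - al * Gp
      v <- 1 / sqrt(colSums(X^2))
      Tt <- X %*% diag(v)
      Tti <- solve(Tt)
      Lt <- A %*% t(Tti)
      vgt <- quartimin_crit(Lt)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt; Ti <- Tti; L <- Lt; f <- vgt$f
    G <- -t(t(L) %*% vgt$G %*% Ti)
  }
  Phi <- t(Tm) %*% Tm
  list(loadings = L, Phi = Phi, converged = it < max_iter, iter = it)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Per-variable MSA from correlations r and partial correlations q (image
#' analysis): `MSA_j = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal
#' entries. Values near 1 indicate a variable set that suits factor
#' analysis; values near 0.5 indicate no shared structure.
#'
#' @param R correlation matrix.
#' @return List with per-variable `msa`, `msa_min` and overall `msa_total`.
#' @export
kmo_msa <- function(R) {
  iv <- solve(R)
  q <- -iv / sqrt(outer(diag(iv), diag(iv)))
  diag(q) <- 0
  r <- R; diag(r) <- 0
  msa <- colSums(r^2) / (colSums(r^2) + colSums(q^2))
  names(msa) <- colnames(R)
  list(msa = msa, msa_min = min(msa),
       msa_total = sum(r^2) / (sum(r^2) + sum(q^2)))
}

#' Exploratory factor analysis index
#'
#' Minimum-residual factor extraction on the correlation matrix, oblimin
#' (gamma = 0) rotation by gradient projection, and regression-method factor
#' scores. The variance explained by a factor is the sum of its squared
#' structure loadings divided by the number of variables; sampling adequacy
#' is the per-variable Kaiser-Meyer-Olkin MSA with the minimum reported as
#' the fit metric. Heywood cases (communality > 1) are clipped and flagged.
#'
#' @param m a `vuln_matrix`.
#' @param n_factors factors to extract (default 2).
#' @return A `latent_index` with pattern `loadings`, `structure` loadings,
#'   factor correlation `Phi`, `scores`, `variance_explained`,
#'   `fit_metric = c(msa_min = )`, `msa` per variable, and convergence info.
#' @export
efa_index <- function(m, n_factors = 2L) {
  stopifnot(inherits(m, "vuln_matrix"))
  z <- m$transformed
  R <- stats::cor(z)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation matrix is not positive definite")
  ext <- efa_minres_extract(R, n_factors)
  if (!ext$converged)
    warning(sprintf("minres extraction did not converge (residual %.3g)",
                    ext$residual_norm))
  rot <- rotate_oblimin(ext$loadings)
  L <- rot$loadings
  Phi <- rot$Phi
  Str <- L %*% Phi                               # structure loadings
  rownames(L) <- rownames(Str) <- colnames(z)
  colnames(L) <- colnames(Str) <- paste0("F", seq_len(ncol(L)))
  # order factors by explained variance, descending
  vexp <- colSums(Str^2) / ncol(z)
  ord <- order(vexp, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]; Str <- Str[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]; vexp <- vexp[ord]
  colnames(L) <- colnames(Str) <- paste0("F", seq_len(ncol(L)))
  scores <- z %*% solve(R) %*% Str               # regression method
  colnames(scores) <- colnames(L)
  anchor <- if ("pct_households_poverty" %in% rownames(L))
    "pct_households_poverty" else rownames(L)[1]
  sgn <- ifelse(L[anchor, ] < 0, -1, 1)
  L <- sweep(L, 2, sgn, "*"); Str <- sweep(Str, 2, sgn, "*")
  scores <- sweep(scores, 2, sgn, "*")
  Phi <- diag(sgn, length(sgn)) %*% Phi %*% diag(sgn, length(sgn))
  kmo <- kmo_msa(R)
  latent_index_result("EFA", scores, L,
                      variance_explained = vexp,
                      fit_metric = c(msa_min = kmo$msa_min),
                      extra = list(structure = Str, Phi = Phi,
                                   msa = kmo$msa,
                                   uniquenesses = ext$uniquenesses,
                                   heywood = ext$heywood,
                                   converged = ext$converged,
                                   adequate = kmo$msa_min >= 0.5))
}

#' Bootstrap confidence interval for explained variance
#'
#' Resamples table rows with replacement, reruns preprocessing and the
#' chosen index method, and takes the percentile interval of the variance
#' explained by the first component/factor. Replicates in which a column
#' becomes constant (so the preprocessing rejects it) are dropped and
#' counted.
#'
#' @param raw the raw percentage table.
#' @param method `"PCA"` or `"EFA"`.
#' @param B bootstrap replicates (default 5000).
#' @param level confidence level.
#' @param seed integer seed for the resampling.
#' @return List with `point`, `ci` (named lower/upper), `level`, `B`,
#'   `n_dropped`, and the replicate values `boot`.
#' @export
bootstrap_variance_ci <- function(raw, method = c("PCA", "EFA"), B = 5000L,
                                  level = 0.95, seed = 1L) {
  method <- match.arg(method)
  if (B < 100L) stop("B must be at least 100")
  x <- extract_vuln_columns(raw)
  n <- nrow(x)
  fit1 <- function(xx) {
    m <- preprocess_vulnerability(xx)
    if (method == "PCA") pca_index(m, 1L)$variance_explained[1]
    else efa_index(m, 1L)$variance_explained[1]
  }
  point <- fit1(x)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fit1(x[idx, , drop = FALSE]), error = function(e) NA_real_)
    }, numeric(1))
  })
  dropped <- sum(is.na(boot))
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(point = point, ci = c(lower = qs[1], upper = qs[2]), level = level,
       B = B, n_dropped = dropped, boot = boot[!is.na(boot)])
}
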