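# Latent-variable selection: Spearman correlation of every candidate latent
# with every original vulnerability variable. The analysis wants an index
# that tracks all 12 indicators at once, so the selection criterion is the
# minimum absolute Spearman correlation across variables (a consistency
# measure), with ties broken by the mean absolute correlation. Both are
# invariant to monotone transforms and sign flips of a latent.

#' Select the best latent variable by Spearman correlation structure
#'
#' Computes the Spearman correlation of every latent column of every
#' supplied result against every raw vulnerability variable, scores each
#' latent by its minimum absolute correlation across the variables (ties
#' broken by the mean absolute correlation), and selects the arg-max latent.
#' Latents with zero variance get missing correlations and are excluded.
#' Methods whose backend did not run are listed in `not_run`. Adapters that
#' return more than two latents (t-SNE returns 3) contribute only their
#' first two to the default comparison; the extras are recorded in
#' `extra_latents`.
#'
#' @param results list of `latent_index` / `latent_not_run` objects.
#' @param raw the raw percentage table the indices were built from.
#' @param max_latents_per_method latents per method entering the comparison
#'   (default 2).
#' @return A `latent_selection`: `spearman` (latents x variables matrix),
#'   `criterion` (min |rho| per latent), `mean_abs` (tie-break), `chosen`
#'   (latent identifier), `chosen_method`, `chosen_scores`, `not_run`,
#'   `extra_latents`.
#' @export
select_latent <- function(results, raw, max_latents_per_method = 2L) {
  x <- extract_vuln_columns(raw)
  ran <- Filter(function(r) inherits(r, "latent_index"), results)
  not_run <- vapply(Filter(function(r) inherits(r, "latent_not_run"), results),
                    function(r) r$method, character(1))
  if (length(ran) == 0L) stop("no latent result with scores was supplied")
  cols <- list(); ids <- character(0); extra <- character(0)
  for (r in ran) {
    sc <- r$scores
    take <- seq_len(min(ncol(sc), max_latents_per_method))
    if (ncol(sc) > max_latents_per_method)
      extra <- c(extra, paste0(r$method, "_",
                               colnames(sc)[-take]))
    for (j in take) {
      cols[[length(cols) + 1L]] <- sc[, j]
      ids <- c(ids, paste0(r$method, "_", colnames(sc)[j]))
    }
  }
  S <- matrix(NA_real_, length(cols), ncol(x),
              dimnames = list(ids, colnames(x)))
  for (i in seq_along(cols)) {
    if (stats::sd(cols[[i]]) == 0) next       # zero-variance latent: excluded
    S[i, ] <- suppressWarnings(
      stats::cor(cols[[i]], x, method = "spearman"))
  }
  crit <- apply(abs(S), 1, min)
  mabs <- rowMeans(abs(S))
  ok <- !is.na(crit)
  if (!any(ok)) stop("all candidate latents have zero variance")
  best <- which(ok & crit == max(crit[ok]))
  if (length(best) > 1L) best <- best[which.max(mabs[best])]
  chosen_method <- sub("_.*$", "", ids[best])
  chosen_scores <- cols[[best]]
  structure(list(spearman = S, criterion = crit, mean_abs = mabs,
                 chosen = ids[best], chosen_method = chosen_method,
                 chosen_scores = chosen_scores, not_run = not_run,
                 extra_latents = extra),
            class = "latent_selection")
}

#' @export
print.latent_selection <- function(x, ...) {
  cat(sprintf("latent_selection: %d candidate latents, chosen %s\n",
              nrow(x$spearman), x$chosen))
  cat(sprintf("  criterion (min |Spearman rho|): %.3f; mean |rho|: %.3f\n",
              x$criterion[x$chosen], x$mean_abs[x$chosen]))
  if (length(x$not_run))
    cat("  not run:", paste(x$not_run, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a pediatric vulnerability index
#'
#' The package's estimator: preprocesses the 12-variable tract table
#' (log10(x+1), center-scale), fits the requested dimensionality-reduction
#' methods (PCA and EFA natively; t-SNE/UMAP/autoencoder through adapters
#' that degrade gracefully when a backend is missing), selects the final
#' latent by Spearman correlation consistency, and optionally bootstraps a
#' confidence interval for the explained variance of the first PCA/EFA
#' component.
#'
#' @param data tract table (data.frame with the 12 percentage columns, e.g.
#'   from [generate_tracts()]).
#' @param methods character subset of `c("pca", "efa", "tsne", "umap",
#'   "ae")`.
#' @param n_components components/factors retained per native method.
#' @param bootstrap_B bootstrap replicates for the explained-variance CI of
#'   PCA (and EFA when fitted); 0 skips the bootstrap.
#' @param level confidence level of the bootstrap interval.
#' @param seed integer seed for bootstrap and adapters.
#' @return An object of class `vuln_index` with components `matrix` (the
#'   `vuln_matrix`), `results` (per-method `latent_index` objects),
#'   `selection` (the `latent_selection`), `scores` (chosen latent per
#'   tract), and `tract_id` when available.
#' @seealso [pca_index()], [efa_index()], [select_latent()],
#'   [bootstrap_variance_ci()]
#' @examples
#' sc <- risk_scenario(seed = 3, n_tracts = 100,
#'                     grid_fine = grid_spec(0, 0, 1000, 20, 20),
#'                     grid_coarse = grid_spec(0, 0, 4000, 5, 5))
#' tr <- generate_tracts(sc)
#' fit <- vuln_index(tr, methods = c("pca", "efa"))
#' fit
#' coef(fit)[, 1]
#' @export
vuln_index <- function(data, methods = c("pca", "efa"), n_components = 2L,
                       bootstrap_B = 0L, level = 0.95, seed = 1L) {
  methods <- match.arg(methods, c("pca", "efa", "tsne", "umap", "ae"),
                       several.ok = TRUE)
  m <- preprocess_vulnerability(data)
  results <- list()
  for (meth in methods) {
    results[[meth]] <- switch(meth,
      pca = pca_index(m, n_components),
      efa = efa_index(m, n_components),
      embed_adapter(m, meth, seed = seed))
  }
  if (bootstrap_B > 0L) {
    for (meth in intersect(c("pca", "efa"), methods)) {
      ci <- bootstrap_variance_ci(data, toupper(meth), B = bootstrap_B,
                                  level = level, seed = seed)
      results[[meth]]$ci <- ci$ci
      results[[meth]]$bootstrap <- ci
    }
  }
  sel <- select_latent(results, data)
  structure(list(matrix = m, results = results, selection = sel,
                 scores = sel$chosen_scores,
                 tract_id = if ("tract_id" %in% names(data)) data$tract_id
                 else NULL,
                 call = match.call()),
            class = "vuln_index")
}

#' @export
print.vuln_index <- function(x, ...) {
  cat("Pediatric vulnerability index\n")
  cat(sprintf("  %d tracts, methods: %s\n", length(x$scores),
              paste(names(x$results), collapse = ", ")))
  cat(sprintf("  chosen latent: %s (min |rho| = %.3f)\n",
              x$selection$chosen,
              x$selection$criterion[x$selection$chosen]))
  pca <- x$results$pca
  if (!is.null(pca)) {
    cat(sprintf("  PC1 variance explained: %.1f%%",
                100 * pca$variance_explained[1]))
    if (!is.null(pca$ci))
      cat(sprintf(" (%.0f%% CI %.1f-%.1f%%)", 100 * 0.95,
                  100 * pca$ci[1], 100 * pca$ci[2]))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.vuln_index <- function(object, ...) {
  out <- list(n = length(object$scores),
              methods = names(object$results),
              chosen = object$selection$chosen,
              criterion = object$selection$criterion,
              spearman = object$selection$spearman,
              not_run = object$selection$not_run,
              loadings = lapply(object$results, function(r)
                if (inherits(r, "latent_index")) r$loadings else NULL),
              variance = lapply(object$results, function(r)
                if (inherits(r, "latent_index")) r$variance_explained
                else NULL),
              score_summary = summary(object$scores))
  class(out) <- "summary.vuln_index"
  out
}

#' @export
print.summary.vuln_index <- function(x, ...) {
  cat(sprintf("vuln_index over %d tracts; chosen latent %s\n", x$n, x$chosen))
  cat("\nSelection criterion (min |Spearman rho| per latent):\n")
  print(round(x$criterion, 3))
  if (!is.null(x$loadings$pca)) {
    cat("\nPCA loadings:\n")
    print(round(x$loadings$pca, 3))
  }
  if (!is.null(x$loadings$efa)) {
    cat("\nEFA pattern loadings:\n")
    print(round(x$loadings$efa, 3))
  }
  cat("\nChosen score distribution:\n")
  print(x$score_summary)
  invisible(x)
}

#' @export
coef.vuln_index <- function(object, method = NULL, ...) {
  if (is.null(method)) {
    method <- tolower(object$selection$chosen_method)
    if (!method %in% names(object$results) ||
        is.null(object$results[[method]]$loadings))
      method <- "pca"
  }
  object$results[[method]]$loadings
}

#' @export
predict.vuln_index <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  method <- tolower(object$selection$chosen_method)
  if (!method %in% c("pca", "efa"))
    stop("prediction for new tracts is only defined for PCA/EFA latents")
  x <- extract_vuln_columns(newdata)
  y <- log10(x + 1)
  z <- sweep(sweep(y, 2, object$matrix$center), 2, object$matrix$scale, "/")
  r <- object$results[[method]]
  comp <- as.integer(sub("^[A-Z]+_(PC|F)", "", object$selection$chosen))
  if (method == "pca") {
    as.vector(z %*% r$loadings[, comp])
  } else {
    R <- stats::cor(object$matrix$transformed)
    as.vector(z %*% solve(R) %*% r$structure[, comp])
  }
}

#' @export
plot.vuln_index <- function(x, ...) {
  S <- x$selection$spearman
  op <- graphics::par(mar = c(8, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(S)), seq_len(nrow(S)), t(S)[, rev(seq_len(nrow(S))), drop = FALSE],
                  col = grDevices::hcl.colors(21, "Blue-Red 3"),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  main = "Spearman correlation: latents vs variables")
  graphics::axis(1, seq_len(ncol(S)), colnames(S), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(S)), rev(rownames(S)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
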