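# Embedding adapters. t-SNE, UMAP and the autoencoder enter the method
# comparison through a thin adapter contract: consume the preprocessed
# matrix, return latent columns plus the method's fit metric. The chosen
# index (PCA) never depends on any of them, so a missing backend degrades
# gracefully: the method is recorded as "not run" in the selection report.

#' Is an embedding backend available?
#'
#' `"tsne"` requires the Rtsne package, `"umap"` requires uwot; `"ae"` uses
#' the package's own compact multilayer-perceptron autoencoder and is always
#' available. Setting `options(pedrisk.disable_backends = c("tsne"))`
#' declares a backend unavailable, which exercises the graceful-degradation
#' path.
#'
#' @param method `"tsne"`, `"umap"` or `"ae"`.
#' @export
adapter_available <- function(method = c("tsne", "umap", "ae")) {
  method <- match.arg(method)
  if (method %in% getOption("pedrisk.disable_backends", character(0)))
    return(FALSE)
  switch(method,
         tsne = requireNamespace("Rtsne", quietly = TRUE),
         umap = requireNamespace("uwot", quietly = TRUE),
         ae = TRUE)
}

#' Run an embedding adapter
#'
#' Applies the named embedding to the preprocessed matrix under the adapter
#' contract: 2 latent columns (3 for t-SNE, of which the default method
#' comparison uses the first 2) plus a method-specific fit metric. Defaults
#' mirror common practice for this analysis: t-SNE perplexity 40, theta 0.8,
#' 3 output dims; autoencoder layers 12-8-2-8-12, mean-squared-error loss,
#' adaptive-moment (Adam) optimizer. Runs are seeded where the backend
#' allows.
#'
#' @param m a `vuln_matrix`.
#' @param method `"tsne"`, `"umap"` or `"ae"`.
#' @param params named list overriding method defaults.
#' @param seed integer seed.
#' @return A `latent_index`, or an object of class `latent_not_run` when
#'   the backend is unavailable.
#' @export
embed_adapter <- function(m, method = c("tsne", "umap", "ae"),
                          params = list(), seed = 1L) {
  stopifnot(inherits(m, "vuln_matrix"))
  method <- match.arg(method)
  if (!adapter_available(method)) {
    return(structure(list(method = toupper(method),
                          reason = "backend not installed"),
                     class = "latent_not_run"))
  }
  z <- m$transformed
  if (method == "tsne") {
    p <- utils::modifyList(list(perplexity = 40, theta = 0.8, dims = 3), params)
    fit <- with_seed(seed, Rtsne::Rtsne(z, dims = p$dims,
                                        perplexity = min(p$perplexity,
                                                         (nrow(z) - 1) %/% 3),
                                        theta = p$theta, pca = FALSE,
                                        check_duplicates = FALSE))
    sc <- fit$Y
    colnames(sc) <- paste0("TSNE", seq_len(ncol(sc)))
    return(latent_index_result("TSNE", sc,
                               fit_metric = c(stress = utils::tail(fit$itercosts, 1))))
  }
  if (method == "umap") {
    p <- utils::modifyList(list(n_neighbors = 15, n_components = 2), params)
    sc <- with_seed(seed, uwot::umap(z, n_neighbors = p$n_neighbors,
                                     n_components = p$n_components))
    colnames(sc) <- paste0("UMAP", seq_len(ncol(sc)))
    return(latent_index_result("UMAP", sc, fit_metric = c(na = NA_real_)))
  }
  p <- utils::modifyList(list(hidden = c(8L, 2L, 8L), epochs = 2000L,
                              lr = 0.01, bottleneck = 2L), params)
  fit <- train_autoencoder(z, hidden = p$hidden, epochs = p$epochs,
                           lr = p$lr, seed = seed)
  latent_index_result("AE", fit$latent,
                      fit_metric = c(reconstruction_mse = fit$mse))
}

#' @export
print.latent_not_run <- function(x, ...) {
  cat(sprintf("latent method %s: not run (%s)\n", x$method, x$reason))
  invisible(x)
}

# ---- compact native autoencoder -------------------------------------------

# fully connected autoencoder input -> hidden ... -> input with tanh on the
# non-bottleneck hidden layers and linear bottleneck/output, trained by
# full-batch Adam on mean squared error
train_autoencoder <- function(X, hidden = c(8L, 2L, 8L), epochs = 2000L,
                              lr = 0.01, seed = 1L,
                              beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  X <- as.matrix(X)
  sizes <- c(ncol(X), hidden, ncol(X))
  L <- length(sizes) - 1L
  bottleneck <- which.min(hidden) + 1L          # layer index of the code
  act <- ifelse(seq_len(L) == bottleneck - 1L | seq_len(L) == L,
                "linear", "tanh")
  n <- nrow(X)
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                          sqrt(1 / sizes[l])), sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    mse <- NA_real_
    for (ep in seq_len(epochs)) {
      # forward
      A <- vector("list", L + 1L); A[[1]] <- X
      for (l in seq_len(L)) {
        Zl <- A[[l]] %*% W[[l]] + rep(b[[l]], each = n)
        A[[l + 1]] <- if (act[l] == "tanh") tanh(Zl) else Zl
      }
      err <- A[[L + 1]] - X
      mse <- mean(err^2)
      # backward
      delta <- 2 * err / length(err)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(W[[l]])
          if (act[l - 1L] == "tanh") delta <- delta * (1 - A[[l]]^2)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
        mhb <- mb[[l]] / (1 - beta1^ep); vhb <- vb[[l]] / (1 - beta2^ep)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    # final forward pass for the code layer
    A <- X
    latent <- NULL
    for (l in seq_len(L)) {
      A <- A %*% W[[l]] + rep(b[[l]], each = n)
      if (act[l] == "tanh") A <- tanh(A)
      if (l == bottleneck - 1L) latent <- A
    }
    colnames(latent) <- paste0("AE", seq_len(ncol(latent)))
    list(latent = latent, mse = mean((A - X)^2), weights = W, biases = b)
  })
}
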