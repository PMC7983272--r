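#' Dimensionality reduction at cell or cluster level
#'
#' Computes a low-dimensional embedding of the kept cells (`level = "cells"`)
#' or of the cluster centroids (`level = "clusters"`). PCA is exact (centred
#' singular value decomposition); tSNE and UMAP are stochastic and seeded;
#' diffusion maps follow the Gaussian-kernel Markov-matrix construction of
#' [diffusion_map()]. Cell-level tSNE/UMAP/diffusion maps refuse to run above
#' 100,000 kept cells unless `force = TRUE` — downsample first.
#'
#' @param state a `cyto_state`.
#' @param method `"pca"`, `"tsne"`, `"dm"` or `"umap"`.
#' @param ndim number of output dimensions.
#' @param seed integer seed for the stochastic methods.
#' @param level `"cells"` (kept cells) or `"clusters"` (centroids).
#' @param force run cell-level nonlinear methods even above the size guard.
#' @param perplexity tSNE perplexity (capped to the sample size).
#' @param n_neighbors UMAP neighbourhood size.
#' @param sigma diffusion-map kernel bandwidth, or `"auto"`.
#' @return The state with the embedding stored under the method name.
#' @export
run_dimred <- function(state, method = c("pca", "tsne", "dm", "umap"),
                       ndim = 2, seed = 42, level = c("cells", "clusters"),
                       force = FALSE, perplexity = 30, n_neighbors = 15,
                       sigma = "auto") {
  stopifnot(inherits(state, "cyto_state"))
  method <- match.arg(method)
  level <- match.arg(level)
  if (level == "cells") {
    idx <- kept_indices(state)
    x <- state$events$values[idx, , drop = FALSE]
    if (method != "pca" && nrow(x) > 100000 && !force)
      stop_ct("more than 100,000 kept cells; downsample first or set force = TRUE")
  } else {
    require_stage(state, "clusters")
    if (is.null(state$cluster_table) ||
        is.null(state$cluster_table$centroid_expression))
      state <- cluster_coordinates(state, "expression")
    x <- state$cluster_table$centroid_expression
  }
  coords <- compute_embedding(x, method, ndim, seed, perplexity, n_neighbors, sigma)
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0(toupper(method), "_", seq_len(ncol(coords)))
  state <- clear_from(state, "dimred")
  if (level == "cells") {
    state$embeddings[[method]] <- coords
  } else {
    if (is.null(state$cluster_table$centroid_embedding))
      state$cluster_table$centroid_embedding <- list()
    state$cluster_table$centroid_embedding[[method]] <- coords
  }
  add_log(state, "run_dimred",
          list(method = method, ndim = ndim, seed = seed, level = level))
}

compute_embedding <- function(x, method, ndim, seed, perplexity, n_neighbors,
                              sigma) {
  n <- nrow(x)
  switch(method,
    pca = {
      if (ndim >= ncol(x))
        stop_ct("PCA ndim (", ndim, ") must be smaller than the number of features (",
                ncol(x), ")")
      p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
      p$x[, seq_len(ndim), drop = FALSE]
    },
    tsne = {
      perp <- min(perplexity, floor((n - 1) / 3))
      if (perp < 1) stop_ct("too few cells for tSNE")
      withr::with_seed(seed,
        Rtsne::Rtsne(x, dims = ndim, perplexity = perp, check_duplicates = FALSE,
                     pca = ncol(x) > 50, num_threads = 1)$Y)
    },
    umap = {
      nb <- max(2L, min(n_neighbors, n - 1L))
      withr::with_seed(seed,
        uwot::umap(x, n_components = ndim, n_neighbors = nb,
                   n_threads = 1, n_sgd_threads = 0))
    },
    dm = diffusion_map(x, ndim = ndim, sigma = sigma))
}

#' Diffusion-map embedding
#'
#' Builds the Gaussian kernel `K_ij = exp(-d_ij^2 / (2 sigma^2))` over
#' Euclidean distances, applies density normalization
#' (`K / (q q^T)` with `q = rowSums(K)`, removing the influence of sampling
#' density), row-normalizes to a Markov transition matrix and takes its top
#' non-trivial right eigenvectors, each scaled by its eigenvalue, as
#' coordinates. The trivial constant eigenvector (eigenvalue 1) is dropped.
#' Eigenvector signs are fixed so the largest-magnitude entry is positive.
#'
#' @param x numeric matrix, observations x features.
#' @param ndim number of diffusion components; needs `nrow(x) >= ndim + 2`.
#' @param sigma kernel bandwidth; `"auto"` uses the median nonzero pairwise
#'   distance.
#' @return List-free numeric matrix of coordinates with attributes
#'   `eigenvalues` and `sigma`.
#' @export
diffusion_map <- function(x, ndim = 2, sigma = "auto", seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < ndim + 2) stop_ct("diffusion_map needs at least ndim + 2 rows")
  d <- as.matrix(stats::dist(x))
  if (any(!is.finite(d))) stop_ct("non-finite distances in diffusion_map input")
  if (identical(sigma, "auto")) {
    nz <- d[upper.tri(d)]
    nz <- nz[nz > 0]
    sigma <- if (length(nz)) stats::median(nz) else 1
  }
  K <- exp(-d^2 / (2 * sigma^2))
  q <- rowSums(K)
  K1 <- K / (q %o% q)
  dd <- rowSums(K1)
  # symmetric conjugate of the Markov matrix P = D^-1 K1:
  # S = D^-1/2 K1 D^-1/2 shares P's eigenvalues; right eigenvectors of P are
  # D^-1/2 times S's eigenvectors.
  S <- K1 / sqrt(dd %o% dd)
  eig <- eigen(S, symmetric = TRUE)
  psi <- eig$vectors / sqrt(dd)
  lam <- eig$values
  keep <- seq(2, ndim + 1)
  coords <- psi[, keep, drop = FALSE]
  # unit-norm columns (eigenvector scale is arbitrary), then eigenvalue scaling
  coords <- sweep(coords, 2, sqrt(colSums(coords^2)), `/`)
  coords <- sweep(coords, 2, lam[keep], `*`)
  for (j in seq_len(ncol(coords))) {
    m <- which.max(abs(coords[, j]))
    if (coords[m, j] < 0) coords[, j] <- -coords[, j]
  }
  attr(coords, "eigenvalues") <- lam[keep]
  attr(coords, "sigma") <- sigma
  coords
}
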