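#' Cluster cells without supervision
#'
#' Groups every cell into one of K clusters. The default method is a
#' self-organizing map on a 6x6 grid (each cell's cluster is its winning grid
#' node, so K <= xdim*ydim); `kmeans` uses kmeans++ seeding and `hclust` uses
#' Ward linkage on Euclidean distances. A user-supplied `plugin` callable
#' (matrix -> integer labels) hooks in external methods such as clara or
#' PhenoGraph. Rows are presented to stochastic methods in an order derived
#' from cell ids, so results are invariant to row permutation.
#'
#' Re-clustering clears all downstream results (embeddings, tree, graph,
#' pseudotime, walk).
#'
#' @param state a [create_state()] object.
#' @param method `"som"` (default), `"kmeans"`, `"hclust"` or `"plugin"`.
#' @param xdim,ydim,rlen,alpha SOM grid and training parameters.
#' @param k number of clusters for kmeans/hclust.
#' @param plugin function(matrix) -> integer labels, for `method = "plugin"`.
#' @param seed integer seed.
#' @return The state with per-cell `cluster_labels` in 1..K.
#' @export
run_cluster <- function(state, method = c("som", "kmeans", "hclust", "plugin"),
                        xdim = 6, ydim = 6, rlen = 8, alpha = c(0.05, 0.01),
                        k = NULL, plugin = NULL, seed = 42) {
  stopifnot(inherits(state, "cyto_state"))
  method <- match.arg(method)
  x <- state$events$values
  n <- nrow(x)
  # canonical row order: stochastic methods see rows sorted by cell id
  ord <- order(rownames(x))
  xs <- x[ord, , drop = FALSE]
  labels_sorted <- switch(method,
    som = som_fit(xs, xdim = xdim, ydim = ydim, rlen = rlen, alpha = alpha,
                  seed = seed)$mapping,
    kmeans = {
      check_k(k, n)
      withr::with_seed(seed, {
        centers <- kmeanspp_rows(xs, k)
        fit <- suppressWarnings(stats::kmeans(xs, centers = centers,
                                              iter.max = 100))
        labs <- fit$cluster
        # re-seed any emptied cluster from the point farthest from its center
        empty <- setdiff(seq_len(k), unique(labs))
        for (e in empty) {
          far <- which.max(rowSums((xs - fit$centers[labs, , drop = FALSE])^2))
          labs[far] <- e
        }
        labs
      })
    },
    hclust = {
      check_k(k, n)
      hc <- stats::hclust(stats::dist(xs), method = "ward.D2")
      stats::cutree(hc, k = k)
    },
    plugin = {
      if (!is.function(plugin)) stop_ct("method 'plugin' requires a plugin function")
      labs <- plugin(xs)
      if (length(labs) != n) stop_ct("plugin returned ", length(labs),
                                     " labels for ", n, " cells")
      as.integer(as.factor(labs))
    })
  labels <- integer(n)
  labels[ord] <- as.integer(labels_sorted)
  state <- clear_from(state, "cluster")
  state$cluster_labels <- labels
  params <- list(method = method, seed = seed)
  if (method == "som") params <- c(params, list(xdim = xdim, ydim = ydim, rlen = rlen))
  if (method %in% c("kmeans", "hclust")) params$k <- k
  params$n_clusters <- length(unique(labels))
  add_log(state, "run_cluster", params)
}

check_k <- function(k, n) {
  if (is.null(k) || !is.numeric(k) || k < 2)
    stop_ct("k must be an integer >= 2")
  if (k > n) stop_ct("k (", k, ") exceeds the number of cells (", n, ")")
  invisible(TRUE)
}

#' Cluster-dependent downsampling
#'
#' Subsamples each cluster separately: cluster `c` keeps
#' `max(1, ceiling(fraction * size_c))` cells, drawn uniformly without
#' replacement. Sampling within a cluster is keyed on cell ids, so the kept
#' set is reproducible and row-order independent. Because every cluster keeps
#' at least one cell, small populations are never dropped.
#'
#' @param state a clustered `cyto_state`.
#' @param fraction fraction in (0, 1] of each cluster to keep.
#' @param seed integer seed.
#' @return The state with a per-cell logical `kept_mask`.
#' @export
cluster_downsample <- function(state, fraction, seed = 42) {
  stopifnot(inherits(state, "cyto_state"))
  require_stage(state, "clusters")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop_ct("fraction must be in (0, 1]")
  ids <- state_cell_ids(state)
  pr <- cell_priority(ids, seed)
  keep <- rep(FALSE, n_cells(state))
  for (cl in sort(unique(state$cluster_labels))) {
    members <- which(state$cluster_labels == cl)
    m <- max(1L, ceiling(fraction * length(members)))
    keep[members[order(pr[members])[seq_len(m)]]] <- TRUE
  }
  state <- clear_from(state, "downsample")
  state$kept_mask <- keep
  add_log(state, "cluster_downsample",
          list(fraction = fraction, seed = seed, kept = sum(keep)))
}

#' Compute per-cluster centroids
#'
#' The centroid of cluster `j` in dimension `i` is the arithmetic mean of that
#' dimension over the cells of cluster `j`. In expression space the mean runs
#' over all clustered cells; in an embedding space it runs over the kept
#' (downsampled) cells, since embeddings are computed on kept cells only.
#'
#' @param state a clustered `cyto_state`.
#' @param space `"expression"` or the name of a computed embedding.
#' @return The state with `cluster_table` centroids for the requested space.
#' @export
cluster_coordinates <- function(state, space = "expression") {
  stopifnot(inherits(state, "cyto_state"))
  require_stage(state, "clusters")
  labels <- state$cluster_labels
  cl_ids <- sort(unique(labels))
  if (is.null(state$cluster_table)) {
    state$cluster_table <- list(
      cluster_ids = cl_ids,
      sizes = as.integer(table(factor(labels, levels = cl_ids))),
      centroid_expression = NULL,
      centroid_embedding = list(),
      branch_labels = NULL)
  }
  if (space == "expression") {
    x <- state$events$values
    cen <- group_means(x, labels, cl_ids)
    state$cluster_table$centroid_expression <- cen
  } else {
    if (!space %in% names(state$embeddings))
      stop_ct("embedding '", space, "' not computed; run run_dimred() first")
    emb <- state$embeddings[[space]]
    kept <- kept_indices(state)
    lab_kept <- labels[kept]
    empty <- setdiff(cl_ids, unique(lab_kept))
    if (length(empty))
      stop_ct("cluster(s) with no kept cells in embedding space: ",
              paste(empty, collapse = ", "))
    cen <- group_means(emb, lab_kept, cl_ids)
    state$cluster_table$centroid_embedding[[space]] <- cen
  }
  add_log(state, "cluster_coordinates", list(space = space))
}

group_means <- function(x, labels, levels) {
  out <- matrix(NA_real_, length(levels), ncol(x),
                dimnames = list(as.character(levels), colnames(x)))
  for (i in seq_along(levels)) {
    rows <- labels == levels[i]
    out[i, ] <- colMeans(x[rows, , drop = FALSE])
  }
  out
}
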