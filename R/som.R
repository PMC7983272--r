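#' Fit a rectangular-grid self-organizing map
#'
#' Online (sequential) SOM on an `xdim` x `ydim` rectangular grid with
#' Euclidean winner selection and a bubble neighbourhood: at each presentation
#' the winning node and every node within the current grid radius move toward
#' the presented cell by the current learning rate. The radius shrinks
#' linearly from two thirds of the grid diameter to zero and the learning rate
#' from `alpha[1]` to `alpha[2]` over `rlen` passes through the data. Node
#' codebooks are initialized from a spread ("farthest-point style",
#' kmeans++-sampled) subset of the data rows, which avoids dead units when the
#' data contain at least as many well-separated populations as grid nodes.
#'
#' Cells are presented in a seeded random order of their row identity, so the
#' fit depends on the seed but not on the row order of the input matrix.
#'
#' @param x numeric matrix, cells x markers; finite values only.
#' @param xdim,ydim grid dimensions; `xdim * ydim >= 2`.
#' @param rlen number of passes through the data.
#' @param alpha length-2 learning-rate range, start and end.
#' @param seed integer seed.
#' @param polish run the batch refinement / dead-unit re-seeding phase after
#'   online training (recommended; see Details).
#' @return List with `codes` (nodes x markers codebook), `mapping` (per-cell
#'   winning node in 1..xdim*ydim), `grid` (node coordinates), `xdim`, `ydim`.
#' @export
som_fit <- function(x, xdim = 6, ydim = 6, rlen = 8, alpha = c(0.05, 0.01),
                    seed = 42, polish = TRUE) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop_ct("som_fit: input contains non-finite values")
  nnodes <- xdim * ydim
  if (nnodes < 2) stop_ct("som_fit: grid must have at least 2 nodes")
  n <- nrow(x)
  grid <- as.matrix(expand.grid(gx = seq_len(xdim), gy = seq_len(ydim)))
  gd <- as.matrix(stats::dist(grid))          # grid-space distances
  radius0 <- stats::quantile(gd, 0.67, names = FALSE)

  codes <- withr::with_seed(seed, kmeanspp_rows(x, min(nnodes, n)))
  if (nrow(codes) < nnodes)                    # fewer cells than nodes
    codes <- codes[rep(seq_len(nrow(codes)), length.out = nnodes), , drop = FALSE]

  order_steps <- withr::with_seed(seed + 1L, {
    unlist(lapply(seq_len(max(rlen, 0)), function(r) sample.int(n)), use.names = FALSE)
  })
  nsteps <- length(order_steps)
  if (nsteps > 0) {
    alphas <- seq(alpha[1], alpha[2], length.out = nsteps)
    radii <- seq(radius0, 0, length.out = nsteps)
    for (s in seq_len(nsteps)) {
      v <- x[order_steps[s], ]
      d2 <- rowSums((codes - matrix(v, nnodes, ncol(x), byrow = TRUE))^2)
      win <- which.min(d2)
      nb <- which(gd[win, ] <= radii[s])
      codes[nb, ] <- codes[nb, , drop = FALSE] +
        alphas[s] * (matrix(v, length(nb), ncol(x), byrow = TRUE) -
                       codes[nb, , drop = FALSE])
    }
  }
  if (polish) codes <- som_polish(x, codes)
  mapping <- map_to_codes(x, codes)
  list(codes = codes, mapping = mapping, grid = grid, xdim = xdim, ydim = ydim)
}

# Batch refinement after online training: recenter every node on the cells it
# wins and re-seed dead nodes from the cells worst represented by their
# current winner. Iterates until the mapping is stable (at most 20 rounds).
# This removes the dead grid units classic online SOM is prone to when the
# data hold at least as many well-separated populations as grid nodes, so a
# full grid yields a full complement of clusters.
som_polish <- function(x, codes, max_iter = 20) {
  nnodes <- nrow(codes)
  prev <- NULL
  for (it in seq_len(max_iter)) {
    mapping <- map_to_codes(x, codes)
    if (identical(mapping, prev)) break
    prev <- mapping
    counts <- tabulate(mapping, nnodes)
    for (i in which(counts > 0))
      codes[i, ] <- colMeans(x[mapping == i, , drop = FALSE])
    empty <- which(counts == 0)
    if (length(empty)) {
      resid <- rowSums((x - codes[mapping, , drop = FALSE])^2)
      ord <- order(resid, decreasing = TRUE)
      seeds <- ord[seq_len(min(length(empty), length(ord)))]
      keep <- resid[seeds] > 0
      codes[empty[keep], ] <- x[seeds[keep], , drop = FALSE]
      prev <- NULL                      # force another mapping pass
    }
  }
  codes
}

# nearest codebook node (Euclidean) for every row
map_to_codes <- function(x, codes) {
  cx <- rowSums(x^2)
  cc <- rowSums(codes^2)
  cross <- x %*% t(codes)
  d2 <- outer(cx, cc, "+") - 2 * cross
  max.col(-d2, ties.method = "first")
}

# kmeans++-style sampling of k spread rows (returned as a k x p matrix).
# Assumes the RNG is already seeded by the caller.
kmeanspp_rows <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  mind2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    p <- if (sum(mind2) > 0) mind2 / sum(mind2) else rep(1 / n, n)
    idx[i + 1] <- sample.int(n, 1, prob = p)
    d2 <- rowSums((x - matrix(x[idx[i + 1], ], n, ncol(x), byrow = TRUE))^2)
    mind2 <- pmin(mind2, d2)
  }
  x[idx, , drop = FALSE]
}
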