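# Independent oracles used to verify the package's graph algorithms.

# All-pairs shortest paths by Floyd-Warshall on an edge list (1-based node
# indices, undirected unless directed = TRUE).
floyd_warshall <- function(n, edges, directed = FALSE) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]; w <- edges$weight[e]
    d[i, j] <- min(d[i, j], w)
    if (!directed) d[j, i] <- min(d[j, i], w)
  }
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# Decode a Prufer sequence into the edge list of a labelled tree on n nodes.
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1, 2)
  ptr <- 1L
  for (s in seq) {
    leaf <- which(degree == 1L)[1]
    edges[ptr, ] <- c(leaf, s)
    ptr <- ptr + 1L
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  u <- which(degree == 1L)
  edges[ptr, ] <- u
  edges
}

# Minimum spanning-tree weight by exhaustive enumeration of all n^(n-2)
# labelled trees (Cayley), for n in 2..6.
brute_mst_weight <- function(dmat) {
  n <- nrow(dmat)
  if (n == 2) return(dmat[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_decode(seqs[r, ], n)
    w <- sum(dmat[ed])
    if (w < best) best <- w
  }
  best
}

# Deterministic shortest path from s to t on a directed weighted graph,
# following the smallest-predecessor tie-break: dist by Floyd-Warshall, then
# pred[v] = smallest node index u with dist(s,u) + w(u,v) == dist(s,v).
# Valid for strictly positive weights. Returns NULL when unreachable.
oracle_path <- function(n, edges, s, t, tol = 1e-9) {
  d <- floyd_warshall(n, edges, directed = TRUE)
  if (!is.finite(d[s, t])) return(NULL)
  wmat <- matrix(Inf, n, n)
  for (e in seq_len(nrow(edges)))
    wmat[edges$i[e], edges$j[e]] <- min(wmat[edges$i[e], edges$j[e]],
                                        edges$weight[e])
  path <- t
  while (path[1] != s) {
    v <- path[1]
    cand <- which(abs(d[s, ] + wmat[, v] - d[s, v]) <= tol & is.finite(wmat[, v]))
    path <- c(cand[1], path)
  }
  path
}

# Enumerate walk counts with the oracle: forward root->leaf on the reversed
# orientation, backward leaf->root on the orientation, smallest-predecessor
# tie-break.
oracle_counts <- function(n, directed, roots, leaves) {
  rev_edges <- data.frame(i = directed$to, j = directed$from,
                          weight = directed$weight)
  fwd_edges <- data.frame(i = directed$from, j = directed$to,
                          weight = directed$weight)
  counts <- integer(n)
  for (r in roots) for (l in leaves) {
    p <- oracle_path(n, rev_edges, r, l)
    if (!is.null(p)) counts[p] <- counts[p] + 1L
    p <- oracle_path(n, fwd_edges, l, r)
    if (!is.null(p)) counts[p] <- counts[p] + 1L
  }
  counts
}

# Adjusted Rand index between two labelings (closed form on the pair table).
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  expc <- si * sj / ch2(sum(tab))
  (sij - expc) / ((si + sj) / 2 - expc)
}

# Small star3 dataset shared by several test files.
star3_sim <- function(seed = 7, n = 200, noise = 0.1)
  simulate_tree_data(star_topology(3), n_per_segment = n, n_markers = 10,
                     noise_sd = noise, seed = seed)

# A tiny deterministic events object.
toy_events <- function(n = 10, p = 3, seed = 1) {
  m <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  colnames(m) <- paste0("M", seq_len(p))
  cyto_events(m, cell_ids = sprintf("c%03d", seq_len(n)))
}
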