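#' Build the KNN cell graph
#'
#' Connects every kept cell to its `k` nearest neighbours (Euclidean) in the
#' chosen space, then symmetrizes the edge set by union, so each node keeps at
#' least `k` incident edges. Edge weight is the Euclidean distance. Duplicate
#' coordinates give zero-weight edges, which are permitted but counted in the
#' log. The default `k` is `min(30, ceiling(sqrt(n)))`.
#'
#' @param state a `cyto_state`.
#' @param k neighbour count, `0 < k < number of kept cells`; `NULL` for the
#'   default.
#' @param space `"expression"` or a computed embedding name.
#' @return The state with a `cell_graph` (nodes, undirected weighted edges).
#' @export
build_knn <- function(state, k = NULL, space = "expression") {
  stopifnot(inherits(state, "cyto_state"))
  idx <- kept_indices(state)
  n <- length(idx)
  if (space == "expression") {
    coords <- state$events$values[idx, , drop = FALSE]
  } else {
    if (!space %in% names(state$embeddings))
      stop_ct("embedding '", space, "' not computed; run run_dimred() first")
    coords <- state$embeddings[[space]]
  }
  k <- k %||% min(30L, ceiling(sqrt(n)))
  if (!is.numeric(k) || k <= 0) stop_ct("k must be a positive integer")
  if (k >= n) stop_ct("k (", k, ") must be smaller than the number of kept cells (", n, ")")
  ids <- rownames(coords)
  # canonical node order by cell id: downstream tie-breaks refer to it
  ord <- order(ids)
  coords <- coords[ord, , drop = FALSE]
  ids <- ids[ord]
  nn <- FNN::get.knn(coords, k = k)
  i <- rep(seq_len(n), k)
  j <- as.vector(nn$nn.index)
  w <- as.vector(nn$nn.dist)
  a <- pmin(i, j); b <- pmax(i, j)
  key <- paste(a, b)
  dup <- duplicated(key)
  edges <- data.frame(i = a[!dup], j = b[!dup], weight = w[!dup])
  n_zero <- sum(edges$weight == 0)
  state <- clear_from(state, "graph")
  state$cell_graph <- list(ids = ids, edges = edges, k = as.integer(k),
                           space = space, directed = NULL)
  add_log(state, "build_knn",
          list(k = k, space = space, n_edges = nrow(edges),
               zero_weight_edges = n_zero))
}

resolve_cells <- function(state, cells = NULL, clusters = NULL, what = "cell") {
  ids <- state_cell_ids(state)
  kept <- kept_indices(state)
  sel <- integer(0)
  if (!is.null(cells)) {
    m <- match(cells, ids)
    if (anyNA(m))
      stop_ct("unknown ", what, " id(s): ", paste(cells[is.na(m)], collapse = ", "))
    not_kept <- setdiff(m, kept)
    if (length(not_kept))
      stop_ct(what, " id(s) not in the kept cell set: ",
              paste(ids[not_kept], collapse = ", "))
    sel <- c(sel, m)
  }
  if (!is.null(clusters)) {
    require_stage(state, "clusters")
    unknown <- setdiff(clusters, unique(state$cluster_labels))
    if (length(unknown))
      stop_ct("unknown cluster id(s): ", paste(unknown, collapse = ", "))
    sel <- c(sel, intersect(which(state$cluster_labels %in% clusters), kept))
  }
  sort(unique(sel))
}

#' Define root cells
#'
#' Root cells are the starting point of the biological process; their
#' pseudotime is fixed to zero. Select them explicitly by cell id or as whole
#' clusters (all kept cells of those clusters). Redefining roots replaces the
#' previous flags and clears pseudotime, leaves and walk results.
#'
#' @param state a `cyto_state`.
#' @param cells explicit cell ids.
#' @param clusters cluster ids whose kept cells become roots.
#' @return The state with `root_flags` set.
#' @export
def_root_cells <- function(state, cells = NULL, clusters = NULL) {
  stopifnot(inherits(state, "cyto_state"))
  sel <- resolve_cells(state, cells, clusters, "root")
  if (length(sel) == 0) stop_ct("root selection is empty")
  state <- clear_from(state, "roots")
  state$root_flags <- rep(FALSE, n_cells(state))
  state$root_flags[sel] <- TRUE
  add_log(state, "def_root_cells",
          list(n_roots = length(sel), clusters = clusters))
}

#' Estimate pseudotime from shortest-path distances
#'
#' Implements the four-step procedure: with root cells defined (step 1) and
#' the KNN graph built (step 2), the weighted shortest-path distance
#' `dist[i, j]` from every cell `i` to every root `j` is computed (step 3) and
#' converted to pseudotime (step 4) as
#' \deqn{D_i = (1/n) \sum_j dist_{i,j}, \quad
#'       pt_i = (D_i - \min D) / (\max D - \min D)}
#' with `n` the number of root cells. Root cells are then forced to exactly 0.
#' If `max D == min D` (e.g. every cell is a root) all pseudotime is 0. A cell
#' unreachable from every root receives the maximum finite `D` (mapping it to
#' pseudotime 1) and is listed in the log; a cell reachable from only some
#' roots averages over the reachable ones.
#'
#' @param state a `cyto_state` with a cell graph and roots.
#' @return The state with per-cell `D` and `pseudotime` (NA for cells outside
#'   the kept set).
#' @export
run_pseudotime <- function(state) {
  stopifnot(inherits(state, "cyto_state"))
  require_stage(state, "graph")
  require_stage(state, "roots")
  cg <- state$cell_graph
  ids <- cg$ids
  all_ids <- state_cell_ids(state)
  root_ids <- all_ids[state$root_flags]
  root_pos <- match(root_ids, ids)
  if (anyNA(root_pos)) stop_ct("root cells are not nodes of the cell graph")
  g <- igraph::graph_from_data_frame(
    data.frame(from = cg$edges$i, to = cg$edges$j),
    directed = FALSE, vertices = data.frame(name = seq_along(ids)))
  dmat <- igraph::distances(g, v = as.character(root_pos),
                            weights = cg$edges$weight, mode = "all")
  # dmat: roots x cells, columns in vertex order 1..n
  dmat <- dmat[, as.character(seq_along(ids)), drop = FALSE]
  D <- apply(dmat, 2, function(col) {
    fin <- is.finite(col)
    if (!any(fin)) Inf else mean(col[fin])
  })
  unreachable <- !is.finite(D)
  non_root <- setdiff(seq_along(ids), root_pos)
  if (length(non_root) && all(unreachable[non_root]))
    stop_ct("no root reaches any non-root cell; increase k in build_knn()")
  if (any(unreachable)) D[unreachable] <- max(D[is.finite(D)])
  rng <- range(D)
  pt <- if (rng[2] > rng[1]) (D - rng[1]) / (rng[2] - rng[1]) else rep(0, length(D))
  pt[root_pos] <- 0
  full_D <- stats::setNames(rep(NA_real_, length(all_ids)), all_ids)
  full_pt <- full_D
  full_D[ids] <- D
  full_pt[ids] <- pt
  state <- clear_from(state, "pseudotime")
  state$D <- full_D
  state$pseudotime <- full_pt
  add_log(state, "run_pseudotime",
          list(n_roots = length(root_ids),
               n_unreachable = sum(unreachable),
               degenerate = rng[2] <= rng[1]))
}

#' Define leaf cells
#'
#' Leaf cells are the terminal sites of differentiation. Select them
#' explicitly (cell ids or clusters) or automatically as the cells whose
#' pseudotime is at or above the `1 - q` quantile (`q = 0.02` flags the top
#' 2%). Leaves must be disjoint from roots: an explicit selection overlapping
#' the roots is an error; automatic selection skips root cells.
#'
#' @param state a `cyto_state` with pseudotime.
#' @param cells explicit cell ids.
#' @param clusters cluster ids whose kept cells become leaves.
#' @param q top-pseudotime quantile for automatic selection.
#' @return The state with `leaf_flags` set.
#' @export
def_leaf_cells <- function(state, cells = NULL, clusters = NULL, q = NULL) {
  stopifnot(inherits(state, "cyto_state"))
  require_stage(state, "pseudotime")
  if (is.null(cells) && is.null(clusters) && is.null(q))
    q <- 0.02
  if (!is.null(q)) {
    stopifnot(q > 0, q <= 1)
    pt <- state$pseudotime
    cand <- which(!is.na(pt) & !state$root_flags)
    thr <- stats::quantile(pt[!is.na(pt)], 1 - q, names = FALSE)
    sel <- cand[pt[cand] >= thr]
    if (length(sel) == 0) sel <- cand[which.max(pt[cand])]
  } else {
    sel <- resolve_cells(state, cells, clusters, "leaf")
    overlap <- sel[state$root_flags[sel]]
    if (length(overlap))
      stop_ct("leaf selection overlaps root cells: ",
              paste(state_cell_ids(state)[overlap], collapse = ", "))
  }
  if (length(sel) == 0) stop_ct("leaf selection is empty")
  state <- clear_from(state, "leaves")
  state$leaf_flags <- rep(FALSE, n_cells(state))
  state$leaf_flags[sel] <- TRUE
  add_log(state, "def_leaf_cells",
          list(n_leaves = length(sel), q = q, clusters = clusters))
}

#' Orient the cell graph by pseudotime
#'
#' Applies the descent rule: each undirected edge becomes a directed edge from
#' the higher-pseudotime endpoint to the lower one, so paths can only descend
#' pseudotime. Edges between equal-pseudotime cells stay bidirected (removing
#' them could disconnect walks); their count is logged. The backward walk
#' (leaf to root) runs on this orientation; the forward walk (root to leaf)
#' runs on its reverse.
#'
#' @param state a `cyto_state` with pseudotime.
#' @return The state with `directed` edges on the cell graph.
#' @export
orient_graph <- function(state) {
  stopifnot(inherits(state, "cyto_state"))
  require_stage(state, "graph")
  require_stage(state, "pseudotime")
  cg <- state$cell_graph
  pt <- state$pseudotime[cg$ids]
  e <- cg$edges
  pi <- pt[e$i]; pj <- pt[e$j]
  from <- ifelse(pi >= pj, e$i, e$j)
  to <- ifelse(pi >= pj, e$j, e$i)
  ties <- pi == pj
  directed <- data.frame(from = c(from, e$j[ties]),
                         to = c(to, e$i[ties]),
                         weight = c(e$weight, e$weight[ties]))
  state$cell_graph$directed <- directed
  state$walk <- NULL
  add_log(state, "orient_graph", list(tied_edges = sum(ties)))
}

# Single-source Dijkstra on an adjacency list with a deterministic tie-break:
# on equal tentative distance the predecessor with the smaller node index
# (= lexicographically smaller cell id, nodes being sorted by id) wins, and
# equal-distance nodes are settled in index order. Returns dist and pred.
dijkstra_pred <- function(adj_to, adj_w, n, source, tol = 1e-12) {
  dist <- rep(Inf, n); pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[source] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))   # first index wins ties
    if (!is.finite(dist[u]) || done[u]) break
    done[u] <- TRUE
    vs <- adj_to[[u]]
    if (length(vs)) {
      nd <- dist[u] + adj_w[[u]]
      better <- nd < dist[vs] - tol
      equal <- !better & nd <= dist[vs] + tol &
        (is.na(pred[vs]) | u < pred[vs]) & !done[vs]
      upd <- better | equal
      if (any(upd)) {
        dist[vs[better]] <- nd[better]
        pred[vs[upd]] <- u
      }
    }
    if (all(done | !is.finite(dist))) break
  }
  list(dist = dist, pred = pred)
}

extract_path <- function(pred, source, target) {
  if (is.na(pred[target]) && target != source) return(NULL)
  path <- target
  while (path[1] != source) {
    p <- pred[path[1]]
    if (is.na(p)) return(NULL)
    path <- c(p, path)
  }
  path
}

adjacency_from_edges <- function(edges, n, reverse = FALSE) {
  from <- if (reverse) edges$to else edges$from
  to <- if (reverse) edges$from else edges$to
  adj_to <- vector("list", n); adj_w <- vector("list", n)
  sp <- split(seq_len(nrow(edges)), factor(from, levels = seq_len(n)))
  for (u in seq_len(n)) {
    rows <- sp[[u]]
    adj_to[[u]] <- to[rows]
    adj_w[[u]] <- edges$weight[rows]
  }
  list(to = adj_to, w = adj_w)
}

#' Walk shortest paths between roots and leaves
#'
#' For every (root, leaf) pair, computes one forward shortest path (root to
#' leaf, on the reverse of the pseudotime orientation) and one backward
#' shortest path (leaf to root, on the orientation itself), both weighted,
#' with a deterministic smallest-predecessor tie-break. Every cell's walk
#' count is the number of such paths passing through it; cells (excluding
#' roots and leaves) whose count reaches the `quantile` level of the positive
#' interior counts are flagged as intermediate-state cells — the cells most
#' often traversed between origin and terminus of the process. Pairs with no
#' path are recorded and skipped.
#'
#' @param state a `cyto_state` with an oriented graph, roots and leaves.
#' @param quantile intermediate-state threshold on positive interior counts.
#' @return The state with a `walk` result (per-cell `counts`, `intermediate`
#'   flags, skipped pairs, parameters).
#' @export
run_walk <- function(state, quantile = 0.8) {
  stopifnot(inherits(state, "cyto_state"))
  require_stage(state, "graph")
  require_stage(state, "leaves")
  if (is.null(state$cell_graph$directed))
    state <- orient_graph(state)
  cg <- state$cell_graph
  n <- length(cg$ids)
  all_ids <- state_cell_ids(state)
  roots <- match(all_ids[state$root_flags], cg$ids)
  leaves <- match(all_ids[state$leaf_flags], cg$ids)
  fwd <- adjacency_from_edges(cg$directed, n, reverse = TRUE)
  bwd <- adjacency_from_edges(cg$directed, n, reverse = FALSE)
  counts <- integer(n)
  skipped <- list()
  n_paths <- 0L
  total_nodes <- 0L
  for (r in roots) {                 # forward walks: one Dijkstra per root
    sp <- dijkstra_pred(fwd$to, fwd$w, n, r)
    for (l in leaves) {
      path <- extract_path(sp$pred, r, l)
      if (is.null(path)) {
        skipped[[length(skipped) + 1]] <- c(root = cg$ids[r], leaf = cg$ids[l],
                                            direction = "forward")
      } else {
        counts[path] <- counts[path] + 1L
        n_paths <- n_paths + 1L
        total_nodes <- total_nodes + length(path)
      }
    }
  }
  for (l in leaves) {                # backward walks: one Dijkstra per leaf
    sp <- dijkstra_pred(bwd$to, bwd$w, n, l)
    for (r in roots) {
      path <- extract_path(sp$pred, l, r)
      if (is.null(path)) {
        skipped[[length(skipped) + 1]] <- c(root = cg$ids[r], leaf = cg$ids[l],
                                            direction = "backward")
      } else {
        counts[path] <- counts[path] + 1L
        n_paths <- n_paths + 1L
        total_nodes <- total_nodes + length(path)
      }
    }
  }
  interior <- setdiff(seq_len(n), c(roots, leaves))
  pos <- counts[interior][counts[interior] > 0]
  inter_flag <- rep(FALSE, n)
  if (length(pos)) {
    thr <- stats::quantile(pos, quantile, names = FALSE)
    inter_flag[interior] <- counts[interior] >= thr & counts[interior] > 0
  }
  full_counts <- stats::setNames(rep(0L, length(all_ids)), all_ids)
  full_counts[cg$ids] <- counts
  full_inter <- stats::setNames(rep(FALSE, length(all_ids)), all_ids)
  full_inter[cg$ids] <- inter_flag
  state$walk <- list(counts = full_counts, intermediate = full_inter,
                     n_paths = n_paths, total_path_nodes = total_nodes,
                     skipped = skipped,
                     params = list(quantile = quantile,
                                   n_roots = length(roots),
                                   n_leaves = length(leaves)))
  add_log(state, "run_walk",
          list(quantile = quantile, n_paths = n_paths,
               n_skipped = length(skipped),
               n_intermediate = sum(inter_flag)))
}
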