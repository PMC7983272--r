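#' Build the MST trajectory over cluster centroids
#'
#' Computes the minimum spanning tree of the complete Euclidean graph over
#' cluster centroids, either in expression space or in a computed embedding.
#' Kruskal's algorithm is used with a fixed tie-break — candidate edges are
#' sorted by (weight, smaller cluster id, larger cluster id) — so the tree is
#' deterministic even when centroid distances tie.
#'
#' @param state a clustered `cyto_state`.
#' @param space `"expression"` (default) or an embedding name.
#' @return The state with a `tree` (nodes, edges with weights, space used).
#' @export
build_tree <- function(state, space = "expression") {
  stopifnot(inherits(state, "cyto_state"))
  require_stage(state, "clusters")
  if (space == "expression") {
    if (is.null(state$cluster_table) ||
        is.null(state$cluster_table$centroid_expression))
      state <- cluster_coordinates(state, "expression")
    cen <- state$cluster_table$centroid_expression
  } else {
    if (is.null(state$cluster_table) ||
        is.null(state$cluster_table$centroid_embedding[[space]]))
      state <- cluster_coordinates(state, space)
    cen <- state$cluster_table$centroid_embedding[[space]]
  }
  ids <- state$cluster_table$cluster_ids
  if (length(ids) < 2) stop_ct("at least 2 clusters are required to build a tree")
  edges <- mst_kruskal(cen, ids)
  state <- clear_from(state, "tree")
  state$tree <- list(nodes = ids, edges = edges, branch_labels = NULL,
                     centroids = cen, space_used = space)
  add_log(state, "build_tree",
          list(space = space, total_weight = sum(edges$weight)))
}

# Kruskal MST over the complete Euclidean graph on rows of `cen`.
# Deterministic tie-break: sort by (weight, smaller id, larger id).
mst_kruskal <- function(cen, ids) {
  n <- nrow(cen)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  w <- sqrt(rowSums((cen[pairs[, 1], , drop = FALSE] -
                       cen[pairs[, 2], , drop = FALSE])^2))
  a <- pmin(ids[pairs[, 1]], ids[pairs[, 2]])
  b <- pmax(ids[pairs[, 1]], ids[pairs[, 2]])
  ord <- order(w, a, b)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  keep <- logical(length(w))
  taken <- 0L
  for (e in ord) {
    ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  data.frame(a = a[keep], b = b[keep], weight = w[keep])
}

#' Divide the trajectory tree into branches
#'
#' Runs Louvain community detection on the MST with edge affinity equal to the
#' inverse edge weight, so closely spaced clusters bind into the same branch
#' and long edges become natural branch boundaries. Branch labels are
#' contiguous from 1, numbered by the smallest cluster id they contain.
#'
#' @param state a `cyto_state` with a built tree.
#' @param resolution Louvain resolution (larger values give more branches).
#' @param seed integer seed (the backend is deterministic for trees; the seed
#'   is fixed and logged for reproducibility).
#' @return The state with per-node `branch_labels` on the tree and cluster
#'   table.
#' @export
detect_branches <- function(state, resolution = 1.0, seed = 42) {
  stopifnot(inherits(state, "cyto_state"))
  require_stage(state, "tree")
  tr <- state$tree
  nodes <- tr$nodes
  state <- clear_from(state, "branches")
  if (length(nodes) == 1L) {
    labels <- stats::setNames(1L, as.character(nodes))
  } else {
    eps <- 1e-12
    aff <- 1 / pmax(tr$edges$weight, eps)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(tr$edges$a), to = as.character(tr$edges$b)),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes)))
    comm <- withr::with_seed(seed,
      igraph::cluster_louvain(g, weights = aff, resolution = resolution))
    memb <- igraph::membership(comm)
    # relabel contiguously, ordered by smallest member cluster id
    first <- tapply(nodes[match(names(memb), as.character(nodes))], memb, min)
    newid <- rank(first, ties.method = "first")
    labels <- stats::setNames(as.integer(newid[as.character(memb)]), names(memb))
    labels <- labels[as.character(nodes)]
  }
  state$tree$branch_labels <- labels
  state$cluster_table$branch_labels <- labels
  add_log(state, "detect_branches",
          list(resolution = resolution, seed = seed,
               n_branches = length(unique(labels))))
}

#' Differentially expressed markers per branch
#'
#' For every branch and marker, compares the cells of the branch against all
#' other clustered cells with a pooled-variance two-sample t test and adjusts
#' p values across all (branch, marker) pairs with Benjamini-Hochberg.
#' Branches with fewer than 2 cells are skipped with a warning record.
#'
#' @param state a `cyto_state` with detected branches.
#' @return A data.frame with columns `branch`, `marker`, `effect` (mean in
#'   branch minus mean in rest), `statistic`, `p_raw`, `p_adj`, with skipped
#'   branches in attribute `"skipped"`.
#' @export
diff_markers <- function(state) {
  stopifnot(inherits(state, "cyto_state"))
  require_stage(state, "branches")
  branch_of_cluster <- state$tree$branch_labels
  cell_branch <- branch_of_cluster[as.character(state$cluster_labels)]
  x <- state$events$values
  branches <- sort(unique(cell_branch))
  if (length(branches) < 2)
    stop_ct("differential markers need at least 2 branches")
  res <- list(); skipped <- integer()
  for (b in branches) {
    inb <- cell_branch == b
    n1 <- sum(inb); n2 <- sum(!inb)
    if (n1 < 2 || n2 < 2) {
      warning("branch ", b, " has fewer than 2 cells on one side; skipped",
              call. = FALSE)
      skipped <- c(skipped, b)
      next
    }
    m1 <- colMeans(x[inb, , drop = FALSE])
    m2 <- colMeans(x[!inb, , drop = FALSE])
    v1 <- apply(x[inb, , drop = FALSE], 2, stats::var)
    v2 <- apply(x[!inb, , drop = FALSE], 2, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tt <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
    res[[length(res) + 1]] <- data.frame(
      branch = b, marker = colnames(x), effect = m1 - m2,
      statistic = tt, p_raw = p, row.names = NULL)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(branch = integer(), marker = character(),
                      effect = numeric(), statistic = numeric(),
                      p_raw = numeric(), p_adj = numeric())
  } else {
    out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
    out <- out[order(out$p_adj, out$p_raw), ]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}
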