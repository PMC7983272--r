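#' Workflow state container
#'
#' `cyto_state` carries the expression matrix and every intermediate result of
#' the trajectory workflow — cluster labels, per-cell embeddings, the cluster
#' centroid table, the MST trajectory, the KNN cell graph, pseudotime and walk
#' results — together with an append-only log of the steps run. Stages are
#' strictly ordered: each stage function checks its prerequisites and clears
#' every downstream result it invalidates, so a state object is always
#' internally consistent.
#'
#' @param events a [cyto_events()] object (the clean, transformed matrix).
#' @param markers markers to analyse; default all. Unknown names raise an
#'   error naming them.
#' @return An object of class `cyto_state`.
#' @export
create_state <- function(events, markers = NULL) {
  stopifnot(inherits(events, "cyto_events"))
  if (nrow(events$values) < 2L)
    stop_ct("at least 2 cells are required; a trajectory is undefined for one cell")
  markers <- markers %||% marker_names(events)
  unknown <- setdiff(markers, marker_names(events))
  if (length(unknown))
    stop_ct("unknown marker(s): ", paste(unknown, collapse = ", "))
  ev <- cyto_events(events$values[, markers, drop = FALSE],
                    sample_labels = events$sample_labels)
  st <- structure(list(
    events = ev,
    cluster_labels = NULL,   # per-cell integer in 1..K
    kept_mask = NULL,        # per-cell logical after cluster downsampling
    embeddings = list(),     # per-cell coordinate matrices over kept cells
    cluster_table = NULL,    # centroids (expression + embeddings) and branches
    tree = NULL,             # MST over cluster centroids
    cell_graph = NULL,       # KNN graph over kept cells
    D = NULL,                # per-cell mean shortest distance to roots
    pseudotime = NULL,       # per-cell value in [0,1]
    root_flags = rep(FALSE, nrow(ev$values)),
    leaf_flags = rep(FALSE, nrow(ev$values)),
    walk = NULL,             # walk counts + intermediate flags
    log = list()
  ), class = "cyto_state")
  add_log(st, "create_state",
          list(n_cells = nrow(ev$values), markers = markers))
}

add_log <- function(state, step, params = list()) {
  state$log <- c(state$log, list(log_entry(step, params)))
  state
}

n_cells <- function(state) nrow(state$events$values)

state_cell_ids <- function(state) rownames(state$events$values)

require_stage <- function(state, what) {
  ok <- switch(what,
    clusters = !is.null(state$cluster_labels),
    tree = !is.null(state$tree),
    branches = !is.null(state$tree) && !is.null(state$tree$branch_labels),
    graph = !is.null(state$cell_graph),
    roots = any(state$root_flags),
    pseudotime = !is.null(state$pseudotime),
    leaves = any(state$leaf_flags),
    stop_ct("internal: unknown stage ", what))
  if (!ok) {
    hint <- switch(what,
      clusters = "run run_cluster() first",
      tree = "run build_tree() first",
      branches = "run detect_branches() first",
      graph = "run build_knn() first",
      roots = "define root cells with def_root_cells() first",
      pseudotime = "run run_pseudotime() first",
      leaves = "define leaf cells with def_leaf_cells() first")
    stop_ct("stage '", what, "' is not available: ", hint)
  }
  invisible(TRUE)
}

# Downstream invalidation. Re-running a stage replaces its results and clears
# everything below it:
#   cluster -> {kept_mask, embeddings, cluster_table, tree -> branches,
#               cell_graph -> ...}
#   cell_graph / roots -> pseudotime -> {leaves, walk}
clear_from <- function(state, stage) {
  lvl <- match.arg(stage, c("cluster", "downsample", "dimred", "tree",
                            "branches", "graph", "roots", "pseudotime",
                            "leaves", "walk"))
  clear_pt <- function(s) {
    s$D <- NULL; s$pseudotime <- NULL
    s$leaf_flags <- rep(FALSE, n_cells(s)); s$walk <- NULL
    s
  }
  if (lvl == "cluster") {
    state$cluster_labels <- NULL; state$kept_mask <- NULL
    state$embeddings <- list(); state$cluster_table <- NULL
    state$tree <- NULL; state$cell_graph <- NULL
    state$root_flags <- rep(FALSE, n_cells(state))
    state <- clear_pt(state)
  } else if (lvl == "downsample") {
    state$kept_mask <- NULL; state$embeddings <- list()
    if (!is.null(state$cluster_table)) state$cluster_table$centroid_embedding <- list()
    state$tree <- NULL; state$cell_graph <- NULL
    state <- clear_pt(state)
  } else if (lvl == "dimred") {
    state$tree <- NULL; state$cell_graph <- NULL
    state <- clear_pt(state)
  } else if (lvl == "tree") {
    state$tree <- NULL
  } else if (lvl == "branches") {
    if (!is.null(state$tree)) state$tree$branch_labels <- NULL
    if (!is.null(state$cluster_table)) state$cluster_table$branch_labels <- NULL
  } else if (lvl == "graph") {
    state$cell_graph <- NULL
    state <- clear_pt(state)
  } else if (lvl %in% c("roots", "pseudotime")) {
    state <- clear_pt(state)
  } else if (lvl == "leaves") {
    state$leaf_flags <- rep(FALSE, n_cells(state)); state$walk <- NULL
  } else if (lvl == "walk") {
    state$walk <- NULL
  }
  state
}

#' @export
print.cyto_state <- function(x, ...) {
  cat(format(summary(x)), sep = "\n")
  invisible(x)
}

#' Summarize a workflow state
#'
#' Reports the cell and marker counts, which workflow stages are populated
#' (clusters, embeddings, tree, pseudotime, walk) and the step log.
#'
#' @param object a `cyto_state`.
#' @param ... unused.
#' @return A `summary.cyto_state` character description (printed by default).
#' @export
summary.cyto_state <- function(object, ...) {
  s <- object
  lines <- c(
    sprintf("cyto_state: %d cells x %d markers (%d sample(s))",
            n_cells(s), ncol(s$events$values),
            length(unique(s$events$sample_labels))),
    sprintf("  clusters:    %s", if (is.null(s$cluster_labels)) "<empty>"
            else sprintf("%d clusters", length(unique(s$cluster_labels)))),
    sprintf("  kept cells:  %s", if (is.null(s$kept_mask)) "<all (no downsampling)>"
            else sprintf("%d of %d", sum(s$kept_mask), n_cells(s))),
    sprintf("  embeddings:  %s", if (length(s$embeddings) == 0) "<empty>"
            else paste(names(s$embeddings), collapse = ", ")),
    sprintf("  tree:        %s", if (is.null(s$tree)) "<empty>"
            else sprintf("%d nodes, %d edges, space=%s%s",
                         length(s$tree$nodes), nrow(s$tree$edges),
                         s$tree$space_used,
                         if (is.null(s$tree$branch_labels)) "" else
                           sprintf(", %d branches",
                                   length(unique(s$tree$branch_labels))))),
    sprintf("  cell graph:  %s", if (is.null(s$cell_graph)) "<empty>"
            else sprintf("%d nodes, %d edges, k=%d%s",
                         length(s$cell_graph$ids), nrow(s$cell_graph$edges),
                         s$cell_graph$k,
                         if (is.null(s$cell_graph$directed)) "" else " (oriented)")),
    sprintf("  roots/leaves: %d / %d", sum(s$root_flags), sum(s$leaf_flags)),
    sprintf("  pseudotime:  %s", if (is.null(s$pseudotime)) "<empty>"
            else sprintf("[%.3f, %.3f] over %d cells",
                         min(s$pseudotime, na.rm = TRUE),
                         max(s$pseudotime, na.rm = TRUE),
                         sum(!is.na(s$pseudotime)))),
    sprintf("  walk:        %s", if (is.null(s$walk)) "<empty>"
            else sprintf("%d paths, %d intermediate cells",
                         s$walk$n_paths, sum(s$walk$intermediate))),
    "log:",
    vapply(s$log, function(e) sprintf("  - %s [%s]", e$step, e$time), character(1))
  )
  structure(lines, class = "summary.cyto_state")
}

#' @export
print.summary.cyto_state <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' @export
format.summary.cyto_state <- function(x, ...) unclass(x)

kept_indices <- function(state) {
  if (is.null(state$kept_mask)) seq_len(n_cells(state)) else which(state$kept_mask)
}
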