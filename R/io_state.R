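# Plain-text serialization of a cyto_state to a directory:
#   matrix.csv, meta.csv, clusters.csv, embeddings/<name>.csv,
#   tree.json, graph.json, pseudotime.csv, log.json
# Readable diffs beat an opaque binary for a pipeline whose runs are compared.

#' Save a workflow state to a directory
#'
#' Writes every populated field as CSV/JSON so the state round-trips through
#' [load_state()] and runs can be diffed file by file.
#'
#' @param state a `cyto_state`.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
save_state <- function(state, dir) {
  stopifnot(inherits(state, "cyto_state"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- state_cell_ids(state)
  utils::write.csv(data.frame(cell_id = ids, state$events$values,
                              check.names = FALSE),
                   file.path(dir, "matrix.csv"), row.names = FALSE)
  meta <- data.frame(cell_id = ids, sample = state$events$sample_labels)
  if (!is.null(state$kept_mask)) meta$kept <- state$kept_mask
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  if (!is.null(state$cluster_labels))
    utils::write.csv(data.frame(cell_id = ids, cluster = state$cluster_labels),
                     file.path(dir, "clusters.csv"), row.names = FALSE)
  if (length(state$embeddings)) {
    dir.create(file.path(dir, "embeddings"), showWarnings = FALSE)
    for (nm in names(state$embeddings))
      utils::write.csv(data.frame(cell_id = rownames(state$embeddings[[nm]]),
                                  state$embeddings[[nm]], check.names = FALSE),
                       file.path(dir, "embeddings", paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(state$tree)) {
    tr <- state$tree
    nodes <- lapply(seq_along(tr$nodes), function(i) {
      nd <- list(id = tr$nodes[i],
                 centroid = unname(tr$centroids[i, ]))
      if (!is.null(tr$branch_labels)) nd$branch <- unname(tr$branch_labels[i])
      nd
    })
    edges <- lapply(seq_len(nrow(tr$edges)), function(e)
      list(a = tr$edges$a[e], b = tr$edges$b[e], weight = tr$edges$weight[e]))
    jsonlite::write_json(list(nodes = nodes, edges = edges,
                              space_used = tr$space_used),
                         file.path(dir, "tree.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(state$cell_graph)) {
    cg <- state$cell_graph
    out <- list(ids = cg$ids, k = cg$k, space = cg$space,
                edges = cg$edges)
    if (!is.null(cg$directed)) out$directed <- cg$directed
    jsonlite::write_json(out, file.path(dir, "graph.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  if (!is.null(state$pseudotime)) {
    pt <- data.frame(cell_id = ids,
                     D = unname(state$D[ids]),
                     pseudotime = unname(state$pseudotime[ids]),
                     is_root = state$root_flags,
                     is_leaf = state$leaf_flags)
    if (!is.null(state$walk)) {
      pt$walk_count <- unname(state$walk$counts[ids])
      pt$is_intermediate <- unname(state$walk$intermediate[ids])
    }
    utils::write.csv(pt, file.path(dir, "pseudotime.csv"), row.names = FALSE)
  }
  jsonlite::write_json(state$log, file.path(dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a workflow state saved by [save_state()]
#'
#' @param dir directory written by [save_state()].
#' @return The reconstructed `cyto_state`.
#' @export
load_state <- function(dir) {
  if (!file.exists(file.path(dir, "matrix.csv")))
    stop_ct("no saved state in ", dir)
  mat <- utils::read.csv(file.path(dir, "matrix.csv"), check.names = FALSE)
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  ids <- as.character(mat$cell_id)
  values <- as.matrix(mat[, -1, drop = FALSE])
  ev <- cyto_events(values, sample_labels = as.character(meta$sample),
                    cell_ids = ids)
  state <- create_state(ev)
  state$log <- list()
  if ("kept" %in% names(meta)) state$kept_mask <- as.logical(meta$kept)
  cl_path <- file.path(dir, "clusters.csv")
  if (file.exists(cl_path)) {
    cl <- utils::read.csv(cl_path)
    state$cluster_labels <- as.integer(cl$cluster[match(ids, cl$cell_id)])
    state <- cluster_coordinates(state, "expression")
  }
  emb_dir <- file.path(dir, "embeddings")
  if (dir.exists(emb_dir)) {
    for (f in list.files(emb_dir, pattern = "\\.csv$")) {
      df <- utils::read.csv(file.path(emb_dir, f), check.names = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- as.character(df$cell_id)
      state$embeddings[[sub("\\.csv$", "", f)]] <- m
    }
  }
  tr_path <- file.path(dir, "tree.json")
  if (file.exists(tr_path)) {
    tj <- jsonlite::read_json(tr_path, simplifyVector = TRUE)
    cen <- do.call(rbind, tj$nodes$centroid)
    rownames(cen) <- as.character(tj$nodes$id)
    state$tree <- list(nodes = tj$nodes$id,
                       edges = as.data.frame(tj$edges),
                       branch_labels = if ("branch" %in% names(tj$nodes))
                         stats::setNames(tj$nodes$branch, tj$nodes$id) else NULL,
                       centroids = cen,
                       space_used = tj$space_used)
    if (!is.null(state$tree$branch_labels) && !is.null(state$cluster_table))
      state$cluster_table$branch_labels <- state$tree$branch_labels
  }
  g_path <- file.path(dir, "graph.json")
  if (file.exists(g_path)) {
    gj <- jsonlite::read_json(g_path, simplifyVector = TRUE)
    state$cell_graph <- list(ids = gj$ids, edges = as.data.frame(gj$edges),
                             k = as.integer(gj$k), space = gj$space,
                             directed = if (!is.null(gj$directed))
                               as.data.frame(gj$directed) else NULL)
  }
  pt_path <- file.path(dir, "pseudotime.csv")
  if (file.exists(pt_path)) {
    pt <- utils::read.csv(pt_path)
    m <- match(ids, pt$cell_id)
    state$D <- stats::setNames(pt$D[m], ids)
    state$pseudotime <- stats::setNames(pt$pseudotime[m], ids)
    state$root_flags <- as.logical(pt$is_root[m])
    state$leaf_flags <- as.logical(pt$is_leaf[m])
    if ("walk_count" %in% names(pt)) {
      state$walk <- list(
        counts = stats::setNames(as.integer(pt$walk_count[m]), ids),
        intermediate = stats::setNames(as.logical(pt$is_intermediate[m]), ids),
        n_paths = NA_integer_, total_path_nodes = NA_integer_,
        skipped = list(), params = list())
    }
  }
  log_path <- file.path(dir, "log.json")
  if (file.exists(log_path))
    state$log <- jsonlite::read_json(log_path, simplifyVector = FALSE)
  state
}
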