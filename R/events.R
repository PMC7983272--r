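#' Cells-by-markers event container
#'
#' `cyto_events` is the basic data container of the package: a numeric matrix
#' of transformed marker intensities (rows = cells, columns = markers) together
#' with unique cell identifiers and a per-cell sample label (for example the
#' time point or stage a cell was collected at).
#'
#' @param values numeric matrix, cells in rows, markers in columns.
#' @param sample_labels character vector of per-cell sample labels, recycled if
#'   length one. Defaults to `"S1"`.
#' @param cell_ids unique cell identifiers; defaults to rownames of `values` or
#'   `cell_<i>`.
#' @param marker_names marker names; defaults to colnames of `values`.
#' @return An object of class `cyto_events`.
#' @export
cyto_events <- function(values, sample_labels = NULL, cell_ids = NULL,
                        marker_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_ct("event matrix must have at least one cell and one marker")
  if (anyNA(values) || any(!is.finite(values)))
    stop_ct("event matrix contains missing or non-finite values")
  cell_ids <- cell_ids %||% rownames(values) %||%
    sprintf("cell_%05d", seq_len(nrow(values)))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(values))
    stop_ct("cell_ids length does not match the number of rows")
  if (anyDuplicated(cell_ids))
    stop_ct("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  marker_names <- marker_names %||% colnames(values) %||%
    sprintf("M%02d", seq_len(ncol(values)))
  marker_names <- as.character(marker_names)
  if (length(marker_names) != ncol(values))
    stop_ct("marker_names length does not match the number of columns")
  if (anyDuplicated(marker_names))
    stop_ct("duplicate marker names: ", paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "))
  sample_labels <- sample_labels %||% "S1"
  if (length(sample_labels) == 1L) sample_labels <- rep(sample_labels, nrow(values))
  sample_labels <- as.character(sample_labels)
  if (length(sample_labels) != nrow(values))
    stop_ct("sample_labels length does not match the number of cells")
  dimnames(values) <- list(cell_ids, marker_names)
  structure(list(values = values, sample_labels = sample_labels),
            class = "cyto_events")
}

#' @export
print.cyto_events <- function(x, ...) {
  cat(sprintf("cyto_events: %d cells x %d markers (%d sample(s))\n",
              nrow(x$values), ncol(x$values), length(unique(x$sample_labels))))
  cat("markers:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cyto_events <- function(x) dim(x$values)

marker_names <- function(x) colnames(x$values)
cell_ids <- function(x) rownames(x$values)

#' Apply spillover compensation
#'
#' Corrects fluorescence spillover between detector channels. For the channels
#' named by the spillover matrix `S` (rows = detectors, columns =
#' fluorochromes), the compensated signal `X'` solves `X' %*% S = X`, i.e.
#' `X' = X %*% solve(S)`. Channels not covered by `S` pass through unchanged.
#'
#' @param events numeric matrix (cells x channels) with column names, or a
#'   `cyto_events` object.
#' @param spillover square numeric matrix with identical row/column names that
#'   are a subset of the event channel names. Diagonal entries must be 1.
#' @return Compensated object of the same type as `events`.
#' @export
compensate <- function(events, spillover) {
  if (inherits(events, "cyto_events")) {
    events$values <- compensate(events$values, spillover)
    return(events)
  }
  x <- as.matrix(events)
  s <- as.matrix(spillover)
  if (nrow(s) != ncol(s)) stop_ct("spillover matrix must be square")
  chan <- colnames(s) %||% rownames(s)
  if (is.null(chan)) stop_ct("spillover matrix must carry channel names")
  missing <- setdiff(chan, colnames(x))
  if (length(missing))
    stop_ct("spillover channels not present in events: ",
            paste(missing, collapse = ", "))
  inv <- tryCatch(solve(s), error = function(e)
    stop_ct("spillover matrix is singular and cannot be inverted"))
  if (any(!is.finite(inv))) stop_ct("spillover matrix is singular and cannot be inverted")
  x[, chan] <- x[, chan, drop = FALSE] %*% inv
  x
}

#' Transform marker intensities
#'
#' Element-wise variance-stabilizing transform. `arcsinh` computes
#' `asinh(x / cofactor)` (cofactor 5 is the mass-cytometry convention;
#' 150 is common for fluorescence data); `log10` computes
#' `log10(pmax(x, 0) + 1)`; `none` returns the input unchanged.
#'
#' @param events numeric matrix or `cyto_events`.
#' @param method one of `"arcsinh"`, `"log10"`, `"none"`.
#' @param cofactor positive scaling constant for `arcsinh`.
#' @return Transformed object of the same type as `events`.
#' @export
transform_events <- function(events, method = c("arcsinh", "log10", "none"),
                             cofactor = 5) {
  method <- match.arg(method)
  if (inherits(events, "cyto_events")) {
    events$values <- transform_events(events$values, method, cofactor)
    return(events)
  }
  x <- as.matrix(events)
  switch(method,
    arcsinh = {
      if (!is.numeric(cofactor) || cofactor <= 0) stop_ct("cofactor must be > 0")
      asinh(x / cofactor)
    },
    log10 = log10(pmax(x, 0) + 1),
    none = x)
}

#' Rectangular gate specification
#'
#' An axis-aligned closed-interval gate on one channel. Cells are kept when
#' `lower <= value <= upper`.
#'
#' @param channel channel (marker) name.
#' @param lower,upper numeric bounds; `-Inf`/`Inf` leave a side unbounded.
#' @return A `cyto_gate` object.
#' @export
gate <- function(channel, lower = -Inf, upper = Inf) {
  stopifnot(is.character(channel), length(channel) == 1L)
  if (is.finite(lower) && is.finite(upper) && !(lower < upper))
    stop_ct("gate on ", channel, ": lower bound must be < upper bound")
  structure(list(channel = channel, lower = lower, upper = upper),
            class = "cyto_gate")
}

#' Apply rectangular gates
#'
#' Returns the logical row mask of cells inside *all* gates (intersection).
#' Bounds are closed intervals; an empty gate list keeps every cell.
#'
#' @param events numeric matrix with column names, or `cyto_events`.
#' @param gates list of [gate()] specifications.
#' @return Logical vector, one entry per cell.
#' @export
apply_gates <- function(events, gates) {
  x <- if (inherits(events, "cyto_events")) events$values else as.matrix(events)
  mask <- rep(TRUE, nrow(x))
  for (g in gates) {
    if (!inherits(g, "cyto_gate")) stop_ct("gates must be built with gate()")
    if (!g$channel %in% colnames(x))
      stop_ct("gate channel not found: ", g$channel)
    v <- x[, g$channel]
    mask <- mask & v >= g$lower & v <= g$upper
  }
  mask
}

#' Subset a cyto_events object by a row mask or indices
#' @param events a `cyto_events` object.
#' @param i logical mask or index vector over cells.
#' @return The subsetted `cyto_events`.
#' @export
subset_events <- function(events, i) {
  cyto_events(events$values[i, , drop = FALSE],
              sample_labels = events$sample_labels[i])
}

#' Merge samples with fixed-size downsampling
#'
#' From each sample, draws `min(n_per_sample, n_cells)` cells uniformly
#' without replacement and concatenates the draws in sample order, keeping the
#' markers shared by every sample (in the order of the first sample). The
#' per-cell draw is keyed on `(seed, sample label, cell id)`, so neither the
#' order of the samples nor the order of rows within a sample changes the
#' selection. Mirrors the common time-course design of extracting a fixed
#' number of cells (e.g. 2,000) per time point before merging.
#'
#' @param samples list of `cyto_events` objects.
#' @param n_per_sample positive integer, cells to draw per sample.
#' @param seed integer seed for the draw.
#' @return A merged `cyto_events` object.
#' @export
merge_samples <- function(samples, n_per_sample = 2000, seed = 42) {
  stopifnot(length(samples) >= 1L, n_per_sample >= 1)
  if (!all(vapply(samples, inherits, logical(1), "cyto_events")))
    stop_ct("samples must be a list of cyto_events objects")
  shared <- Reduce(intersect, lapply(samples, marker_names))
  if (length(shared) == 0L) stop_ct("samples share no markers")
  shared <- intersect(marker_names(samples[[1]]), shared)  # first-sample order
  picks <- lapply(samples, function(s) {
    ids <- cell_ids(s)
    pr <- cell_priority(paste(s$sample_labels, ids, sep = ":"), seed)
    keep <- order(pr)[seq_len(min(n_per_sample, length(ids)))]
    sort(keep)
  })
  vals <- do.call(rbind, Map(function(s, k) s$values[k, shared, drop = FALSE],
                             samples, picks))
  labs <- unlist(Map(function(s, k) s$sample_labels[k], samples, picks),
                 use.names = FALSE)
  ids <- rownames(vals)
  if (anyDuplicated(ids))
    ids <- paste(labs, ids, sep = ":")
  cyto_events(vals, sample_labels = labs, cell_ids = ids)
}

#' Install an externally batch-corrected matrix
#'
#' Batch correction (e.g. ComBat from the sva package) is delegated to
#' external tools: run the correction on `events$values` outside the package
#' and hand the corrected matrix back here. Dimensions and dimnames must match.
#'
#' @param events a `cyto_events` object.
#' @param corrected numeric matrix of identical shape and dimnames.
#' @return `events` with the corrected values installed.
#' @export
set_corrected_values <- function(events, corrected) {
  corrected <- as.matrix(corrected)
  if (!identical(dim(corrected), dim(events$values)))
    stop_ct("corrected matrix shape does not match")
  if (!identical(rownames(corrected), rownames(events$values)) ||
      !identical(colnames(corrected), colnames(events$values)))
    stop_ct("corrected matrix dimnames do not match")
  events$values <- corrected
  events
}

#' Read a cells-by-markers table from CSV/TSV
#'
#' The header row holds marker names; an optional id column (default
#' `cell_id`) holds unique cell identifiers and an optional `sample` column
#' holds per-cell sample labels.
#'
#' @param path file path; the separator is inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param sample_label label to assign when the file has no `sample` column.
#' @param id_column name of the id column, if present.
#' @return A `cyto_events` object.
#' @export
read_events <- function(path, sample_label = NULL, id_column = "cell_id") {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- NULL
  if (id_column %in% names(df)) {
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  labs <- NULL
  if ("sample" %in% names(df)) {
    labs <- as.character(df[["sample"]])
    df[["sample"]] <- NULL
  }
  cyto_events(as.matrix(df), sample_labels = labs %||% sample_label %||% basename(path),
              cell_ids = ids)
}

#' Write a cyto_events object to CSV
#'
#' Writes the matrix with a leading `cell_id` column plus a sidecar metadata
#' file holding the per-cell sample label.
#'
#' @param events a `cyto_events` object.
#' @param path output CSV path for the matrix.
#' @param meta_path output CSV path for the metadata; default replaces the
#'   extension with `_meta.csv`.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path, meta_path = NULL) {
  df <- data.frame(cell_id = cell_ids(events), events$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta_path <- meta_path %||% sub("\\.csv$", "_meta.csv", path)
  utils::write.csv(data.frame(cell_id = cell_ids(events),
                              sample = events$sample_labels),
                   meta_path, row.names = FALSE)
  invisible(path)
}
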