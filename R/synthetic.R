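#' Segment topologies for synthetic branching data
#'
#' A topology is a rooted tree over *segments*, given as a data.frame with
#' columns `parent` and `child`; the root segment appears as a child of `NA`.
#' `star_topology(m)` builds a root segment with `m` arm segments hanging off
#' it — the classic multi-branch differentiation layout.
#'
#' @param n_arms number of arm segments.
#' @return A data.frame topology.
#' @export
star_topology <- function(n_arms = 3) {
  data.frame(parent = c(NA, rep("root", n_arms)),
             child = c("root", paste0("arm", seq_len(n_arms))),
             stringsAsFactors = FALSE)
}

#' Linear chain topology of `n_segments` segments.
#' @param n_segments number of consecutive segments.
#' @return A data.frame topology.
#' @export
chain_topology <- function(n_segments = 1) {
  segs <- paste0("seg", seq_len(n_segments))
  data.frame(parent = c(NA, segs[-n_segments]), child = segs,
             stringsAsFactors = FALSE)
}

validate_topology <- function(topology) {
  stopifnot(is.data.frame(topology), all(c("parent", "child") %in% names(topology)))
  segs <- topology$child
  if (anyDuplicated(segs)) stop_ct("topology: duplicate segment ids")
  roots <- segs[is.na(topology$parent)]
  if (length(roots) != 1) stop_ct("topology must have exactly one root segment")
  unknown <- setdiff(stats::na.omit(topology$parent), segs)
  if (length(unknown))
    stop_ct("topology: unknown parent segment(s): ", paste(unknown, collapse = ", "))
  # depth computation doubles as the cycle check
  depth <- stats::setNames(rep(NA_real_, length(segs)), segs)
  depth[roots] <- 0
  for (pass in seq_along(segs)) {
    for (i in seq_along(segs)) {
      p <- topology$parent[i]
      if (!is.na(p) && !is.na(depth[p])) depth[segs[i]] <- depth[p] + 1
    }
    if (!anyNA(depth)) break
  }
  if (anyNA(depth)) stop_ct("topology contains a cycle or unreachable segment")
  list(segments = segs, root = roots, depth = depth)
}

#' Simulate branching cytometry-like data with known ground truth
#'
#' Cells are placed uniformly along the segments of a rooted tree. Each
#' segment carries a linear marker program: a cell at position `u` in segment
#' `s` has mean expression `start_s + u * (end_s - start_s)`, and child
#' segments start where their parent ends (continuity). Observed values add
#' independent Gaussian noise. The true pseudotime of a cell is its distance
#' from the root-segment start along the tree (segments have unit length),
#' normalized by the maximum root-to-leaf depth so the deepest leaf tip sits
#' at 1.
#'
#' By default segment programs are drawn once from the seed: the root program
#' ramps from the origin along a random unit direction, and every child
#' continues from its parent's end along a fresh random direction, so
#' different arms separate in marker space. Pass `programs` (list with
#' `start` and `end`, segments x markers matrices) to fix the programs
#' explicitly.
#'
#' @param topology a topology data.frame (see [star_topology()]).
#' @param n_per_segment cells per segment (scalar or named per segment).
#' @param n_markers number of markers (>= 2).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed; the same seed reproduces the data bit for bit.
#' @param programs optional explicit marker programs.
#' @return A list with `events` (a [cyto_events()] object, sample labels =
#'   segment ids) and `truth` (per-cell `segment`, `position` within segment,
#'   `pseudotime`, plus `programs`, `topology`, `depth`, `noise_sd`, `seed`).
#' @export
simulate_tree_data <- function(topology = star_topology(3), n_per_segment = 200,
                               n_markers = 10, noise_sd = 0.1, seed = 7,
                               programs = NULL) {
  if (n_markers < 2) stop_ct("n_markers must be >= 2")
  if (noise_sd < 0) stop_ct("noise_sd must be >= 0")
  info <- validate_topology(topology)
  segs <- info$segments
  nseg <- length(segs)
  if (length(n_per_segment) == 1L)
    n_per_segment <- stats::setNames(rep(n_per_segment, nseg), segs)
  withr::with_seed(seed, {
    if (is.null(programs)) {
      start <- matrix(0, nseg, n_markers, dimnames = list(segs, NULL))
      end <- start
      parent_dir <- stats::setNames(vector("list", nseg), segs)
      root_dir <- stats::rnorm(n_markers)
      root_dir <- root_dir / sqrt(sum(root_dir^2))
      end[info$root, ] <- root_dir
      parent_dir[[info$root]] <- root_dir
      for (p in segs[order(info$depth)]) {
        kids <- segs[!is.na(topology$parent) & topology$parent == p]
        if (!length(kids)) next
        dirs <- branch_directions(length(kids), n_markers, parent_dir[[p]])
        for (ci in seq_along(kids)) {
          s <- kids[ci]
          start[s, ] <- end[p, ]
          end[s, ] <- start[s, ] + dirs[ci, ]
          parent_dir[[s]] <- dirs[ci, ]
        }
      }
      programs <- list(start = start, end = end)
    } else {
      stopifnot(is.list(programs), all(c("start", "end") %in% names(programs)))
    }
    seg_of <- rep(segs, n_per_segment[segs])
    n <- length(seg_of)
    pos <- stats::runif(n)
    means <- programs$start[seg_of, , drop = FALSE] +
      pos * (programs$end[seg_of, , drop = FALSE] -
               programs$start[seg_of, , drop = FALSE])
    values <- means + matrix(stats::rnorm(n * n_markers, sd = noise_sd),
                             n, n_markers)
    colnames(values) <- sprintf("M%02d", seq_len(n_markers))
    max_depth <- max(info$depth) + 1
    pt <- (info$depth[seg_of] + pos) / max_depth
    ev <- cyto_events(values, sample_labels = seg_of,
                      cell_ids = sprintf("cell_%05d", seq_len(n)))
    list(events = ev,
         truth = list(segment = seg_of, position = pos,
                      pseudotime = unname(pt), programs = programs,
                      topology = topology, depth = info$depth,
                      noise_sd = noise_sd, seed = seed))
  })
}

# Unit directions for the children of one segment. A single child continues
# its parent's direction; m >= 2 siblings take maximally dispersed (simplex)
# directions, pairwise cosine -1/(m-1), in a random subspace orthogonal to the
# parent's direction — differentiation branches diverge rather than fold onto
# each other, and the noiseless cluster-level MST then reproduces the
# generating topology. Falls back to random directions when the marker space
# is too small to hold the simplex.
branch_directions <- function(m, n_markers, parent) {
  if (m == 1) return(matrix(parent, 1, n_markers))
  if (n_markers <= m) {
    dirs <- matrix(stats::rnorm(m * n_markers), m, n_markers)
    return(dirs / sqrt(rowSums(dirs^2)))
  }
  a <- matrix(stats::rnorm(n_markers * m), n_markers, m)
  a <- a - parent %o% as.vector(parent %*% a)   # orthogonal to parent
  q <- qr.Q(qr(a))[, seq_len(m), drop = FALSE]
  s <- diag(m) - 1 / m                          # centered simplex vertices
  s <- s / sqrt(rowSums(s^2))
  s %*% t(q)
}

#' Simulate a differentiation time course as separate samples
#'
#' Emulates a multi-day differentiation experiment sampled at discrete time
#' points: all cells live on one linear program of unit length, and sample
#' `t` draws its cells at positions centred at `(t - 1) * drift` (Gaussian
#' spread, clipped to [0, 1]), so later time points sit progressively further
#' along the program. With `drift = 0` all time points are exchangeable.
#'
#' @param n_timepoints number of samples (>= 2), labelled `T1..Tn`.
#' @param drift per-timepoint shift of the mean position along the program.
#' @param n_per_timepoint cells per sample.
#' @param n_markers number of markers.
#' @param noise_sd Gaussian marker noise.
#' @param position_sd spread of positions within a time point.
#' @param seed integer seed.
#' @return A list with `samples` (list of [cyto_events()]) and `truth`
#'   (per-sample true positions).
#' @export
simulate_samples_over_time <- function(n_timepoints = 5, drift = 0.2,
                                       n_per_timepoint = 500, n_markers = 10,
                                       noise_sd = 0.1, position_sd = 0.1,
                                       seed = 7) {
  if (n_timepoints < 2) stop_ct("n_timepoints must be >= 2")
  withr::with_seed(seed, {
    dir <- stats::rnorm(n_markers)
    dir <- dir / sqrt(sum(dir^2))
    samples <- list(); positions <- list()
    for (t in seq_len(n_timepoints)) {
      lab <- paste0("T", t)
      pos <- pmin(1, pmax(0, stats::rnorm(n_per_timepoint,
                                          mean = (t - 1) * drift,
                                          sd = position_sd)))
      values <- outer(pos, dir) +
        matrix(stats::rnorm(n_per_timepoint * n_markers, sd = noise_sd),
               n_per_timepoint, n_markers)
      colnames(values) <- sprintf("M%02d", seq_len(n_markers))
      samples[[lab]] <- cyto_events(values, sample_labels = lab,
                                    cell_ids = sprintf("%s_%05d", lab,
                                                       seq_len(n_per_timepoint)))
      positions[[lab]] <- pos
    }
    list(samples = samples, truth = list(positions = positions, drift = drift,
                                         direction = dir, seed = seed))
  })
}

#' Simulate well-separated Gaussian populations
#'
#' Draws `n_blobs` population centres far apart (independent normal
#' coordinates with `center_sd` much larger than `noise_sd`) and splits
#' `n_cells` as evenly as possible among them. Useful for exercising
#' clustering: with populations this separated, a sound method must recover
#' them.
#'
#' @param n_cells total number of cells.
#' @param n_blobs number of populations.
#' @param n_markers dimensionality.
#' @param center_sd spread of the population centres.
#' @param noise_sd within-population standard deviation.
#' @param seed integer seed.
#' @return A list with `events` and `truth` (per-cell population label).
#' @export
simulate_blobs <- function(n_cells = 3600, n_blobs = 36, n_markers = 10,
                           center_sd = 10, noise_sd = 1, seed = 42) {
  withr::with_seed(seed, {
    centers <- matrix(stats::rnorm(n_blobs * n_markers, sd = center_sd),
                      n_blobs, n_markers)
    sizes <- rep(n_cells %/% n_blobs, n_blobs)
    extra <- n_cells - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    blob <- rep(seq_len(n_blobs), sizes)
    values <- centers[blob, ] + matrix(stats::rnorm(n_cells * n_markers,
                                                    sd = noise_sd),
                                       n_cells, n_markers)
    colnames(values) <- sprintf("M%02d", seq_len(n_markers))
    ev <- cyto_events(values, sample_labels = "blobs",
                      cell_ids = sprintf("cell_%05d", seq_len(n_cells)))
    list(events = ev, truth = list(blob = blob, centers = centers, seed = seed))
  })
}
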