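# Inject a graph and a pseudotime field directly, so run_walk is exercised on
# exactly known topologies.
walk_state <- function(n, edges, pt, roots, leaves,
                       ids = sprintf("c%02d", seq_len(n))) {
  coords <- matrix(seq_len(n), n, 2, dimnames = list(ids, c("M1", "M2")))
  st <- create_state(cyto_events(coords))
  sids <- sort(ids)
  st$cell_graph <- list(ids = sids, edges = edges, k = NA_integer_,
                        space = "injected", directed = NULL)
  st$pseudotime <- stats::setNames(as.numeric(pt), ids)
  st$D <- st$pseudotime
  st$root_flags <- ids %in% roots
  st$leaf_flags <- ids %in% leaves
  st
}


test_that("a chain root-a-leaf counts the middle cell twice", {
  edges <- data.frame(i = c(1, 2), j = c(2, 3), weight = c(1, 1))
  st <- walk_state(3, edges, pt = c(0, 0.5, 1), roots = "c01", leaves = "c03")
  st <- orient_graph(st)
  st <- run_walk(st)
  expect_identical(unname(st$walk$counts), c(2L, 2L, 2L))
  expect_identical(unname(st$walk$intermediate), c(FALSE, TRUE, FALSE))
  # conservation: total count equals the summed node lengths of all paths
  expect_identical(sum(st$walk$counts), st$walk$total_path_nodes)
  expect_identical(st$walk$n_paths, 2L)
})

test_that("a root adjacent to its leaf yields no intermediate cells", {
  edges <- data.frame(i = 1, j = 2, weight = 1)
  st <- walk_state(2, edges, pt = c(0, 1), roots = "c01", leaves = "c02")
  st <- run_walk(st)
  expect_identical(sum(st$walk$intermediate), 0L)
  expect_identical(st$walk$n_paths, 2L)
})

test_that("the equal-weight diamond resolves deterministically by predecessor id", {
  # c01 -> {c02, c03} -> c04, all edges weight 1: both paths tie, and the
  # smallest-predecessor rule must pick c02 in both directions.
  edges <- data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4), weight = rep(1, 4))
  st <- walk_state(4, edges, pt = c(0, 0.5, 0.5, 1), roots = "c01", leaves = "c04")
  st <- orient_graph(st)
  st <- run_walk(st)
  counts <- st$walk$counts
  expect_identical(unname(counts[c("c01", "c04")]), c(2L, 2L))
  expect_identical(unname(counts["c02"]), 2L)  # tie-break winner
  expect_identical(unname(counts["c03"]), 0L)
  expect_identical(unname(st$walk$counts),
                   oracle_counts(4, st$cell_graph$directed, 1, 4))
})

test_that("unreachable root-leaf pairs are recorded and skipped", {
  edges <- data.frame(i = c(1, 3), j = c(2, 4), weight = c(1, 1))
  st <- walk_state(4, edges, pt = c(0, 1, 0, 1), roots = c("c01", "c03"),
                   leaves = c("c02", "c04"))
  st <- run_walk(st)
  expect_identical(st$walk$n_paths, 4L)       # within-component pairs walk
  expect_identical(length(st$walk$skipped), 4L)  # cross-component pairs do not
})

test_that("bottleneck cells collect the highest walk counts on a branching fixture", {
  # Ten cells: two roots converge on c04, one bottleneck chain c04-c05-c07-c08
  # carries every walk to the leaf c10; c06/c09 are costlier detours and c03
  # hangs off the main line.
  edges <- data.frame(
    i = c(1, 2, 4, 4, 5, 6, 7, 7, 8, 9, 3),
    j = c(4, 4, 5, 6, 7, 7, 8, 9, 10, 10, 4),
    weight = c(1, 1, 1, 1.5, 1, 1.5, 1, 1.5, 1, 1.5, 1))
  d <- floyd_warshall(10, edges)
  D <- colMeans(d[c(1, 2), ])
  pt <- (D - min(D)) / (max(D) - min(D))
  pt[c(1, 2)] <- 0
  st <- walk_state(10, edges, pt = pt, roots = c("c01", "c02"), leaves = "c10")
  st <- orient_graph(st)
  st <- run_walk(st)
  counts <- st$walk$counts
  # oracle agreement
  expect_identical(unname(counts),
                   oracle_counts(10, st$cell_graph$directed,
                                 c(1, 2), 10))
  # the through-cells c04 and c07 carry every path
  interior <- setdiff(names(counts), c("c01", "c02", "c10"))
  expect_true(all(counts[c("c04", "c07")] == max(counts[interior])))
  expect_identical(unname(counts[c("c03", "c06", "c09")]), c(0L, 0L, 0L))
  expect_true(all(c("c04", "c07") %in% names(which(st$walk$intermediate))))
  expect_false(any(st$walk$intermediate[c("c01", "c02", "c10")]))
})

test_that("walk counts equal exhaustive enumeration on random orientable graphs", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- 15
      # random connected graph with distinct pseudotime values
      pt <- sort(runif(n)); pt[1] <- 0
      extra <- data.frame(i = sample(n, 8, TRUE), j = sample(n, 8, TRUE))
      extra <- extra[extra$i != extra$j, ]
      edges <- rbind(data.frame(i = 1:(n - 1), j = 2:n),  # spine keeps it connected
                     extra)
      a <- pmin(edges$i, edges$j); b <- pmax(edges$i, edges$j)
      keep <- !duplicated(paste(a, b))
      edges <- data.frame(i = a[keep], j = b[keep],
                          weight = round(runif(sum(keep), 0.5, 2), 3))
      roots <- "c01"
      leaves <- sprintf("c%02d", sample(8:15, 2))
      st <- walk_state(n, edges, pt = pt, roots = roots, leaves = leaves)
      st <- orient_graph(st)
      st <- run_walk(st)
      expect_identical(unname(st$walk$counts),
                       oracle_counts(n, st$cell_graph$directed, 1,
                                     match(leaves, st$cell_graph$ids)))
    })
  }
})

test_that("each walked path contributes its node length to the count total", {
  sim <- star3_sim(n = 50)
  st <- create_state(sim$events)
  st <- run_cluster(st, "kmeans", k = 6, seed = 2)
  st <- build_knn(st, k = 5)
  st <- def_root_cells(st, clusters = st$cluster_labels[which.min(sim$truth$pseudotime)])
  st <- run_pseudotime(st)
  st <- def_leaf_cells(st, q = 0.03)
  st <- run_walk(st)
  expect_identical(sum(st$walk$counts), st$walk$total_path_nodes)
  expect_gte(st$walk$n_paths, 1L)
})
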