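test_that("FCS write/read round-trips events, channel names and spillover", {
  x <- withr::with_seed(11, matrix(abs(rnorm(15, 100, 50)), 5, 3))
  colnames(x) <- c("FSC-A", "CD34", "CD45")
  spill <- diag(3)
  spill[1, 2] <- 0.12; spill[2, 1] <- 0.05
  dimnames(spill) <- list(colnames(x), colnames(x))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(x, path, spillover = spill, marker_names = c("", "CD34-PE", ""))
  rs <- read_fcs(path)
  expect_s3_class(rs, "raw_sample")
  expect_identical(dim(rs$events), c(5L, 3L))
  expect_identical(rs$channel_names, colnames(x))
  expect_identical(rs$marker_names[2], "CD34-PE")
  expect_equal(rs$events, x, ignore_attr = TRUE, tolerance = 1e-6)  # float32
  expect_equal(rs$spillover, spill, tolerance = 1e-12)
  expect_true(all(diag(rs$spillover) == 1))
})

test_that("spillover covering a channel subset is parsed at its own size", {
  x <- matrix(runif(15, 0, 100), 5, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  spill <- matrix(c(1, 0.1, 0.2, 1), 2, 2,
                  dimnames = list(c("A", "B"), c("A", "B")))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(x, path, spillover = spill)
  rs <- read_fcs(path)
  expect_identical(dim(rs$spillover), c(2L, 2L))
  expect_identical(rownames(rs$spillover), c("A", "B"))
  expect_equal(diag(rs$spillover), c(A = 1, B = 1))
})

test_that("malformed and unsupported files raise parse errors", {
  txt <- withr::local_tempfile(fileext = ".fcs")
  writeLines("this is not a flow cytometry file", txt)
  expect_error(read_fcs(txt), "parse error")
  old <- withr::local_tempfile(fileext = ".fcs")
  con <- file(old, "wb")
  writeChar(sprintf("FCS2.0    %48s", ""), con, eos = NULL)
  close(con)
  expect_error(read_fcs(old), "unsupported FCS version")
  expect_error(read_fcs(withr::local_tempfile()), "not found")
})

test_that("log-stored integer parameters are linearized via $PnE", {
  # hand-built FCS 3.0 file: one 16-bit log-amplified channel, $PnE = 4,1,
  # $PnR = 1024, so stored x maps to 10^(4 x / 1024)
  path <- withr::local_tempfile(fileext = ".fcs")
  stored <- c(0L, 256L, 512L, 1023L)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0", "$NEXTDATA", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "I", "$MODE", "L",
          "$PAR", "1", "$TOT", "4",
          "$P1B", "16", "$P1E", "4,1", "$P1N", "LOGCH", "$P1R", "1024")
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  text_begin <- 58L
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 2L * length(stored) - 1L
  con <- file(path, "wb")
  writeChar(sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d", text_begin, text_end,
                    data_begin, data_end, 0L, 0L), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(stored, con, size = 2, endian = "little")
  close(con)
  rs <- read_fcs(path)
  expect_equal(as.vector(rs$events), 10^(4 * stored / 1024), tolerance = 1e-12)
})

test_that("compensation solves X' S = X and passes uncovered channels through", {
  # identity spillover leaves events untouched
  x <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  s <- diag(3); dimnames(s) <- list(colnames(x), colnames(x))
  expect_identical(compensate(x, s), x)
  # hand-solved single event: [110, 10] with 10% spill of A into B
  s2 <- matrix(c(1, 0, 0.1, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  out <- compensate(matrix(c(110, 10), 1, 2, dimnames = list(NULL, c("A", "B"))), s2)
  expect_equal(as.vector(out), c(110, -1), tolerance = 1e-12)
  # uncovered channel C unchanged
  x2 <- cbind(x[, c("A", "B")], C = 7)
  expect_equal(compensate(x2, s2)[, "C"], x2[, "C"])
  # errors
  sing <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(compensate(x, sing), "singular")
  bad <- s2; dimnames(bad) <- list(c("A", "Z"), c("A", "Z"))
  expect_error(compensate(x, bad), "Z")
})

test_that("compensation round-trips through the spillover matrix", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      p <- sample(2:6, 1)
      s <- diag(p) + matrix(runif(p * p, 0, 0.15), p, p) * (1 - diag(p))
      nm <- paste0("ch", seq_len(p))
      dimnames(s) <- list(nm, nm)
      x <- matrix(rnorm(10 * p, 100, 30), 10, p, dimnames = list(NULL, nm))
      expect_lt(max(abs(compensate(x, s) %*% s - x)), 1e-9)
    })
  }
})

test_that("transforms follow their closed forms", {
  x <- matrix(c(0, 5, 25), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(as.vector(transform_events(x, "arcsinh", cofactor = 5)),
               asinh(c(0, 1, 5)), tolerance = 1e-12)
  expect_identical(transform_events(x, "none"), x)
  expect_equal(as.vector(transform_events(x, "log10")),
               log10(c(0, 5, 25) + 1))
  expect_error(transform_events(x, "arcsinh", cofactor = 0), "cofactor")
  expect_error(transform_events(x, "sqrt"), "arg")
})

test_that("gating keeps the intersection of closed intervals", {
  x <- matrix(c(-1, 0.5, 2, 0, 1, 3), 3, 2, dimnames = list(NULL, c("A", "B")))
  expect_identical(apply_gates(x, list()), rep(TRUE, 3))
  m1 <- apply_gates(x, list(gate("A", 0, 1)))
  expect_identical(m1, c(FALSE, TRUE, FALSE))
  # intersection equals the AND of single-gate masks; idempotent; order-free
  g1 <- gate("A", 0, 2); g2 <- gate("B", 1, 3)
  expect_identical(apply_gates(x, list(g1, g2)),
                   apply_gates(x, list(g1)) & apply_gates(x, list(g2)))
  expect_identical(apply_gates(x, list(g1, g2)), apply_gates(x, list(g2, g1)))
  expect_identical(apply_gates(x, list(g1, g1)), apply_gates(x, list(g1)))
  # closed bounds keep boundary values
  expect_identical(apply_gates(x, list(gate("B", 0, 1))), c(TRUE, TRUE, FALSE))
  expect_error(apply_gates(x, list(gate("missing", 0, 1))), "missing")
  expect_error(gate("A", 2, 1), "lower")
})

test_that("merge_samples draws fixed-size per-sample subsets reproducibly", {
  samples <- lapply(1:3, function(i) {
    m <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
    cyto_events(m, sample_labels = paste0("T", i),
                cell_ids = sprintf("T%d_%02d", i, 1:10))
  })
  merged <- merge_samples(samples, n_per_sample = 2, seed = 5)
  expect_identical(nrow(merged$values), 6L)
  expect_identical(merged$sample_labels, rep(c("T1", "T2", "T3"), each = 2))
  # n_per_sample above every sample size concatenates everything
  all_cells <- merge_samples(samples, n_per_sample = 99, seed = 5)
  expect_identical(nrow(all_cells$values), 30L)
  # shared markers in first-sample order
  samples[[2]]$values <- samples[[2]]$values[, c("D", "B", "A")]
  shared <- merge_samples(samples, n_per_sample = 3, seed = 5)
  expect_identical(colnames(shared$values), c("A", "B", "D"))
  expect_error(merge_samples(list(samples[[1]],
    cyto_events(matrix(1:4, 2, 2, dimnames = list(NULL, c("X", "Y"))))), 2),
    "share no markers")
})

test_that("merge draws are seed-stable and sample-order independent", {
  big <- lapply(1:2, function(i) {
    m <- matrix(rnorm(1000 * 2), 1000, 2, dimnames = list(NULL, c("A", "B")))
    cyto_events(m, sample_labels = paste0("S", i),
                cell_ids = sprintf("S%d_%04d", i, 1:1000))
  })
  m1 <- merge_samples(big, 50, seed = 9)
  m2 <- merge_samples(big, 50, seed = 9)
  expect_identical(rownames(m1$values), rownames(m2$values))
  m3 <- merge_samples(big, 50, seed = 10)
  expect_false(identical(rownames(m1$values), rownames(m3$values)))
  # reversing the sample list permutes blocks but not the chosen cells
  m4 <- merge_samples(rev(big), 50, seed = 9)
  expect_setequal(rownames(m1$values), rownames(m4$values))
})
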