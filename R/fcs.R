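# Minimal FCS 3.0/3.1 reader and writer.
#
# Supported dialect: single-dataset files, list mode ($MODE/L), data types
# F (float32), D (float64) and I (unsigned integers of 8/16/32 bits), byte
# orders 1,2,3,4 (little endian) and 4,3,2,1 (big endian). Log-amplified
# integer parameters ($PnE/f1,f2 with f1 > 0) are linearized on read as
# 10^(f1 * x / $PnR) * f2 (f2 = 0 treated as 1, per common practice).

fcs_read_segment <- function(con, begin, end, what, path) {
  seek(con, begin)
  n <- end - begin + 1
  raw <- readBin(con, "raw", n = n)
  if (length(raw) < n)
    stop_ct("FCS parse error in ", basename(path), ": ", what,
            " segment truncated at offset ", begin + length(raw))
  raw
}

fcs_parse_text <- function(raw) {
  delim <- rawToChar(raw[1])
  txt <- rawToChar(raw[-1])
  # Split on the delimiter; escaped (doubled) delimiters inside values are not
  # supported in this dialect.
  parts <- strsplit(txt, delim, fixed = TRUE)[[1]]
  if (length(parts) < 2) stop_ct("FCS parse error: empty TEXT segment")
  if (length(parts) %% 2 == 1) parts <- parts[seq_len(length(parts) - 1)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(vals), keys)
}

fcs_parse_spillover <- function(value) {
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  n <- as.integer(parts[1])
  if (is.na(n) || n < 1 || length(parts) < 1 + n + n * n)
    stop_ct("FCS parse error: malformed spillover keyword")
  chan <- trimws(parts[2:(1 + n)])
  vals <- as.numeric(parts[(2 + n):(1 + n + n * n)])
  m <- matrix(vals, nrow = n, ncol = n, byrow = TRUE,
              dimnames = list(chan, chan))
  m
}

#' Read an FCS 3.0/3.1 file
#'
#' Parses the header, TEXT and DATA segments of a single-dataset FCS file and
#' returns the raw events with channel metadata. Log-stored parameters
#' ($PnE with a positive first field) are linearized. The spillover matrix is
#' populated from the `$SPILLOVER`, `SPILL` or `$SPILL` keyword when present.
#'
#' @param path path to an FCS 3.0 or 3.1 file.
#' @return A list of class `raw_sample` with elements `events` (events x
#'   channels matrix), `channel_names` ($PnN), `marker_names` ($PnS, empty
#'   string where unset), `spillover` (square matrix or NULL), `source_id`
#'   (file basename) and `keywords`.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop_ct("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 58)
  if (length(header) < 58)
    stop_ct("FCS parse error in ", basename(path),
            ": file truncated at offset ", length(header),
            " (58-byte header expected)")
  version <- rawToChar(header[1:6])
  if (!grepl("^FCS", version))
    stop_ct("FCS parse error in ", basename(path),
            ": missing FCS magic at offset 0")
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_ct("unsupported FCS version '", version,
            "': only FCS 3.0 and 3.1 are supported")
  off <- suppressWarnings(as.numeric(vapply(0:3, function(i)
    rawToChar(header[(11 + 8 * i):(18 + 8 * i)]), character(1))))
  if (anyNA(off[1:2]))
    stop_ct("FCS parse error in ", basename(path),
            ": unreadable TEXT offsets at offset 10")
  kw <- fcs_parse_text(fcs_read_segment(con, off[1], off[2], "TEXT", path))

  data_begin <- off[3]; data_end <- off[4]
  if (is.na(data_begin) || data_begin == 0)
    data_begin <- as.numeric(kw[["$BEGINDATA"]])
  if (is.na(data_end) || data_end == 0)
    data_end <- as.numeric(kw[["$ENDDATA"]])
  if (anyNA(c(data_begin, data_end)) || data_begin <= 0)
    stop_ct("FCS parse error in ", basename(path), ": DATA offsets missing")

  npar <- as.integer(kw[["$PAR"]]); ntot <- as.integer(kw[["$TOT"]])
  if (anyNA(c(npar, ntot)) || npar < 1 || ntot < 1)
    stop_ct("FCS parse error in ", basename(path), ": $PAR/$TOT missing")
  mode <- kw[["$MODE"]] %||% "L"
  if (toupper(mode) != "L") stop_ct("unsupported $MODE '", mode, "' (list mode only)")
  dtype <- toupper(kw[["$DATATYPE"]] %||% "F")
  byteord <- kw[["$BYTEORD"]] %||% "1,2,3,4"
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  bits <- vapply(seq_len(npar), function(i)
    as.integer(kw[[paste0("$P", i, "B")]] %||% "32"), integer(1))
  chn <- vapply(seq_len(npar), function(i)
    kw[[paste0("$P", i, "N")]] %||% paste0("P", i), character(1))
  stn <- vapply(seq_len(npar), function(i)
    kw[[paste0("$P", i, "S")]] %||% "", character(1))

  seek(con, data_begin)
  nvals <- npar * ntot
  if (dtype %in% c("F", "D")) {
    size <- if (dtype == "F") 4L else 8L
    vals <- readBin(con, "double", n = nvals, size = size, endian = endian)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1 || !unique(bits) %in% c(8L, 16L, 32L))
      stop_ct("unsupported $PnB layout for integer data (uniform 8/16/32 only)")
    size <- unique(bits) / 8L
    vals <- readBin(con, "integer", n = nvals, size = size,
                    signed = size == 4L, endian = endian)
    vals <- as.numeric(vals)
    if (size < 4L) vals[vals < 0] <- vals[vals < 0] + 2^bits[1]
  } else stop_ct("unsupported $DATATYPE '", dtype, "'")
  if (length(vals) < nvals)
    stop_ct("FCS parse error in ", basename(path),
            ": DATA segment truncated at offset ",
            data_begin + length(vals) * (bits[1] / 8))
  events <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE,
                   dimnames = list(NULL, chn))

  # $PnE linearization for log-amplified stored values
  for (i in seq_len(npar)) {
    pe <- kw[[paste0("$P", i, "E")]]
    if (is.null(pe)) next
    ef <- suppressWarnings(as.numeric(strsplit(pe, ",")[[1]]))
    if (length(ef) == 2 && !anyNA(ef) && ef[1] > 0) {
      r <- as.numeric(kw[[paste0("$P", i, "R")]] %||% "1024")
      f2 <- if (ef[2] == 0) 1 else ef[2]
      events[, i] <- 10^(ef[1] * events[, i] / r) * f2
    }
  }

  spill <- NULL
  for (k in c("$SPILLOVER", "SPILL", "$SPILL")) {
    if (!is.null(kw[[k]])) { spill <- fcs_parse_spillover(kw[[k]]); break }
  }
  if (!is.null(spill)) {
    unknown <- setdiff(rownames(spill), chn)
    if (length(unknown))
      stop_ct("FCS parse error: spillover names not among channels: ",
              paste(unknown, collapse = ", "))
  }
  structure(list(events = events, channel_names = chn, marker_names = stn,
                 spillover = spill, source_id = basename(path), keywords = kw),
            class = "raw_sample")
}

#' @export
print.raw_sample <- function(x, ...) {
  cat(sprintf("raw_sample '%s': %d events x %d channels%s\n", x$source_id,
              nrow(x$events), ncol(x$events),
              if (is.null(x$spillover)) "" else
                sprintf(" (spillover over %d channels)", nrow(x$spillover))))
  invisible(x)
}

#' Write a minimal FCS 3.1 file
#'
#' Writes events as little-endian float32 list-mode data with `$PnE/0,0`
#' (already linear). Intended for fixtures and interchange; values round-trip
#' through [read_fcs()] at float precision.
#'
#' @param events numeric matrix (events x channels) with column names, or a
#'   `cyto_events` object.
#' @param path output path.
#' @param spillover optional square spillover matrix with channel dimnames; is
#'   written as the `$SPILLOVER` keyword.
#' @param marker_names optional $PnS stain names.
#' @return Invisibly, `path`.
#' @export
write_fcs <- function(events, path, spillover = NULL, marker_names = NULL) {
  x <- if (inherits(events, "cyto_events")) events$values else as.matrix(events)
  if (nrow(x) > 100000) stop_ct("write_fcs supports at most 100,000 events")
  chn <- colnames(x) %||% sprintf("P%d", seq_len(ncol(x)))
  npar <- ncol(x); ntot <- nrow(x)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(npar), "$TOT", as.character(ntot))
  rng <- max(1, ceiling(max(abs(x))))
  for (i in seq_len(npar)) {
    kw <- c(kw, paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "N"), chn[i],
            paste0("$P", i, "R"), as.character(rng))
    if (!is.null(marker_names) && nzchar(marker_names[i]))
      kw <- c(kw, paste0("$P", i, "S"), marker_names[i])
  }
  if (!is.null(spillover)) {
    sn <- rownames(spillover) %||% colnames(spillover)
    sv <- paste(c(nrow(spillover), sn,
                  format(t(spillover), trim = TRUE, digits = 15)),
                collapse = ",")
    kw <- c(kw, "$SPILLOVER", sv)
  }
  # Fixed-width data offsets keep the TEXT length stable across the two passes.
  delim <- "/"
  build_text <- function(begin_data, end_data) {
    all_kw <- c(kw, "$BEGINDATA", sprintf("%010d", begin_data),
                "$ENDDATA", sprintf("%010d", end_data))
    paste0(delim, paste(all_kw, collapse = delim), delim)
  }
  text0 <- build_text(0, 0)
  text_begin <- 58L
  text_end <- text_begin + nchar(text0) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * npar * ntot - 1L
  text <- build_text(data_begin, data_end)
  stopifnot(nchar(text) == nchar(text0))
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    if (data_end <= 99999999) data_begin else 0,
                    if (data_end <= 99999999) data_end else 0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(x)), con, size = 4, endian = "little")
  invisible(path)
}

#' Convert a raw sample to a cyto_events object
#'
#' Keeps the requested channels (default: all), renaming them to their stain
#' names ($PnS) where available.
#'
#' @param sample a `raw_sample` from [read_fcs()].
#' @param channels channel names to keep; default all.
#' @param use_marker_names replace channel names by $PnS stain names where set.
#' @return A `cyto_events` object labelled with the sample's `source_id`.
#' @export
as_events <- function(sample, channels = NULL, use_marker_names = TRUE) {
  stopifnot(inherits(sample, "raw_sample"))
  channels <- channels %||% sample$channel_names
  idx <- match(channels, sample$channel_names)
  if (anyNA(idx))
    stop_ct("unknown channels: ", paste(channels[is.na(idx)], collapse = ", "))
  vals <- sample$events[, idx, drop = FALSE]
  nm <- channels
  if (use_marker_names) {
    stn <- sample$marker_names[idx]
    nm <- ifelse(nzchar(stn), stn, nm)
  }
  colnames(vals) <- nm
  label <- sub("\\.fcs$", "", sample$source_id, ignore.case = TRUE)
  cyto_events(vals, sample_labels = label,
              cell_ids = sprintf("%s:%06d", label, seq_len(nrow(vals))))
}
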