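# Plain-text sweep-train I/O.
#
# Dialect: optional '#' comment/header lines, then whitespace- or
# comma-delimited numeric columns time_s, current_pA, voltage_mV,
# sweep_index; sweeps are contiguous blocks of equal sweep_index. Header
# lines of the form "# key: value" carry metadata (cell_id, regime,
# stim_freq_hz). Units are fixed at s / pA / mV at the I/O boundary.

.header_meta <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*\\S)\\s*$", hdr))
  kv <- Filter(function(m) length(m) == 3L, kv)
  stats::setNames(
    lapply(kv, function(m) m[[3L]]),
    vapply(kv, function(m) m[[2L]], character(1))
  )
}

#' Read a sweep-train recording from a plain-text export
#'
#' Parses an ASCII sweep export: comment/header lines start with `#`,
#' data rows hold numeric columns separated by whitespace or commas.
#' Column roles default to `time` (s), `current` (pA), `voltage` (mV),
#' `sweep` (sweep index); `column_map` reassigns them by position.
#' The sampling period is inferred from the time column.
#'
#' @param path Path to the file.
#' @param column_map Named integer vector mapping roles `time`, `current`,
#'   `voltage` and (optionally) `sweep` to column positions. Without a
#'   `sweep` role the file is read as a single sweep.
#' @return A [cell_recording()] (metadata taken from `# key: value` header
#'   lines when present).
#' @export
read_ascii_recording <- function(path,
                                 column_map = c(time = 1L, current = 2L,
                                                voltage = 3L, sweep = 4L)) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  for (role in c("time", "current", "voltage")) {
    if (!role %in% names(column_map)) {
      stop(sprintf("column_map is missing required role '%s'", role), call. = FALSE)
    }
  }
  lines <- readLines(path, warn = FALSE)
  meta <- .header_meta(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0L) {
    stop(sprintf("no data rows in %s", path), call. = FALSE)
  }

  fields <- strsplit(trimws(data_lines), "[,[:space:]]+")
  nf <- lengths(fields)
  need <- max(column_map)
  bad_shape <- which(nf < need)
  if (length(bad_shape) > 0L) {
    absent <- names(column_map)[column_map > nf[bad_shape[1L]]]
    stop(sprintf(
      "%s: line %d has %d column(s); no column for role(s) %s",
      path, line_no[bad_shape[1L]], nf[bad_shape[1L]],
      paste(absent, collapse = ", ")
    ), call. = FALSE)
  }
  if (any(nf != nf[1L])) {
    i <- which(nf != nf[1L])[1L]
    stop(sprintf("%s: inconsistent column count at line %d", path, line_no[i]),
         call. = FALSE)
  }
  mat <- matrix(unlist(fields, use.names = FALSE), nrow = length(fields), byrow = TRUE)
  num <- suppressWarnings(
    matrix(as.numeric(mat[, column_map, drop = FALSE]), nrow = nrow(mat))
  )
  colnames(num) <- names(column_map)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[1L]
    stop(sprintf("%s: non-numeric value at line %d", path, line_no[bad]),
         call. = FALSE)
  }

  sweep_id <- if ("sweep" %in% names(column_map)) num[, "sweep"] else rep(1, nrow(num))
  # sweeps must be contiguous blocks
  blocks <- rle(sweep_id)
  if (anyDuplicated(blocks$values)) {
    stop(sprintf("%s: sweep indices are not contiguous", path), call. = FALSE)
  }
  idx <- split(seq_len(nrow(num)), factor(sweep_id, levels = blocks$values))
  lens <- lengths(idx)
  if (any(lens != lens[1L])) {
    stop(sprintf("%s: sweeps have inconsistent lengths (%s)", path,
                 paste(lens, collapse = ", ")), call. = FALSE)
  }
  sweeps <- lapply(idx, function(i) {
    sweep_trace(
      current = num[i, "current"],
      voltage_cmd = num[i, "voltage"],
      time = num[i, "time"] - num[i[1L], "time"]
    )
  })
  if (length(sweeps) == 1L) {
    # single-pulse file: duplicate into the minimal valid recording is wrong;
    # keep it as a bare sweep wrapped lazily by the caller.
    stop(sprintf("%s: a recording requires at least 2 sweeps; use a 'sweep' column",
                 path), call. = FALSE)
  }
  regime <- meta[["regime"]] %||% "unknown"
  if (!regime %in% c("uniform", "alternant", "unknown")) regime <- "unknown"
  cell_recording(
    sweeps,
    cell_id = meta[["cell_id"]] %||% sub("\\.[^.]*$", "", basename(path)),
    regime_label = regime,
    stimulation_frequency = as.numeric(meta[["stim_freq_hz"]] %||% NA)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording in the package's ASCII dialect
#'
#' @param rec A [cell_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_ascii <- function(rec, path) {
  stopifnot(inherits(rec, "cell_recording"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cell_id: %s", rec$cell_id),
    sprintf("# regime: %s", rec$regime_label),
    sprintf("# stim_freq_hz: %.10g", rec$stimulation_frequency),
    "# columns: time_s current_pA voltage_mV sweep_index"
  ), con)
  for (k in seq_along(rec$sweeps)) {
    s <- rec$sweeps[[k]]
    writeLines(sprintf("%.12g %.17g %.17g %d", s$time, s$current, s$voltage_cmd, k), con)
  }
  invisible(path)
}

#' Write a per-sweep feature matrix to CSV
#'
#' One row per sweep with the canonical schema: `sweep`, `peak_cap_pA`,
#' `peak_ca_pA`, `peak_tail_pA`, `q_ca_pAms`, `q_tail_pAms`, `tau_ms`,
#' `tau1_ms`, `tau2_ms`. Re-reading with [read_features_csv()] reproduces
#' the values to better than 1e-12 relative.
#'
#' @param matrix A feature matrix as returned by
#'   [extract_recording_features()] (a data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(matrix, path) {
  stopifnot(is.data.frame(matrix))
  df <- as.data.frame(lapply(matrix, function(col) {
    if (is.numeric(col)) format(col, digits = 17, scientific = FALSE, trim = TRUE) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write %s: %s", path, conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features_csv()]
#' @param path CSV path.
#' @return A data.frame with one row per sweep.
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Load every recording in a dataset directory
#'
#' Reads all `*.asc` files (lexicographic order, so the cell order is
#' deterministic). Any unreadable file aborts the load rather than
#' silently dropping cells.
#'
#' @param directory Dataset directory.
#' @param pattern File pattern (default `"\\.asc$"`).
#' @return A list of [cell_recording()] objects.
#' @export
load_dataset <- function(directory, pattern = "\\.asc$") {
  if (!dir.exists(directory)) {
    stop(sprintf("directory not found: %s", directory), call. = FALSE)
  }
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) == 0L) {
    stop(sprintf("no recordings (%s) in %s", pattern, directory), call. = FALSE)
  }
  lapply(files, function(f) {
    tryCatch(read_ascii_recording(f), error = function(e) {
      stop(sprintf("failed to read %s: %s", basename(f), conditionMessage(e)),
           call. = FALSE)
    })
  })
}
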