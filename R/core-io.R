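# Sweep Table CSV: '#'-prefixed `key=value` header lines, then a
# `time_ms,sweep_000,...` column header and data rows. UTF-8, '.' decimal,
# LF endings, samples serialized to 6 decimal places.

.required_header_keys <- c("sample_rate_hz", "kind", "condition",
                           "stim_onset_ms", "stim_duration_ms",
                           "stim_intensity_frac")
.protocol_keys <- c(.required_header_keys, "stim_iti_s", "holding_mv")

#' Write a sweep set to a Sweep Table CSV file
#'
#' @param s A [sweep_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_sweepset()]
#' @export
write_sweepset <- function(s, path) {
  stopifnot(inherits(s, "sweep_set"))
  t1 <- s$sweeps[[1]]
  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(...) writeLines(sprintf(...), con, sep = "\n")
  emit("# sample_rate_hz=%s", format(t1$rate_hz, scientific = FALSE))
  emit("# kind=%s", t1$kind)
  emit("# condition=%s", s$condition)
  emit("# stim_onset_ms=%s", format(s$protocol$onset_ms, scientific = FALSE))
  emit("# stim_duration_ms=%s", format(s$protocol$duration_ms, scientific = FALSE))
  emit("# stim_intensity_frac=%s", format(s$protocol$intensity_frac, scientific = FALSE))
  emit("# stim_iti_s=%s", format(s$protocol$iti_s, scientific = FALSE))
  if (!is.null(t1$holding_mv))
    emit("# holding_mv=%s", format(t1$holding_mv, scientific = FALSE))
  for (nm in names(s$labels))
    emit("# %s=%s", nm, paste(format(s$labels[[nm]], scientific = FALSE,
                                     trim = TRUE), collapse = ";"))
  n_sweep <- length(s$sweeps)
  emit("time_ms,%s", paste(sprintf("sweep_%03d", seq_len(n_sweep) - 1),
                           collapse = ","))
  times <- trace_times_ms(t1)
  mat <- vapply(s$sweeps, function(tr) tr$samples, numeric(length(t1)))
  mat <- cbind(times, mat)
  rows <- apply(mat, 1L, function(r) paste(sprintf("%.6f", r), collapse = ","))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Read a sweep set from a Sweep Table CSV file
#'
#' @param path Path to a file written by [write_sweepset()] (or conforming
#'   to the same format).
#' @return A [sweep_set()]. Metadata round-trips exactly; samples round-trip
#'   to 1e-6.
#' @export
read_sweepset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(diff(hdr_idx) != 1L))
    stop("header lines must be contiguous at the top of the file",
         call. = FALSE)
  meta <- list()
  for (i in hdr_idx) {
    body <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 1L)
      stop(sprintf("malformed header at line %d: '%s'", i, lines[i]),
           call. = FALSE)
    key <- substr(body, 1L, eq - 1L)
    meta[[key]] <- substr(body, eq + 1L, nchar(body))
  }
  missing <- setdiff(.required_header_keys, names(meta))
  if (length(missing))
    stop("missing required header key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!meta$condition %in% .known_conditions)
    stop("unknown condition in header: ", meta$condition, call. = FALSE)

  first_data <- length(hdr_idx) + 1L
  cols <- strsplit(lines[first_data], ",", fixed = TRUE)[[1]]
  if (cols[1] != "time_ms" || length(cols) < 2L)
    stop(sprintf("malformed column header at line %d", first_data),
         call. = FALSE)
  n_sweep <- length(cols) - 1L
  data_lines <- lines[(first_data + 1L):length(lines)]
  data_lines <- data_lines[nzchar(data_lines)]
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != n_sweep + 1L)
  if (length(bad))
    stop(sprintf("inconsistent column count at line %d",
                 first_data + bad[1]), call. = FALSE)
  mat <- matrix(as.numeric(unlist(parts, use.names = FALSE)),
                ncol = n_sweep + 1L, byrow = TRUE)
  if (anyNA(mat))
    stop("non-numeric data value in sweep table", call. = FALSE)

  rate <- as.numeric(meta$sample_rate_hz)
  holding <- if (!is.null(meta$holding_mv)) as.numeric(meta$holding_mv) else NULL
  protocol <- stimulus_protocol(
    onset_ms = as.numeric(meta$stim_onset_ms),
    duration_ms = as.numeric(meta$stim_duration_ms),
    intensity_frac = as.numeric(meta$stim_intensity_frac),
    iti_s = if (!is.null(meta$stim_iti_s)) as.numeric(meta$stim_iti_s) else 8)
  labels <- meta[setdiff(names(meta), .protocol_keys)]
  labels <- lapply(labels, function(v) {
    parts <- strsplit(v, ";", fixed = TRUE)[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) nums else v
  })
  sweeps <- lapply(seq_len(n_sweep), function(j)
    trace(mat[, j + 1L], rate_hz = rate, kind = meta$kind,
          holding_mv = holding))
  sweep_set(sweeps, protocol, condition = meta$condition, labels = labels)
}

#' Serialize an analysis result to a JSON document
#'
#' Writes one top-level JSON object per analysis result (ripplet
#' features, burst statistics, JBSI matrices, simulation summaries,
#' test results, ...), with scalars unboxed and full numeric precision.
#'
#' @param x A result object (any list-like structure of numbers,
#'   strings and vectors); classed objects are unclassed first.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_result_json <- function(x, path) {
  x <- unclass(x)
  if (!is.null(x$params)) x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
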