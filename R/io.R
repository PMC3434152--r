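#' Read and write time series as delimited text
#'
#' Plain-text dialect for exchanging signals with other tools: two commented
#' header lines `# sample_rate_hz=<float>` and `# t0_s=<float>` followed by
#' one numeric value per row. The reader also accepts two-column
#' `time,value` rows (the time column is ignored beyond a consistency
#' check); the writer always emits the single-column form. A write-then-read
#' round trip reproduces values to full stored precision (17 significant
#' digits) and the sample rate exactly.
#'
#' @param path File path.
#' @param ts A [whisk_ts()] to write.
#'
#' @return `read_timeseries` returns a [whisk_ts()]; `write_timeseries`
#'   returns `path` invisibly.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) {
    stop_invalid("%s: need two header lines and at least one data row", path)
  }
  rate <- parse_header(lines[1], "sample_rate_hz", path, 1L)
  t0 <- parse_header(lines[2], "t0_s", path, 2L)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop_invalid("%s: no data rows", path)
  ncol1 <- length(strsplit(body[1], ",", fixed = TRUE)[[1]])
  if (!ncol1 %in% c(1L, 2L)) {
    stop_invalid("%s: line 3: expected 1 or 2 columns, found %d", path, ncol1)
  }
  values <- numeric(length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(fields) != ncol1) {
      stop_invalid("%s: line %d: inconsistent column count (%d, expected %d)",
                   path, i + 2L, length(fields), ncol1)
    }
    v <- suppressWarnings(as.numeric(fields[ncol1]))
    if (is.na(v)) {
      stop_invalid("%s: line %d: non-numeric value '%s'",
                   path, i + 2L, fields[ncol1])
    }
    values[i] <- v
  }
  whisk_ts(values, rate, t0)
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, path) {
  assert_ts(ts)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# sample_rate_hz=%.17g", ts$sample_rate_hz),
               sprintf("# t0_s=%.17g", ts$t0_s),
               sprintf("%.17g", ts$values)), con)
  invisible(path)
}

parse_header <- function(line, key, path, lineno) {
  pattern <- paste0("^#\\s*", key, "\\s*=\\s*([-+0-9.eE]+)\\s*$")
  m <- regmatches(line, regexec(pattern, line))[[1]]
  if (length(m) != 2L) {
    stop_invalid("%s: line %d: expected header '# %s=<value>', got '%s'",
                 path, lineno, key, line)
  }
  v <- suppressWarnings(as.numeric(m[2]))
  if (is.na(v)) stop_invalid("%s: line %d: non-numeric %s", path, lineno, key)
  v
}
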