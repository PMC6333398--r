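#' Read and write LFP traces
#'
#' Two on-disk formats are supported:
#'
#' * `"text"` — two tab-separated columns `time_s` and `mv`, preceded by
#'   `#`-prefixed header lines of the form `# key=value`. The header must
#'   contain `fs_hz`; the time column must be uniform and consistent with
#'   it (the declared rate is cross-checked against the median time step at
#'   1e-6 relative tolerance). Round trips preserve samples to the written
#'   decimal precision.
#' * `"binary"` — a small self-describing container: ASCII magic `SLFP`,
#'   a version integer, `fs_hz`, `t0_s`, the sample count, a JSON metadata
#'   block, then little-endian 64-bit float samples. Round trips are
#'   bit-exact.
#'
#' @param path File path.
#' @param format One of `"text"` or `"binary"`.
#' @param trace An [lfp_trace()].
#' @param digits Decimal digits written per sample in text mode.
#' @return `read_trace()` returns an [lfp_trace()]; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path, format = c("binary", "text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         text = read_trace_text(path),
         binary = read_trace_binary(path))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path, format = c("binary", "text"),
                        digits = 7L) {
  stopifnot(inherits(trace, "lfp_trace"))
  format <- match.arg(format)
  switch(format,
         text = write_trace_text(trace, path, digits),
         binary = write_trace_binary(trace, path))
  invisible(path)
}

TRACE_MAGIC <- "SLFP"
TRACE_VERSION <- 1L

write_trace_binary <- function(trace, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(TRACE_MAGIC), con)
  writeBin(TRACE_VERSION, con, size = 4L, endian = "little")
  writeBin(trace$fs_hz, con, size = 8L, endian = "little")
  writeBin(trace$t0_s, con, size = 8L, endian = "little")
  writeBin(length(trace$samples), con, size = 4L, endian = "little")
  meta_json <- charToRaw(as.character(
    jsonlite::toJSON(trace$meta, auto_unbox = TRUE, null = "null")))
  writeBin(length(meta_json), con, size = 4L, endian = "little")
  writeBin(meta_json, con)
  writeBin(trace$samples, con, size = 8L, endian = "little")
}

read_trace_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, TRACE_MAGIC)) {
    stop("malformed header: bad magic at offset 0 in ", path, call. = FALSE)
  }
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (version != TRACE_VERSION) {
    stop("unsupported container version ", version, call. = FALSE)
  }
  fs_hz <- readBin(con, "double", 1L, size = 8L, endian = "little")
  t0_s <- readBin(con, "double", 1L, size = 8L, endian = "little")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  n_meta <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n_meta)),
                             simplifyVector = TRUE)
  samples <- readBin(con, "double", n, size = 8L, endian = "little")
  if (length(samples) != n) {
    stop("truncated sample block: expected ", n, " samples, got ",
         length(samples), call. = FALSE)
  }
  lfp_trace(samples, fs_hz, t0_s, as.list(meta))
}

write_trace_text <- function(trace, path, digits) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g", trace$fs_hz), con)
  writeLines(sprintf("# t0_s=%.10g", trace$t0_s), con)
  m <- trace$meta[!vapply(trace$meta, is.null, logical(1))]
  for (k in names(m)) writeLines(sprintf("# %s=%s", k, as.character(m[[k]])), con)
  t_s <- trace$t0_s + (seq_along(trace$samples) - 1) / trace$fs_hz
  fmt <- paste0("%.10g\t%.", digits, "g")
  writeLines(sprintf(fmt, t_s, trace$samples), con)
}

read_trace_text <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(diff(hdr_idx) != 1L)) {
    stop("format error: header lines must precede data (line ",
         hdr_idx[which(diff(hdr_idx) != 1L)[1] + 1L], ")", call. = FALSE)
  }
  hdr <- lines[hdr_idx]
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  if (!"fs_hz" %in% keys) {
    stop("format error: missing 'fs_hz' header in ", path, call. = FALSE)
  }
  fs_hz <- as.numeric(vals[["fs_hz"]])
  t0_s <- if ("t0_s" %in% keys) as.numeric(vals[["t0_s"]]) else 0
  data_lines <- lines[setdiff(seq_along(lines), hdr_idx)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1]
    stop("format error: expected 2 tab-separated columns at data line ",
         bad, call. = FALSE)
  }
  t_s <- as.numeric(vapply(parts, `[[`, "", 1L))
  mv <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(t_s) || anyNA(mv)) {
    stop("format error: non-numeric value at data line ",
         which(is.na(t_s) | is.na(mv))[1], call. = FALSE)
  }
  dt <- diff(t_s)
  if (length(dt)) {
    med_dt <- stats::median(dt)
    if (med_dt <= 0 || any(abs(dt - med_dt) > 1e-6 * med_dt + 1e-12)) {
      stop("format error: non-uniform time column near data line ",
           which(abs(dt - med_dt) > 1e-6 * med_dt + 1e-12)[1] + 1L,
           call. = FALSE)
    }
    fs_inferred <- 1 / med_dt
    if (abs(fs_inferred - fs_hz) > 1e-6 * fs_hz) {
      stop("format error: declared fs_hz=", fs_hz,
           " inconsistent with time column (inferred ", fs_inferred, ")",
           call. = FALSE)
    }
  }
  meta_keys <- setdiff(keys, c("fs_hz", "t0_s"))
  meta <- as.list(vals[meta_keys])
  lfp_trace(mv, fs_hz, t0_s, meta)
}
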