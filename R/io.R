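#' Write a photon stream as columnar TSV
#'
#' Three columns (`timestamp_us`, `channel`, `excitation_slot`) preceded by
#' `#`-prefixed header lines recording the alternation period (us), duty
#' cycle and acquisition duration (s).
#'
#' @param stream A `photon_stream`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_photon_tsv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# alternation_period_us: %g", attr(stream, "alternation_period") %||% 100),
    sprintf("# duty: %g", attr(stream, "duty") %||% 0.5),
    sprintf("# duration_s: %g", attr(stream, "duration") %||%
              (if (nrow(stream)) max(stream$timestamp_us) * 1e-6 else 0))), con)
  write.table(stream[, c("timestamp_us", "channel", "excitation_slot")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a photon stream
#'
#' Parses the TSV dialect written by [write_photon_tsv()], validates
#' monotonicity and channel codes (errors name the offending line) and
#' returns a classified `photon_stream`. An empty file yields an empty
#' stream with a warning.
#'
#' @param path Input file.
#' @param dialect Only `"tsv"` is supported.
#' @return A `photon_stream`.
#' @export
read_photon_stream <- function(path, dialect = "tsv") {
  if (!identical(dialect, "tsv"))
    stopf("unsupported photon-stream dialect: %s", dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(".*: *", "", m[1])) else default
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) <= 1) {
    warnf("empty photon stream: %s", path)
    empty <- data.frame(timestamp_us = numeric(0), channel = character(0))
    attr(empty, "alternation_period") <- get_hdr("alternation_period_us", 100)
    attr(empty, "duty") <- get_hdr("duty", 0.5)
    attr(empty, "duration") <- get_hdr("duration_s", 0)
    return(classify_photons(empty))
  }
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  for (col in c("timestamp_us", "channel"))
    if (!col %in% names(df)) stopf("photon TSV is missing column '%s'", col)
  bad_ch <- which(!df$channel %in% c("donor", "acceptor"))
  if (length(bad_ch))
    stopf("unknown channel code '%s' at data line %d", df$channel[bad_ch[1]],
          bad_ch[1])
  bad_ts <- which(diff(df$timestamp_us) <= 0)
  if (length(bad_ts))
    stopf("non-monotone timestamp at data line %d (t = %g after %g)",
          bad_ts[1] + 1L, df$timestamp_us[bad_ts[1] + 1L], df$timestamp_us[bad_ts[1]])
  out <- df[, c("timestamp_us", "channel")]
  attr(out, "alternation_period") <- get_hdr("alternation_period_us", 100)
  attr(out, "duty") <- get_hdr("duty", 0.5)
  attr(out, "duration") <- get_hdr("duration_s", max(df$timestamp_us) * 1e-6)
  classify_photons(out)
}

#' Write TIRF traces as long-format CSV
#'
#' Columns: `trace_id`, `frame`, `time_s`, `I_D`, `I_A`.
#'
#' @param traces A list of `fret_trace` objects (or one).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(traces)
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trace_id = attr(tr, "trace_id") %||% "trace1",
               frame = tr$frame, time_s = tr$time_s,
               # 17 significant digits: doubles survive the round trip exactly
               I_D = formatC(tr$I_D, digits = 17, format = "g"),
               I_A = formatC(tr$I_A, digits = 17, format = "g"))
  }))
  write.table(long, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read long-format trace CSV
#'
#' Validates the schema and a constant frame period within each trace.
#'
#' @param path Input file.
#' @return A list of `fret_trace` objects.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("trace_id", "frame", "time_s", "I_D", "I_A")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("trace CSV is missing column(s): %s",
                          paste(miss, collapse = ", "))
  lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$frame), ]
    if (nrow(d) > 1) {
      dt <- diff(d$time_s)
      if (max(dt) - min(dt) > 1e-9 * max(dt, 1))
        stopf("frame-period mismatch within trace '%s'", d$trace_id[1])
      fp <- dt[1]
    } else fp <- NA_real_
    structure(data.frame(frame = d$frame, time_s = d$time_s,
                         I_D = d$I_D, I_A = d$I_A),
              frame_period = fp, trace_id = d$trace_id[1],
              class = c("fret_trace", "data.frame"))
  })
}

#' Write a ground-truth state path table as CSV
#'
#' Columns: `trace_id`, `state`, `t_start_s`, `t_end_s`.
#'
#' @param paths Named list of `ctmc_path` objects (names = trace ids).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paths_csv <- function(paths, path) {
  long <- do.call(rbind, lapply(names(paths), function(id) {
    p <- paths[[id]]
    data.frame(trace_id = id, state = p$state,
               t_start_s = p$t_entry, t_end_s = p$t_exit)
  }))
  write.table(long, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dwell table as CSV
#' @param dwells A `dwell_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dwells_csv <- function(dwells, path) {
  write.table(as.data.frame(dwells), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a per-burst table as CSV
#' @param bursts A `burst_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bursts_csv <- function(bursts, path) {
  write.table(as.data.frame(bursts), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an analysis results list as JSON
#' @param results A list (population fits, rates, lifetimes, ...).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
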