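#' Write a spike record to a plain-text spike file
#'
#' Self-describing text format: '#'-prefixed header lines carrying the
#' duration, the timestep and the population map, followed by one event per
#' line as `time_ms<TAB>neuron_id`, sorted by time then id. Timestamps are
#' 0-based milliseconds. The round trip through [read_spikes()] is lossless.
#'
#' ```
#' # barrelsim spikes v1
#' # duration 1000
#' # dt 1
#' # population L4E 0 3471
#' 12<TAB>77
#' ```
#'
#' @param record a [spike_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# barrelsim spikes v1",
               sprintf("# duration %g", record$duration),
               "# dt 1",
               sprintf("# population %s %d %d",
                       record$populations$name,
                       record$populations$first_id,
                       record$populations$size)), con)
  if (length(record$time))
    writeLines(sprintf("%d\t%d", record$time, record$id), con)
  invisible(path)
}

#' Read a spike file
#'
#' Parses the format written by [write_spikes()]. Malformed event lines
#' (wrong field count, non-integers, negative times) raise a parse error
#' identifying the line number; out-of-order times raise a format error.
#'
#' @param path file path.
#' @return A [spike_record()].
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  head_lines <- lines[hdr]
  body <- lines[!hdr]
  body_lineno <- which(!hdr)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, " "), head_lines, value = TRUE)
    if (length(m) == 0) stop(sprintf("spike file header lacks '%s'", key),
                             call. = FALSE)
    sub(paste0("^# ", key, " "), "", m)
  }
  duration <- as.numeric(get_field("duration")[1])
  popf <- strsplit(get_field("population"), " ", fixed = TRUE)
  pops <- data.frame(name = vapply(popf, `[[`, character(1), 1),
                     first_id = as.integer(vapply(popf, `[[`, character(1), 2)),
                     size = as.integer(vapply(popf, `[[`, character(1), 3)),
                     stringsAsFactors = FALSE)
  body_keep <- nzchar(trimws(body))
  body <- body[body_keep]
  body_lineno <- body_lineno[body_keep]
  if (length(body) == 0)
    return(spike_record(integer(0), integer(0), duration, pops))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  time <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 1)))
  id <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  bad <- sort(unique(c(bad, which(is.na(time) | is.na(id) | time < 0 | id < 0))))
  if (length(bad))
    stop(sprintf("parse error in spike file at line %d: '%s'",
                 body_lineno[bad[1]], body[bad[1]]), call. = FALSE)
  if (is.unsorted(time))
    stop("format error: spike times are not sorted", call. = FALSE)
  spike_record(time, id, duration, pops)
}

#' Default model and protocol configuration
#'
#' Flat key-value configuration covering every standard model constant:
#' population sizes, neuron parameters of both layers, connection
#' probabilities, synaptic weights, the balance coefficient, the
#' inhibitory-to-excitatory scaling and the stimulus parameters. Values
#' default to the published ones; [read_config()] / [write_config()] move
#' the set to and from a plain-text file (`key = value` per line, '#'
#' comments).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    n_L23E = 4507, n_L23I = 795, n_L4E = 3471, n_L4I = 613, n_thalamus = 285,
    L4E_E_L = -66, L4E_V_reset = -66, L4E_V_theta = -40, L4E_tau_m = 35,
    L4E_R_m = 300, L4E_tau_se = 5, L4E_tau_si = 15, L4E_t_ref = 10,
    L23E_E_L = -72, L23E_V_reset = -72, L23E_V_theta = -40, L23E_tau_m = 30,
    L23E_R_m = 190, L23E_tau_se = 5, L23E_tau_si = 15, L23E_t_ref = 10,
    p_tc = 0.25, p_cc = 0.1, w_e = 0.1, b = 1, i2e_scale = 1.5,
    w_interlayer = 0.2, w_lateral = 0.1,
    base_rate = 6, peak_rate = 30, onset_rise = 5, onset_fall = 30,
    rest_ms = 500, onset_offset_separation = 150, repetition_period = 100,
    n_columns = 5)
}

#' @rdname default_config
#' @param config named list of values.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, character(1))), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, integer(1)) != 2)
  if (length(bad))
    stop(sprintf("config parse error at line: '%s'", lines[bad[1]]),
         call. = FALSE)
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  names(vals) <- trimws(vapply(kv, `[[`, character(1), 1))
  vals
}

#' Write a delimited results table
#'
#' Tab-separated text with a header row, as used for sweep results, PSTH
#' tables and count maps.
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a PSTH to a data frame
#'
#' @param x a [psth()] object.
#' @param ... unused.
#' @return Data frame with bin left edges, centres and rates.
#' @export
as.data.frame.psth <- function(x, ...) {
  data.frame(bin_left = x$breaks[-length(x$breaks)], bin_mid = x$mid,
             rate_hz = x$rate, count = x$counts)
}
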