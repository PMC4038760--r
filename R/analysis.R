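#' Mean population firing rate in a time window
#'
#' Events from the population falling in the half-open window `[t0, t1)`,
#' divided by population size and window length:
#' `rate = count / (n_neurons * (t1 - t0) / 1000)` Hz per neuron.
#'
#' @param record a [spike_record()].
#' @param population population name; `NULL` pools every population in the
#'   record's map.
#' @param window numeric `c(t0, t1)`, ms, with `t1 > t0`.
#' @return Mean rate, Hz.
#' @examples
#' rec <- spike_record(c(10, 20, 30), c(0, 1, 2), 1000,
#'                     data.frame(name = "pop", first_id = 0L, size = 100L))
#' mean_rate(rec, "pop", c(0, 1000))  # 0.03 Hz
#' @export
mean_rate <- function(record, population = NULL,
                      window = c(0, record$duration)) {
  if (window[2] <= window[1])
    stop("invalid window: t1 must exceed t0", call. = FALSE)
  pops <- population_range(record$populations, population)
  n <- sum(pops$size)
  if (n == 0) stop("empty population", call. = FALSE)
  in_pop <- rep(FALSE, length(record$id))
  for (k in seq_len(nrow(pops)))
    in_pop <- in_pop | (record$id >= pops$first_id[k] &
                        record$id < pops$first_id[k] + pops$size[k])
  cnt <- sum(in_pop & record$time >= window[1] & record$time < window[2])
  cnt / (n * (window[2] - window[1]) / 1000)
}

#' Peristimulus time histogram
#'
#' Trial-averaged, stimulus-aligned firing-rate estimate: every spike of the
#' population is re-referenced to each alignment time, binned at
#' `bin_width`, and normalized to Hz per neuron:
#' `rate = count / (n_neurons * n_presentations * bin_width / 1000)`,
#' where a presentation is one (record, alignment time) pair. Bins are
#' half-open `[left, right)`.
#'
#' @param records a `spike_record` or list of them (e.g. one per trial).
#' @param population population name (`NULL`: all).
#' @param align_times numeric vector of alignment times, ms, applied to
#'   every record (must be non-empty).
#' @param bin_width bin width, ms (> 0).
#' @param window alignment-relative range `c(lo, hi)`, ms.
#' @return A `psth` object: list with `breaks` (bin edges, ms, relative),
#'   `mid` (bin centres), `rate` (Hz/neuron), `population`,
#'   `n_presentations`, `bin_width`.
#' @export
psth <- function(records, population = NULL, align_times, bin_width = 5,
                 window = c(-100, 100)) {
  if (inherits(records, "spike_record")) records <- list(records)
  if (length(align_times) == 0)
    stop("at least one alignment time is required", call. = FALSE)
  stopifnot(bin_width > 0, window[2] > window[1])
  breaks <- seq(window[1], window[2], by = bin_width)
  if (breaks[length(breaks)] < window[2])
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  counts <- numeric(length(breaks) - 1)
  pops <- population_range(records[[1]]$populations, population)
  n_neurons <- sum(pops$size)
  for (rec in records) {
    in_pop <- rep(FALSE, length(rec$id))
    for (k in seq_len(nrow(pops)))
      in_pop <- in_pop | (rec$id >= pops$first_id[k] &
                          rec$id < pops$first_id[k] + pops$size[k])
    tt <- rec$time[in_pop]
    for (a in align_times) {
      rel <- tt - a
      rel <- rel[rel >= breaks[1] & rel < breaks[length(breaks)]]
      if (length(rel))
        counts <- counts + tabulate(findInterval(rel, breaks),
                                    nbins = length(breaks) - 1)
    }
  }
  n_pres <- length(records) * length(align_times)
  structure(list(breaks = breaks, mid = breaks[-length(breaks)] + bin_width / 2,
                 rate = counts / (n_neurons * n_pres * bin_width / 1000),
                 counts = counts, n_neurons = n_neurons,
                 population = if (is.null(population)) "all" else population,
                 n_presentations = n_pres, bin_width = bin_width),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH [%s]: %d bins of %g ms over [%g, %g) ms, %d presentations x %d neurons\n",
              x$population, length(x$rate), x$bin_width, x$breaks[1],
              x$breaks[length(x$breaks)], x$n_presentations, x$n_neurons))
  cat(sprintf("  peak %.2f Hz at %g ms, mean %.2f Hz\n",
              max(x$rate), x$mid[which.max(x$rate)], mean(x$rate)))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  graphics::plot(x$mid, x$rate, type = "s", xlab = "time from alignment (ms)",
                 ylab = "rate (Hz/neuron)",
                 main = sprintf("PSTH: %s", x$population), ...)
  invisible(x)
}

#' Per-neuron spike counts in post-onset windows
#'
#' Counts, for every neuron in the record's population map, the spikes
#' falling in the union of the half-open windows `[onset_k, onset_k + width)`
#' over all supplied onset times. Events exactly at `onset + width` are
#' excluded.
#'
#' @param record a `spike_record`.
#' @param onset_times numeric vector of window starts, ms.
#' @param width window length, ms (default the 25-ms post-deflection
#'   analysis window).
#' @return A `count_map`: integer vector of length `sum(sizes)` indexed by
#'   global neuron id + 1, with the population map as attribute
#'   `"populations"`.
#' @export
window_counts <- function(record, onset_times, width = 25) {
  n_total <- sum(record$populations$size)
  counts <- integer(n_total)
  for (a in onset_times) {
    sel <- record$time >= a & record$time < a + width
    if (any(sel))
      counts <- counts + tabulate(record$id[sel] + 1L, nbins = n_total)
  }
  structure(counts, populations = record$populations, width = width,
            class = "count_map")
}

#' @export
print.count_map <- function(x, ...) {
  pops <- attr(x, "populations")
  cat(sprintf("count_map: %d cells, %d spikes in %g-ms windows\n",
              length(x), sum(x), attr(x, "width")))
  for (k in seq_len(nrow(pops))) {
    idx <- pops$first_id[k] + seq_len(pops$size[k])
    cat(sprintf("  %-12s total %d, max %d\n", pops$name[k],
                sum(x[idx]), max(x[idx])))
  }
  invisible(x)
}

# Detect an evoked response: does any PSTH bin in the test windows exceed
# the baseline mean by 3 baseline standard deviations?
detect_evoked <- function(ps, baseline_window, test_windows) {
  base <- ps$rate[ps$mid >= baseline_window[1] & ps$mid < baseline_window[2]]
  thr <- mean(base) + 3 * stats::sd(base)
  test <- rep(FALSE, length(ps$mid))
  for (k in seq_len(nrow(test_windows)))
    test <- test | (ps$mid >= test_windows[k, 1] & ps$mid < test_windows[k, 2])
  peak <- if (any(test)) max(ps$rate[test]) else NA_real_
  list(evoked = isTRUE(peak > thr), threshold = thr, peak = peak,
       baseline_mean = mean(base), baseline_sd = stats::sd(base))
}
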