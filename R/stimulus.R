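#' Triangular thalamic rate profile
#'
#' Piecewise-linear firing-rate profile of one whisker-deflection transient:
#' the rate rises linearly from `base` at time `t0` to `peak` at `t0 + rise`,
#' decays linearly back to `base` at `t0 + rise + fall`, and equals `base`
#' elsewhere. A deflection onset uses a fast rise and slow decay
#' (6 -> 30 Hz in 5 ms, back in 30 ms); the offset is the mirrored triangle
#' of equal amplitude with opposite rise and decay times.
#'
#' @param base baseline rate, Hz (>= 0).
#' @param peak peak rate, Hz (>= base).
#' @param rise,fall rise / decay duration, ms (> 0).
#' @param t0 triangle start time, ms.
#' @param duration profile horizon, ms; the sampled rate covers times
#'   0..duration-1 at 1-ms resolution.
#' @return A `rate_profile` object: list with `rate` (Hz at each 1-ms step)
#'   and the construction parameters.
#' @examples
#' pr <- triangle_profile(6, 30, 5, 30, t0 = 100, duration = 200)
#' rate_at(pr, 105)    # 30 Hz at the peak
#' rate_at(pr, 102.5)  # linear midpoint, 18 Hz
#' @export
triangle_profile <- function(base = 6, peak = 30, rise = 5, fall = 30,
                             t0 = 0, duration = NULL) {
  stopifnot(peak >= base, base >= 0, rise > 0, fall > 0)
  if (is.null(duration)) duration <- ceiling(t0 + rise + fall)
  events <- data.frame(t0 = t0, peak = peak, rise = rise, fall = fall)
  new_rate_profile(base, events, duration)
}

new_rate_profile <- function(base, events, duration) {
  duration <- as.integer(duration)
  stopifnot(duration > 0)
  pr <- structure(list(base = base, events = events, duration = duration,
                       rate = NULL),
                  class = "rate_profile")
  pr$rate <- rate_at(pr, seq_len(duration) - 1)
  pr
}

#' Evaluate a rate profile at arbitrary times
#'
#' Exact piecewise-linear evaluation of a [triangle_profile()] or
#' [schedule_rate()] profile. Where triangles would overlap, the
#' instantaneous rate is the maximum of the baseline and every active
#' triangle (no summation).
#'
#' @param profile a `rate_profile`.
#' @param t numeric vector of times, ms.
#' @return Rate in Hz at each time.
#' @export
rate_at <- function(profile, t) {
  r <- rep(profile$base, length(t))
  ev <- profile$events
  for (k in seq_len(nrow(ev))) {
    up <- profile$base + (ev$peak[k] - profile$base) * (t - ev$t0[k]) / ev$rise[k]
    dn <- ev$peak[k] - (ev$peak[k] - profile$base) *
      (t - ev$t0[k] - ev$rise[k]) / ev$fall[k]
    tri <- pmax(profile$base, pmin(up, dn))
    r <- pmax(r, tri)
  }
  r
}

#' Single-deflection stimulus battery
#'
#' The basic stimulation unit of the response-transformation protocol: a
#' 500-ms rest period, then one whisker-deflection onset, then one offset
#' 150 ms later.
#'
#' @param t0 battery start time, ms (>= 0).
#' @return A `stimulus_schedule`: data frame with columns `kind`
#'   ("onset"/"offset") and `time` (ms), time-ordered, with the battery
#'   timing metadata stored as attributes `rest` and `separation`.
#' @examples
#' battery_single()          # onset at 500 ms, offset at 650 ms
#' @export
battery_single <- function(t0 = 0) {
  stopifnot(t0 >= 0)
  sched <- data.frame(kind = c("onset", "offset"), time = t0 + c(500, 650),
                      stringsAsFactors = FALSE)
  structure(sched, class = c("stimulus_schedule", "data.frame"),
            rest = 500, separation = 150)
}

#' Repeated-deflection stimulus battery for the chain protocol
#'
#' A 500-ms rest period followed by five repetitions, at 10 Hz, of the
#' deflection onset and offset: repetition k (k = 0..4) places an onset at
#' `t0 + 500 + 100 k` and an offset 50 ms later. Five such batteries give
#' the protocol's 25 deflection onsets.
#'
#' @param t0 battery start time, ms (>= 0).
#' @param n_repetitions onset/offset pairs per battery.
#' @return A `stimulus_schedule` (see [battery_single()]).
#' @export
battery_chain <- function(t0 = 0, n_repetitions = 5) {
  stopifnot(t0 >= 0, n_repetitions >= 1)
  on <- t0 + 500 + 100 * (seq_len(n_repetitions) - 1)
  sched <- data.frame(kind = rep(c("onset", "offset"), n_repetitions),
                      time = as.numeric(rbind(on, on + 50)),
                      stringsAsFactors = FALSE)
  structure(sched, class = c("stimulus_schedule", "data.frame"),
            rest = 500, repetition_period = 100)
}

#' Thalamic rate profile of a stimulus schedule
#'
#' Expands a [battery_single()] / [battery_chain()] schedule into the
#' piecewise-linear thalamic rate profile: every onset event contributes a
#' fast-rising triangle (`rise`/`fall` = 5/30 ms by default) and every
#' offset the mirrored slow-rising one (30/5 ms), on the 6-Hz baseline.
#'
#' @param schedule a `stimulus_schedule`.
#' @param duration profile horizon, ms.
#' @param base,peak baseline and peak rate, Hz.
#' @param onset_rise,onset_fall onset-triangle rise/decay, ms (the offset
#'   triangle swaps them).
#' @return A `rate_profile`.
#' @export
schedule_rate <- function(schedule, duration, base = 6, peak = 30,
                          onset_rise = 5, onset_fall = 30) {
  stopifnot(nrow(schedule) >= 1)
  is_on <- schedule$kind == "onset"
  events <- data.frame(
    t0 = schedule$time, peak = peak,
    rise = ifelse(is_on, onset_rise, onset_fall),
    fall = ifelse(is_on, onset_fall, onset_rise))
  new_rate_profile(base, events, duration)
}

#' Generate inhomogeneous Poisson spike trains
#'
#' Emits spikes from `n_sources` mutually independent Poisson sources on the
#' 1-ms grid by Bernoulli thinning: in each 1-ms bin each source fires with
#' probability `rate(t) * dt / 1000`. The thinning bias relative to an exact
#' point process is of order `rate * dt` (at most 3% at the 30-Hz stimulus
#' peak). Output is deterministic given the seed.
#'
#' @param n_sources number of independent sources.
#' @param profile a `rate_profile`, a numeric vector of per-ms rates (Hz),
#'   or a single constant rate in Hz.
#' @param duration horizon, ms; defaults to the profile length.
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @param first_id global id of the first source (ids are
#'   `first_id .. first_id + n_sources - 1`).
#' @param population name recorded in the output's population map.
#' @param dt bin width, ms (must satisfy `rate * dt < 1000` everywhere).
#' @return A [spike_record()] holding the source spikes.
#' @export
generate_spikes <- function(n_sources, profile, duration = NULL, seed = NULL,
                            first_id = 0, population = "thalamus", dt = 1) {
  rate <- if (inherits(profile, "rate_profile")) profile$rate
          else as.numeric(profile)
  if (length(rate) == 1 && !is.null(duration))
    rate <- rep(rate, duration)
  if (is.null(duration)) duration <- length(rate)
  if (length(rate) < duration)
    stop("rate profile shorter than requested duration", call. = FALSE)
  rate <- rate[seq_len(duration)]
  if (any(rate < 0)) stop("rates must be non-negative", call. = FALSE)
  p <- rate * dt / 1000
  if (any(p >= 1))
    stop("invalid profile: rate*dt must stay below one spike per bin",
         call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  u <- matrix(stats::runif(duration * n_sources), nrow = duration)
  hit <- which(u < p)  # p recycles down columns: one column per source
  time <- (hit - 1) %% duration
  id <- first_id + (hit - 1) %/% duration
  pops <- data.frame(name = population, first_id = first_id,
                     size = n_sources, stringsAsFactors = FALSE)
  spike_record(time, id, duration, pops)
}

#' Spike record
#'
#' The universal container for simulated activity: time-ordered spike events
#' `(time ms, neuron id)` with the population map needed to decode global
#' ids. Ids are 0-based and globally unique; times lie in `[0, duration)`.
#'
#' @param time integer vector of spike times, ms.
#' @param id integer vector of 0-based global neuron ids.
#' @param duration record horizon, ms.
#' @param populations data frame with columns `name`, `first_id`, `size`.
#' @return A `spike_record` (events sorted by time, then id).
#' @export
spike_record <- function(time, id, duration,
                         populations = data.frame(name = "all", first_id = 0L,
                                                  size = max(c(id, 0L)) + 1L)) {
  stopifnot(length(time) == length(id), duration > 0)
  if (length(time) && (min(time) < 0 || max(time) >= duration))
    stop("spike times must lie in [0, duration)", call. = FALSE)
  o <- order(time, id)
  structure(list(time = as.integer(time)[o], id = as.integer(id)[o],
                 duration = as.numeric(duration),
                 populations = populations),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike_record: %d events over %g ms, %d population(s)\n",
              length(x$time), x$duration, nrow(x$populations)))
  for (k in seq_len(nrow(x$populations))) {
    p <- x$populations[k, ]
    in_pop <- sum(x$id >= p$first_id & x$id < p$first_id + p$size)
    cat(sprintf("  %-12s ids %d..%d  %d spikes (%.2f Hz/neuron)\n",
                p$name, p$first_id, p$first_id + p$size - 1, in_pop,
                1000 * in_pop / (p$size * x$duration)))
  }
  invisible(x)
}

#' Raster plot of a spike record
#'
#' @param x a `spike_record`.
#' @param populations optional character vector restricting the raster.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spike_record <- function(x, populations = NULL, ...) {
  keep <- rep(TRUE, length(x$time))
  if (!is.null(populations)) {
    keep <- rep(FALSE, length(x$time))
    for (p in populations) {
      row <- population_range(x$populations, p)
      keep <- keep | (x$id >= row$first_id & x$id < row$first_id + row$size)
    }
  }
  graphics::plot(x$time[keep], x$id[keep], pch = ".", cex = 1.2,
                 xlab = "time (ms)", ylab = "neuron id", ...)
  invisible(x)
}

# Merge several spike records (disjoint id ranges) into one.
merge_records <- function(records, duration = NULL) {
  if (is.null(duration)) duration <- max(vapply(records, `[[`, numeric(1),
                                                "duration"))
  spike_record(unlist(lapply(records, `[[`, "time")),
               unlist(lapply(records, `[[`, "id")),
               duration,
               do.call(rbind, lapply(records, `[[`, "populations")))
}
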