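#' Calibrate the thalamocortical synaptic weight
#'
#' Finds the minimum thalamocortical weight that elicits firing in the
#' barrel without intracortical projections under constant-rate Poisson
#' thalamic drive. "Elicits firing" is quantified as a mean L4E rate of at
#' least `criterion_rate` (0.1 Hz) over a `duration`-long simulation — a
#' small positive threshold over a long window, robust to Poisson
#' fluctuations. The search brackets the criterion by factor-2 steps from
#' `w_start` and then bisects to `tol` (1%) relative precision, holding the
#' connectivity and the stimulus realization fixed so that the firing
#' criterion is monotone in the weight: every weight above the returned one
#' also satisfies it.
#'
#' @param drive_rate thalamic Poisson rate, Hz (> 0; the in-vivo spontaneous
#'   rate is 6 Hz).
#' @param seed integer seed (connectivity and stimulus).
#' @param duration evaluation window per probe, ms.
#' @param criterion_rate firing criterion on the mean L4E rate, Hz.
#' @param w_start initial probe weight, nA.
#' @param w_max largest probe weight before the search is declared failed.
#' @param tol relative bisection tolerance.
#' @param scale population-size multiplier (see [build_barrel()]).
#' @return Calibrated weight, nA, with the probe history in attribute
#'   `"history"`.
#' @export
calibrate_tc_weight <- function(drive_rate = 6, seed = 1, duration = 10000,
                                criterion_rate = 0.1, w_start = 0.005,
                                w_max = 1.28, tol = 0.01, scale = 1) {
  stopifnot(drive_rate > 0, duration > 0, w_start > 0, tol > 0)
  seeds <- derive_seeds(seed, 2)
  model <- build_barrel(w_tc = w_start, seed = seeds[1], scale = scale,
                        intracortical = FALSE)
  stim <- baseline_stimulus(model, duration, seeds[2], rate = drive_rate)
  probe <- function(w) {
    m <- set_tc_weight(model, w)
    rec <- run_simulation(m, stim, duration)
    mean_rate(rec, "L4E")
  }
  history <- data.frame(w = numeric(0), rate = numeric(0))
  fires <- function(w) {
    r <- probe(w)
    history[nrow(history) + 1, ] <<- c(w, r)
    r >= criterion_rate
  }
  w_hi <- w_start
  while (!fires(w_hi)) {
    w_hi <- w_hi * 2
    if (w_hi > w_max)
      stop("calibration failure: no weight up to w_max satisfies the firing criterion",
           call. = FALSE)
  }
  w_lo <- w_hi / 2
  if (w_hi > w_start) {
    while ((w_hi - w_lo) > tol * w_hi) {
      mid <- (w_hi + w_lo) / 2
      if (fires(mid)) w_hi <- mid else w_lo <- mid
    }
  }
  structure(w_hi, history = history)
}

# Replace the weight of the thalamocortical projections without resampling
# connectivity (the model is instantiated once; only weights change).
set_tc_weight <- function(model, w) {
  for (k in seq_along(model$projections)) {
    if (grepl("^(c[0-9]+\\.)?thalamus->", model$projections[[k]]$name))
      model$projections[[k]]$w <- w
  }
  model$provenance$w_tc <- w
  model
}
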