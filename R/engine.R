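#' Run a clock-driven network simulation
#'
#' Advances every neuron of a [build_barrel()] / [build_column()] /
#' [build_chain()] model on the fixed 1-ms grid. At each step t, source
#' spikes stamped t and network spikes stamped t-1 are delivered through the
#' sampled connection sets into the target accumulators (one-step conduction
#' delay); each cortical neuron is then advanced with the exact propagator
#' of its membrane/synaptic-current system (see [advance_neuron()]) and
#' tested against threshold. All cortical spikes are returned, stamped with
#' the step at which they were detected. The run is fully deterministic
#' given the model, the stimulus and the initial state.
#'
#' Membrane potentials start at `E_L` and synaptic currents at zero unless
#' overridden; the stimulation protocols' 500-ms rest period washes out the
#' deterministic start.
#'
#' @param model a `barrel_network`.
#' @param stimulus a [spike_record()] of source-population spikes covering
#'   `[0, duration)` (its `duration` must be at least `duration`).
#' @param duration simulated time, ms.
#' @param dt timestep, ms (the model is defined on a 1-ms clock).
#' @param i_offset optional per-neuron constant injected current (nA),
#'   length `model$n_neurons`.
#' @param v_init optional per-neuron initial membrane potential (mV).
#' @param verbose if `TRUE`, print a per-population spike-count summary.
#' @return A `spike_record` of cortical spikes, with the model's full
#'   population map attached.
#' @export
run_simulation <- function(model, stimulus = NULL, duration = 1000, dt = 1,
                           i_offset = NULL, v_init = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "barrel_network"), duration > 0)
  if (is.null(stimulus)) {
    stim_t <- integer(0); stim_i <- integer(0)
  } else {
    if (stimulus$duration < duration)
      stop("stimulus record is shorter than the simulation duration",
           call. = FALSE)
    stim_t <- stimulus$time; stim_i <- stimulus$id
  }
  set_names <- names(model$params)
  pmat <- do.call(rbind, lapply(model$params, function(p)
    c(p$E_L, p$V_reset, p$V_theta, p$tau_m, p$R_m, p$tau_se, p$tau_si,
      p$t_ref)))
  pidx <- integer(model$n_neurons)
  for (k in seq_len(nrow(model$populations))) {
    pop <- model$populations[k, ]
    idx <- pop$first_id + seq_len(pop$size)
    pidx[idx] <- if (is.na(pop$param_set)) -1L
                 else match(pop$param_set, set_names) - 1L
  }
  res <- cpp_run(pidx, pmat, model$projections,
                 stim_t, stim_i, as.integer(duration), dt,
                 if (is.null(i_offset)) numeric(0) else as.numeric(i_offset),
                 if (is.null(v_init)) numeric(0) else as.numeric(v_init))
  rec <- spike_record(res$time, res$id, duration, model$populations)
  if (verbose) print(rec)
  rec
}

#' Run repeated trials with fresh stimulus realizations
#'
#' Simulates the same instantiated model `n_trials` times: connectivity is
#' held fixed, while each trial gets a fresh initial state and a fresh,
#' independently seeded stimulus realization. Trials are mutually
#' independent, so any trial can be reproduced in isolation from the master
#' seed and its index.
#'
#' @param model a `barrel_network`.
#' @param stimulus_fn function of one argument (the trial's stimulus seed)
#'   returning the trial's stimulus `spike_record`.
#' @param n_trials number of trials (>= 1).
#' @param duration per-trial simulated time, ms.
#' @param seed master seed from which the per-trial stimulus seeds are
#'   derived.
#' @param init initial membrane potentials: `"E_L"` (deterministic start at
#'   the equilibrium potential) or `"random"` (per-trial seeded uniform draw
#'   on `[E_L, V_theta)`, the usual convention for steady-state rate
#'   measurements without a rest period, avoiding the start-up dead time of
#'   a cold network).
#' @param ... passed on to [run_simulation()].
#' @return List of `n_trials` spike records, with the per-trial seeds in
#'   attribute `"trial_seeds"`.
#' @export
run_trials <- function(model, stimulus_fn, n_trials = 10, duration = 1000,
                       seed = 1, init = c("E_L", "random"), ...) {
  stopifnot(n_trials >= 1)
  init <- match.arg(init)
  seeds <- derive_seeds(seed, n_trials)
  out <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    stim <- stimulus_fn(seeds[k])
    v0 <- if (init == "random") random_v_init(model, seeds[k]) else NULL
    out[[k]] <- run_simulation(model, stim, duration, v_init = v0, ...)
  }
  attr(out, "trial_seeds") <- seeds
  out
}

# Seeded uniform initial membrane potentials on [E_L, V_theta) per neuron
# (source neurons get a placeholder; the engine never integrates them).
random_v_init <- function(model, seed) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  v0 <- numeric(model$n_neurons)
  for (k in seq_len(nrow(model$populations))) {
    pop <- model$populations[k, ]
    idx <- pop$first_id + seq_len(pop$size)
    if (is.na(pop$param_set)) next
    p <- model$params[[pop$param_set]]
    v0[idx] <- stats::runif(pop$size, p$E_L, p$V_theta)
  }
  v0
}

# Split one master seed into n reproducible sub-seeds (< 2^31).
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Constant 6-Hz thalamic drive for every source population of a model.
baseline_stimulus <- function(model, duration, seed, rate = 6) {
  src <- model$populations[model$populations$polarity == "source", ,
                           drop = FALSE]
  seeds <- derive_seeds(seed, nrow(src))
  recs <- lapply(seq_len(nrow(src)), function(k)
    generate_spikes(src$size[k], rate, duration, seed = seeds[k],
                    first_id = src$first_id[k], population = src$name[k]))
  merge_records(recs, duration)
}
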