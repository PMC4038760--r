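#' Balance-coefficient sweep
#'
#' The first protocol: one barrel (inhibitory-to-excitatory scaling 1) is
#' driven by constant 6-Hz thalamic Poisson spiking while the balance
#' coefficient b sweeps the grid. The model is instantiated once per b value
#' with the same connectivity seed (so connectivity is identical across the
#' sweep and only the inhibitory weights change) and simulated `n_trials`
#' times with fresh stimulus seeds; each trial's mean excitatory (L4E)
#' firing rate over the run is recorded and summarized as mean and standard
#' deviation across trials. The rate traverses a sigmoid from the
#' refractory-limited maximum (~1000/t_ref Hz) at small b to near-silence at
#' large b, centred on b = 1.
#'
#' The sweep protocol has no rest period, so each trial starts from seeded
#' uniform membrane potentials on `[E_L, V_theta)` (see [run_trials()]): the
#' one-second window then measures the steady-state rate rather than the
#' cold-start ignition transient of a network initialized at `E_L`.
#'
#' @param b_grid balance coefficients (> 0); default 25 log-spaced points on
#'   `[0.1, 10]`.
#' @param n_trials trials per b value.
#' @param duration per-trial simulated time, ms.
#' @param seed master seed (connectivity, calibration, trial stimuli).
#' @param w_tc thalamocortical weight, nA; `NULL` calibrates it first via
#'   [calibrate_tc_weight()].
#' @param drive_rate thalamic rate, Hz.
#' @param scale population-size multiplier.
#' @param i2e_scale I-to-E weight multiplier (the sweep protocol uses 1).
#' @return A `balance_sweep` data frame with columns `b`, `rate_mean`,
#'   `rate_sd` (Hz), one row per grid point; `w_tc` and the call parameters
#'   are kept as attributes.
#' @export
balance_sweep <- function(b_grid = 10^seq(-1, 1, length.out = 25),
                          n_trials = 10, duration = 1000, seed = 1,
                          w_tc = NULL, drive_rate = 6, scale = 1,
                          i2e_scale = 1) {
  stopifnot(all(b_grid > 0), n_trials >= 1)
  seeds <- derive_seeds(seed, 2)
  if (is.null(w_tc))
    w_tc <- calibrate_tc_weight(drive_rate, seed = seeds[1], scale = scale)
  rows <- lapply(b_grid, function(b) {
    model <- build_barrel(b = b, i2e_scale = i2e_scale, w_tc = w_tc,
                          seed = seeds[2], scale = scale)
    recs <- run_trials(model,
                       function(s) baseline_stimulus(model, duration, s,
                                                     rate = drive_rate),
                       n_trials = n_trials, duration = duration, seed = seed,
                       init = "random")
    rates <- vapply(recs, mean_rate, numeric(1), population = "L4E")
    data.frame(b = b, rate_mean = mean(rates),
               rate_sd = if (n_trials > 1) stats::sd(rates) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("balance_sweep", "data.frame"),
            w_tc = as.numeric(w_tc), n_trials = n_trials,
            duration = duration, seed = seed, scale = scale)
}

#' @export
plot.balance_sweep <- function(x, ...) {
  graphics::plot(x$b, x$rate_mean, log = "x", type = "b", pch = 16,
                 xlab = "balance coefficient b",
                 ylab = "mean L4E rate (Hz)", ...)
  graphics::arrows(x$b, pmax(0, x$rate_mean - x$rate_sd),
                   x$b, x$rate_mean + x$rate_sd,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(v = 1, lty = 3)
  invisible(x)
}

#' Thalamocortical response-transformation experiment
#'
#' The second protocol: `n_models` independently sampled barrels in the
#' balanced regime (b = 1, I-to-E weights scaled by 1.5) each receive
#' `n_batteries` single-deflection stimulus batteries ([battery_single()]:
#' 500-ms rest, deflection onset, offset 150 ms later). Each battery is an
#' independent run with a fresh stimulus seed (the rest period washes out
#' initial transients, so this is equivalent to concatenation). PSTHs are
#' pooled across every presentation of every instance and summarized per
#' instance: spontaneous excitatory rate (rest window), onset-response peak
#' and offset-response peak.
#'
#' The two transformations under test: cortical excitatory spontaneous
#' rates fall well below the 6-Hz thalamic rate, and deflection onsets (fast
#' rate rise) evoke larger responses than offsets (slow rise).
#'
#' @param n_models independently instantiated barrels.
#' @param n_batteries batteries per instance.
#' @param b,i2e_scale balance parameters of the regime under test.
#' @param seed master seed.
#' @param w_tc thalamocortical weight; `NULL` calibrates it.
#' @param scale population-size multiplier.
#' @param bin_width PSTH bin, ms.
#' @return A `transformation_result`: list with pooled `psth` per population
#'   (aligned to battery start), per-instance `summary` data frame
#'   (`spont_rate`, `onset_peak`, `offset_peak`, Hz), and the parameters.
#' @export
response_transformation <- function(n_models = 10, n_batteries = 25, b = 1,
                                    i2e_scale = 1.5, seed = 1, w_tc = NULL,
                                    scale = 1, bin_width = 5) {
  stopifnot(n_models >= 1, n_batteries >= 1)
  duration <- 700  # 500 rest + onset + offset at 650 + 35-ms triangle tail
  seeds <- derive_seeds(seed, 1 + n_models)
  if (is.null(w_tc))
    w_tc <- calibrate_tc_weight(6, seed = seeds[1], scale = scale)
  sched <- battery_single(0)
  profile <- schedule_rate(sched, duration)
  onset_t <- sched$time[sched$kind == "onset"]
  offset_t <- sched$time[sched$kind == "offset"]

  all_recs <- list()
  all_stims <- list()
  summaries <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    model <- build_barrel(b = b, i2e_scale = i2e_scale, w_tc = w_tc,
                          seed = seeds[1 + m], scale = scale)
    thal <- model$populations[model$populations$name == "thalamus", ]
    recs <- run_trials(model,
      function(s) generate_spikes(thal$size, profile, duration, seed = s,
                                  first_id = thal$first_id),
      n_trials = n_batteries, duration = duration, seed = seeds[1 + m],
      init = "random")
    stims <- lapply(attr(recs, "trial_seeds"), function(s)
      generate_spikes(thal$size, profile, duration, seed = s,
                      first_id = thal$first_id))
    inst_psth <- psth(recs, "L4E", align_times = 0, bin_width = bin_width,
                      window = c(0, duration))
    onset_peak <- max(inst_psth$rate[inst_psth$mid >= onset_t &
                                     inst_psth$mid < onset_t + 50])
    offset_peak <- max(inst_psth$rate[inst_psth$mid >= offset_t &
                                      inst_psth$mid < offset_t + 50])
    spont <- mean(vapply(recs, mean_rate, numeric(1), population = "L4E",
                         window = c(100, 500)))
    summaries[[m]] <- data.frame(instance = m, spont_rate = spont,
                                 onset_peak = onset_peak,
                                 offset_peak = offset_peak)
    all_recs <- c(all_recs, recs)
    all_stims <- c(all_stims, stims)
  }
  pooled <- list(
    L4E = psth(all_recs, "L4E", 0, bin_width, c(0, duration)),
    L4I = psth(all_recs, "L4I", 0, bin_width, c(0, duration)),
    thalamus = psth(all_stims, "thalamus", 0, bin_width, c(0, duration)))
  structure(list(psth = pooled,
                 summary = do.call(rbind, summaries),
                 onset_time = onset_t, offset_time = offset_t,
                 w_tc = as.numeric(w_tc), b = b, i2e_scale = i2e_scale,
                 n_models = n_models, n_batteries = n_batteries,
                 duration = duration, seed = seed, scale = scale),
            class = "transformation_result")
}

#' @export
print.transformation_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("response transformation: %d instances x %d batteries (b = %g, i2e_scale = %g)\n",
              x$n_models, x$n_batteries, x$b, x$i2e_scale))
  cat(sprintf("  spontaneous L4E rate: %.2f Hz (thalamus 6 Hz)\n",
              mean(s$spont_rate)))
  cat(sprintf("  onset peak %.1f Hz vs offset peak %.1f Hz; onset > offset in %d/%d instances\n",
              max(x$psth$L4E$rate[x$psth$L4E$mid >= x$onset_time &
                                  x$psth$L4E$mid < x$onset_time + 50]),
              max(x$psth$L4E$rate[x$psth$L4E$mid >= x$offset_time &
                                  x$psth$L4E$mid < x$offset_time + 50]),
              sum(s$onset_peak > s$offset_peak), nrow(s)))
  invisible(x)
}

#' Lateral-propagation experiment on the column chain
#'
#' The third protocol: a chain of `n_columns` barrel columns
#' ([build_chain()]) in the balanced regime. Column 0's thalamus receives
#' `n_batteries` repeated-deflection batteries ([battery_chain()]: 500-ms
#' rest, then five onset/offset pairs at 10 Hz); every other thalamus fires
#' at the 6-Hz baseline throughout. Each battery is simulated as an
#' independent run with fresh stimulus seeds. Outputs: battery-aligned
#' PSTHs for every population of every column, per-cell spike counts summed
#' over the 25-ms windows following every deflection onset, and an
#' evoked-response table (a population is "evoked" when any post-onset PSTH
#' bin exceeds its pre-battery baseline mean by 3 baseline standard
#' deviations).
#'
#' @param n_columns chain length (>= 2).
#' @param n_batteries batteries delivered to column 0.
#' @param b,i2e_scale balance parameters.
#' @param seed master seed.
#' @param w_tc thalamocortical weight; `NULL` calibrates it.
#' @param scale population-size multiplier.
#' @param bin_width PSTH bin, ms.
#' @return A `chain_result`: list with `psth` (per column, per population),
#'   `count_map` (per-cell counts over all onsets and batteries), `evoked`
#'   (per column/population table), and per-column L2/3E window-count
#'   summaries (`l23e_counts` raw, `l23e_evoked_counts` baseline-subtracted).
#' @export
chain_experiment <- function(n_columns = 5, n_batteries = 5, b = 1,
                             i2e_scale = 1.5, seed = 1, w_tc = NULL,
                             scale = 1, bin_width = 5) {
  stopifnot(n_columns >= 2, n_batteries >= 1)
  duration <- 1000  # 500 rest + 5 repetitions at 10 Hz (last offset ends 985)
  seeds <- derive_seeds(seed, 3)
  if (is.null(w_tc))
    w_tc <- calibrate_tc_weight(6, seed = seeds[1], scale = scale)
  model <- build_chain(n_columns = n_columns, b = b, i2e_scale = i2e_scale,
                       w_tc = w_tc, seed = seeds[2], scale = scale)
  sched <- battery_chain(0)
  profile <- schedule_rate(sched, duration)
  onsets <- sched$time[sched$kind == "onset"]
  src <- model$populations[model$populations$polarity == "source", ,
                           drop = FALSE]

  make_stim <- function(s) {
    sub_seeds <- derive_seeds(s, nrow(src))
    recs <- lapply(seq_len(nrow(src)), function(k) {
      prof <- if (src$name[k] == "c0.thalamus") profile else 6
      generate_spikes(src$size[k], prof, duration, seed = sub_seeds[k],
                      first_id = src$first_id[k], population = src$name[k])
    })
    merge_records(recs, duration)
  }
  trial_seeds <- derive_seeds(seeds[3], n_batteries)
  recs <- vector("list", n_batteries)
  stims <- vector("list", n_batteries)
  counts <- NULL
  for (k in seq_len(n_batteries)) {
    stims[[k]] <- make_stim(trial_seeds[k])
    recs[[k]] <- run_simulation(model, stims[[k]], duration,
                                v_init = random_v_init(model, trial_seeds[k]))
    cm <- window_counts(recs[[k]], onsets, width = 25)
    counts <- if (is.null(counts)) cm else structure(
      counts + cm, populations = attr(cm, "populations"),
      width = 25, class = "count_map")
  }

  layers <- c("L23E", "L23I", "L4E", "L4I")
  psths <- list()
  evoked_rows <- list()
  test_windows <- cbind(onsets, onsets + 50)
  l23e_counts <- numeric(n_columns)
  l23e_evoked <- numeric(n_columns)
  for (col in seq_len(n_columns) - 1L) {
    for (ly in layers) {
      popname <- sprintf("c%d.%s", col, ly)
      ps <- psth(recs, popname, 0, bin_width, c(0, duration))
      psths[[popname]] <- ps
      ev <- detect_evoked(ps, c(100, 500), test_windows)
      evoked_rows[[popname]] <- data.frame(
        column = col, population = ly, evoked = ev$evoked,
        peak = ev$peak, threshold = ev$threshold,
        baseline_mean = ev$baseline_mean)
    }
    # thalamic PSTH from the stimulus records
    tn <- sprintf("c%d.thalamus", col)
    psths[[tn]] <- psth(stims, tn, 0, bin_width, c(0, duration))
    # L2/3E post-onset counts, raw and baseline-subtracted
    pe <- model$populations[model$populations$name ==
                              sprintf("c%d.L23E", col), ]
    idx <- pe$first_id + seq_len(pe$size)
    l23e_counts[col + 1] <- sum(counts[idx])
    base_rate <- mean(vapply(recs, mean_rate, numeric(1),
                             population = sprintf("c%d.L23E", col),
                             window = c(100, 500)))
    expected_base <- base_rate * pe$size * length(onsets) * 25 / 1000 *
      n_batteries
    l23e_evoked[col + 1] <- l23e_counts[col + 1] - expected_base
  }
  structure(list(psth = psths, count_map = counts,
                 evoked = do.call(rbind, c(evoked_rows,
                                           make.row.names = FALSE)),
                 l23e_counts = l23e_counts,
                 l23e_evoked_counts = l23e_evoked,
                 onsets = onsets, w_tc = as.numeric(w_tc),
                 n_columns = n_columns, n_batteries = n_batteries,
                 b = b, i2e_scale = i2e_scale, duration = duration,
                 seed = seed, scale = scale),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("chain experiment: %d columns, %d batteries (b = %g, i2e_scale = %g, w_tc = %.4g nA)\n",
              x$n_columns, x$n_batteries, x$b, x$i2e_scale, x$w_tc))
  cat("  L2/3E evoked 25-ms counts (baseline-subtracted) by column:\n   ",
      paste(sprintf("%.0f", x$l23e_evoked_counts), collapse = "  "), "\n")
  ev <- x$evoked
  for (col in sort(unique(ev$column))) {
    e <- ev[ev$column == col, ]
    cat(sprintf("  column %d evoked: %s\n", col,
                paste(sprintf("%s=%s", e$population,
                              ifelse(e$evoked, "yes", "no")), collapse = " ")))
  }
  invisible(x)
}
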