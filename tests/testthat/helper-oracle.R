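# Independent oracles used across the suite.

# Fine-step explicit (Euler) integration of the coupled membrane/synapse
# ODEs: tau_m dV/dt = E_L - V + R_m (I_e + I_i + I_off), tau_s dI/dt = -I,
# with spikes delivered as instantaneous current increments w at their
# stamped millisecond (matching the engine's delivery-before-update
# contract). Returns V at the integer-ms grid points 0..duration.
reference_trajectory <- function(params, spikes, duration, dt_fine = 0.001,
                                 I_offset = 0, V0 = params$E_L) {
  V <- V0; Ie <- 0; Ii <- 0
  n_sub <- round(1 / dt_fine)
  Vgrid <- numeric(duration + 1)
  Vgrid[1] <- V
  for (t in seq_len(duration) - 1L) {
    arriving <- spikes$w[spikes$t == t]
    Ie <- Ie + sum(arriving[arriving > 0])
    Ii <- Ii + sum(arriving[arriving < 0])
    for (s in seq_len(n_sub)) {
      dV <- (params$E_L - V + params$R_m * (Ie + Ii + I_offset)) / params$tau_m
      V <- V + dt_fine * dV
      Ie <- Ie - dt_fine * Ie / params$tau_se
      Ii <- Ii - dt_fine * Ii / params$tau_si
    }
    Vgrid[t + 2] <- V
  }
  Vgrid
}

# Trajectory of the package's 1-ms update under the same spike train
# (subthreshold use: no threshold test).
package_trajectory <- function(params, spikes, duration, I_offset = 0,
                               V0 = params$E_L) {
  st <- neuron_state(V = V0)
  Vgrid <- numeric(duration + 1)
  Vgrid[1] <- st$V
  for (t in seq_len(duration) - 1L) {
    arriving <- spikes$w[spikes$t == t]
    st$I_e <- add_spike_weights(st$I_e, arriving[arriving > 0])
    st$I_i <- add_spike_weights(st$I_i, arriving[arriving < 0])
    st <- advance_neuron(st, params, 1, I_offset = I_offset)
    Vgrid[t + 2] <- st$V
  }
  Vgrid
}

# Plain-R reference network simulator implementing the same per-step
# contract as the compiled engine (deliver stimulus spikes stamped t and
# network spikes stamped t-1, exact propagation, inclusive threshold,
# decrement-first refractory). Independent code path used to cross-validate
# the engine on small networks.
reference_net_run <- function(model, stimulus, duration, v_init = NULL) {
  n <- model$n_neurons
  pops <- model$populations
  set_names <- names(model$params)
  pidx <- integer(n)
  for (k in seq_len(nrow(pops))) {
    idx <- pops$first_id[k] + seq_len(pops$size[k])
    pidx[idx] <- if (is.na(pops$param_set[k])) -1L
                 else match(pops$param_set[k], set_names)
  }
  cst <- lapply(model$params, function(p) {
    em <- exp(-1 / p$tau_m)
    list(E_L = p$E_L, V_reset = p$V_reset, V_theta = p$V_theta,
         t_ref = p$t_ref, em = em,
         ee = exp(-1 / p$tau_se), ei = exp(-1 / p$tau_si),
         ce = p$R_m * p$tau_se / (p$tau_se - p$tau_m) *
           (exp(-1 / p$tau_se) - em),
         ci = p$R_m * p$tau_si / (p$tau_si - p$tau_m) *
           (exp(-1 / p$tau_si) - em))
  })
  # adjacency by source
  adj <- vector("list", n)
  for (pr in model$projections) {
    for (j in seq_along(pr$pre)) {
      s <- pr$pre[j] + 1L
      adj[[s]] <- rbind(adj[[s]], c(pr$post[j] + 1L, pr$w))
    }
  }
  V <- numeric(n); Ie <- numeric(n); Ii <- numeric(n); refr <- numeric(n)
  for (i in seq_len(n))
    if (pidx[i] > 0)
      V[i] <- if (is.null(v_init)) cst[[pidx[i]]]$E_L else v_init[i]
  out_t <- integer(0); out_id <- integer(0)
  prev <- integer(0)
  for (t in seq_len(duration) - 1L) {
    sources <- c(stimulus$id[stimulus$time == t] + 1L, prev)
    for (s in sources) {
      a <- adj[[s]]
      if (is.null(a)) next
      for (j in seq_len(nrow(a))) {
        if (a[j, 2] >= 0) Ie[a[j, 1]] <- Ie[a[j, 1]] + a[j, 2]
        else Ii[a[j, 1]] <- Ii[a[j, 1]] + a[j, 2]
      }
    }
    cur <- integer(0)
    for (i in seq_len(n)) {
      if (pidx[i] < 0) next
      cc <- cst[[pidx[i]]]
      if (refr[i] > 0) refr[i] <- max(0, refr[i] - 1)
      if (refr[i] > 0) {
        V[i] <- cc$V_reset
      } else {
        V[i] <- cc$E_L + (V[i] - cc$E_L) * cc$em + cc$ce * Ie[i] +
          cc$ci * Ii[i]
      }
      Ie[i] <- Ie[i] * cc$ee
      Ii[i] <- Ii[i] * cc$ei
      if (refr[i] <= 0 && V[i] >= cc$V_theta) {
        V[i] <- cc$V_reset
        refr[i] <- cc$t_ref
        cur <- c(cur, i)
        out_t <- c(out_t, t); out_id <- c(out_id, i - 1L)
      }
    }
    prev <- cur
  }
  spike_record(out_t, out_id, duration, model$populations)
}

# Fraction of spikes in a that can be matched one-to-one to a spike of the
# same neuron in b within `jitter` ms.
spike_agreement <- function(a, b, jitter = 1) {
  if (length(a$time) == 0 && length(b$time) == 0) return(1)
  matched <- 0
  for (id in unique(c(a$id, b$id))) {
    ta <- a$time[a$id == id]
    tb <- b$time[b$id == id]
    for (x in ta) {
      hit <- which(abs(tb - x) <= jitter)
      if (length(hit)) {
        tb <- tb[-hit[1]]
        matched <- matched + 1
      }
    }
  }
  matched / max(length(a$time), length(b$time))
}

# Tiny two-population network with dyadic weights for exact engine
# comparisons.
tiny_network <- function(n_e = 80, n_i = 20, n_src = 20, p = 0.3,
                         w_e = 0.0625, w_i = -0.25, w_src = 0.0625,
                         seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  bld <- barrelsim:::new_model_builder()
  barrelsim:::add_population(bld, "E", "L4", "excitatory", n_e, "L4E")
  barrelsim:::add_population(bld, "I", "L4", "inhibitory", n_i, "L4E")
  barrelsim:::add_population(bld, "src", "thalamus", "source", n_src, NA)
  barrelsim:::add_projection(bld, "src", "E", p, w_src)
  barrelsim:::add_projection(bld, "src", "I", p, w_src)
  barrelsim:::add_projection(bld, "E", "E", p, w_e)
  barrelsim:::add_projection(bld, "E", "I", p, w_e)
  barrelsim:::add_projection(bld, "I", "E", p, w_i)
  barrelsim:::add_projection(bld, "I", "I", p, w_i)
  barrelsim:::finish_model(bld, "tiny", barrelsim:::standard_params(),
                           list(seed = seed, b = NA, w_e = w_e,
                                i2e_scale = 1, w_tc = w_src, scale = NA))
}
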