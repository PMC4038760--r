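#' Leaky integrate-and-fire neuron parameters
#'
#' Constructs the biophysical constant set of a LIF neuron with two
#' exponential-current synaptic accumulators. Defaults are the published
#' paired-recording values for the excitatory cells of the granular (L4) and
#' supragranular (L2/3) layers of the rat barrel column; inhibitory cells use
#' their layer's excitatory parameters.
#'
#' Units are fixed throughout the package: potentials in mV, currents in nA,
#' resistances in MOhm, times in ms, so that `R_m * I` is directly a voltage
#' (MOhm * nA = mV).
#'
#' @param layer `"L4E"` or `"L23E"`, selecting the default column.
#' @param E_L equilibrium (leak reversal) potential, mV.
#' @param V_reset post-spike reset potential, mV. Must be below `V_theta`.
#' @param V_theta spike threshold, mV.
#' @param tau_m membrane time constant, ms.
#' @param R_m membrane resistance, MOhm.
#' @param tau_se excitatory synaptic-current time constant, ms.
#' @param tau_si inhibitory synaptic-current time constant, ms.
#' @param t_ref absolute refractory period, ms.
#' @return An object of class `neuron_params` (named list of the eight
#'   constants plus the layer label).
#' @examples
#' neuron_params("L4E")
#' neuron_params("L23E")$tau_m
#' @export
neuron_params <- function(layer = c("L4E", "L23E"),
                          E_L = NULL, V_reset = NULL, V_theta = -40,
                          tau_m = NULL, R_m = NULL,
                          tau_se = 5, tau_si = 15, t_ref = 10) {
  layer <- match.arg(layer)
  defaults <- switch(layer,
    L4E  = list(E_L = -66, V_reset = -66, tau_m = 35, R_m = 300),
    L23E = list(E_L = -72, V_reset = -72, tau_m = 30, R_m = 190))
  if (is.null(E_L)) E_L <- defaults$E_L
  if (is.null(V_reset)) V_reset <- defaults$V_reset
  if (is.null(tau_m)) tau_m <- defaults$tau_m
  if (is.null(R_m)) R_m <- defaults$R_m
  p <- list(layer = layer, E_L = E_L, V_reset = V_reset, V_theta = V_theta,
            tau_m = tau_m, R_m = R_m, tau_se = tau_se, tau_si = tau_si,
            t_ref = t_ref)
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  stopifnot(p$tau_m > 0, p$tau_se > 0, p$tau_si > 0, p$R_m > 0, p$t_ref >= 0)
  if (p$V_reset >= p$V_theta)
    stop("invalid neuron parameters: V_reset must lie below V_theta",
         call. = FALSE)
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("LIF neuron parameters [%s]\n", x$layer))
  cat(sprintf("  E_L %g mV, V_reset %g mV, V_theta %g mV\n",
              x$E_L, x$V_reset, x$V_theta))
  cat(sprintf("  tau_m %g ms, R_m %g MOhm, tau_se %g ms, tau_si %g ms, t_ref %g ms\n",
              x$tau_m, x$R_m, x$tau_se, x$tau_si, x$t_ref))
  invisible(x)
}

#' Neuron state of a single LIF cell
#'
#' Bundles the dynamical variables advanced by the 1-ms update: membrane
#' potential, the two synaptic-current accumulators (excitatory non-negative,
#' inhibitory non-positive), and the remaining refractory time.
#'
#' @param V membrane potential, mV.
#' @param I_e excitatory synaptic current, nA (>= 0).
#' @param I_i inhibitory synaptic current, nA (<= 0).
#' @param refrac_remaining remaining refractory time, ms (>= 0).
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V, I_e = 0, I_i = 0, refrac_remaining = 0) {
  if (I_e < 0) stop("I_e must be non-negative", call. = FALSE)
  if (I_i > 0) stop("I_i must be non-positive", call. = FALSE)
  if (refrac_remaining < 0) stop("refrac_remaining must be >= 0", call. = FALSE)
  structure(list(V = V, I_e = I_e, I_i = I_i,
                 refrac_remaining = refrac_remaining),
            class = "neuron_state")
}

# Published per-column population sizes (thalamic barreloid + two cortical
# layers, excitatory/inhibitory split at 15%).
POPULATION_SIZES <- list(
  L23E = 4507, L23I = 795,
  L4E  = 3471, L4I  = 613,
  thalamus = 285)

#' Standard population sizes of one barrel column
#'
#' Neuron counts per population of the standard model: layer 2/3 (4507
#' excitatory, 795 inhibitory), layer 4 (3471/613) and the thalamic barreloid
#' (285 Poisson sources). `scale` shrinks every population proportionally
#' (rounded, minimum 1) for scaled-down runs; connection probabilities are
#' never scaled, and balance weights are recomputed from the scaled counts by
#' the builders.
#'
#' @param scale positive multiplier applied to all sizes.
#' @return Named integer vector.
#' @export
population_sizes <- function(scale = 1) {
  stopifnot(scale > 0)
  sz <- vapply(POPULATION_SIZES, function(n) max(1L, as.integer(round(n * scale))),
               integer(1))
  sz
}
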