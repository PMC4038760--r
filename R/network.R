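#' Balanced inhibitory synaptic weight
#'
#' Magnitude of the inhibitory weight that balances postsynaptic-current
#' charge against excitation in a sparsely connected two-population network.
#' The Brunel condition `w_i = b w_e N_e/N_i` equates total excitatory and
#' inhibitory synaptic drive at balance coefficient `b = 1`; with unequal
#' synaptic time constants the balanced quantity is the PSC charge
#' `w tau_s`, giving
#' `|w_i| = b w_e (tau_se/tau_si) (N_e/N_i)`.
#' The returned value is a magnitude; the builders negate it when storing
#' inhibitory projection weights.
#'
#' @param b balance coefficient (dimensionless, >= 0). `b < 1` lets
#'   recurrent excitation dominate (hyperactivity), `b > 1` lets inhibition
#'   dominate (hypoactivity).
#' @param w_e excitatory synaptic weight, nA.
#' @param N_e,N_i excitatory / inhibitory neuron counts (`N_i > 0`).
#' @param tau_se,tau_si excitatory / inhibitory synaptic time constants, ms.
#' @return Inhibitory weight magnitude, nA.
#' @examples
#' inhibitory_weight(1, 0.1, 3471, 613, 5, 15)  # L4 balance point
#' @export
inhibitory_weight <- function(b, w_e, N_e, N_i, tau_se = 5, tau_si = 15) {
  stopifnot(b >= 0, N_i > 0, tau_si > 0, tau_se > 0)
  b * w_e * (tau_se / tau_si) * (N_e / N_i)
}

#' Sample one probabilistic projection
#'
#' Connects every ordered (pre, post) pair independently with probability
#' `p`, including self-pairs when pre and post are the same population, so
#' the expected synapse count of a recurrent two-population network with
#' uniform `p` is `p (N_e + N_i)^2`. Sampling is bit-stable: the same seed
#' always yields the same synapse set.
#'
#' @param n_pre,n_post population sizes.
#' @param p connection probability in `[0, 1]`.
#' @param w synaptic weight, nA (signed; negative weights target the
#'   inhibitory accumulator).
#' @param delay conduction delay, ms (the engine delivers all spikes with a
#'   one-step delay; only `delay = 1` is supported).
#' @param seed optional integer seed; if `NULL`, the current RNG stream is
#'   used (and advanced).
#' @return A connection set: list with 0-based integer vectors `pre`,
#'   `post`, scalar `w`, `p`, `delay`, `n_pre`, `n_post`.
#' @export
sample_projection <- function(n_pre, n_post, p, w = 0.1, delay = 1,
                              seed = NULL) {
  stopifnot(n_pre > 0, n_post > 0, p >= 0, p <= 1)
  if (delay != 1)
    stop("only the one-step (1 ms) conduction delay is supported", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  cs <- cpp_sample_pairs(as.integer(n_pre), as.integer(n_post), p)
  list(pre = cs$pre, post = cs$post, w = w, p = p, delay = delay,
       n_pre = as.integer(n_pre), n_post = as.integer(n_post))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# internal builder state -----------------------------------------------------

new_model_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$populations <- list()
  env$projections <- list()
  env$next_id <- 0L
  env
}

add_population <- function(bld, name, layer, polarity, size, param_set = NA) {
  bld$populations[[name]] <- list(
    name = name, layer = layer, polarity = polarity, size = as.integer(size),
    first_id = bld$next_id, param_set = param_set)
  bld$next_id <- bld$next_id + as.integer(size)
  invisible(bld)
}

add_projection <- function(bld, pre, post, p, w, name = NULL) {
  pp <- bld$populations[[pre]]
  qq <- bld$populations[[post]]
  if (is.null(pp) || is.null(qq)) stop("unknown population in projection")
  cs <- sample_projection(pp$size, qq$size, p, w)
  if (is.null(name)) name <- paste0(pre, "->", post)
  bld$projections[[length(bld$projections) + 1L]] <- list(
    name = name, pre_pop = pre, post_pop = post, p = p, w = w, delay = 1,
    n_pre = pp$size, n_post = qq$size,
    pre = cs$pre + pp$first_id, post = cs$post + qq$first_id)
  invisible(bld)
}

finish_model <- function(bld, kind, params, provenance) {
  pops <- do.call(rbind, lapply(bld$populations, function(p)
    data.frame(name = p$name, layer = p$layer, polarity = p$polarity,
               size = p$size, first_id = p$first_id,
               param_set = p$param_set, stringsAsFactors = FALSE)))
  rownames(pops) <- NULL
  structure(list(kind = kind, populations = pops, params = params,
                 projections = bld$projections,
                 n_neurons = bld$next_id, provenance = provenance),
            class = "barrel_network")
}

# Shared construction of one barrel column's populations and projections.
# layers = "L4" builds a bare barrel; c("L4", "L23") a full column.
# prefix distinguishes columns in the chain model.
build_column_into <- function(bld, b, w_e, i2e_scale, w_tc, scale,
                              layers = c("L4", "L23"), prefix = "",
                              intracortical = TRUE, w_interlayer = 0.2,
                              p_tc = 0.25, p_cc = 0.1) {
  sz <- population_sizes(scale)
  nm <- function(x) paste0(prefix, x)
  if ("L23" %in% layers) {
    add_population(bld, nm("L23E"), "L2/3", "excitatory", sz[["L23E"]], "L23E")
    add_population(bld, nm("L23I"), "L2/3", "inhibitory", sz[["L23I"]], "L23E")
  }
  add_population(bld, nm("L4E"), "L4", "excitatory", sz[["L4E"]], "L4E")
  add_population(bld, nm("L4I"), "L4", "inhibitory", sz[["L4I"]], "L4E")
  add_population(bld, nm("thalamus"), "thalamus", "source", sz[["thalamus"]], NA)

  add_projection(bld, nm("thalamus"), nm("L4E"), p_tc, w_tc)
  add_projection(bld, nm("thalamus"), nm("L4I"), p_tc, w_tc)

  if (intracortical) {
    w_i4 <- inhibitory_weight(b, w_e, sz[["L4E"]], sz[["L4I"]])
    add_projection(bld, nm("L4E"), nm("L4E"), p_cc, w_e)
    add_projection(bld, nm("L4E"), nm("L4I"), p_cc, w_e)
    add_projection(bld, nm("L4I"), nm("L4E"), p_cc, -w_i4 * i2e_scale)
    add_projection(bld, nm("L4I"), nm("L4I"), p_cc, -w_i4)
    if ("L23" %in% layers) {
      w_i23 <- inhibitory_weight(b, w_e, sz[["L23E"]], sz[["L23I"]])
      add_projection(bld, nm("L23E"), nm("L23E"), p_cc, w_e)
      add_projection(bld, nm("L23E"), nm("L23I"), p_cc, w_e)
      add_projection(bld, nm("L23I"), nm("L23E"), p_cc, -w_i23 * i2e_scale)
      add_projection(bld, nm("L23I"), nm("L23I"), p_cc, -w_i23)
      add_projection(bld, nm("L4E"), nm("L23E"), p_cc, w_interlayer)
      add_projection(bld, nm("L4E"), nm("L23I"), p_cc, w_interlayer)
    }
  }
  invisible(bld)
}

standard_params <- function() {
  list(L4E = neuron_params("L4E"), L23E = neuron_params("L23E"))
}

#' Build the single-barrel network
#'
#' One granular-layer barrel: excitatory (L4E, 3471) and inhibitory (L4I,
#' 613) populations with all-to-all-probabilistic recurrent projections at
#' `p = 0.1`, driven by a 285-source thalamic barreloid connected to both
#' cortical populations at `p = 0.25` with weight `w_tc`. The excitatory
#' intracortical weight is `w_e`; the inhibitory weight magnitude follows the
#' extended balance condition (see [inhibitory_weight()]) at coefficient
#' `b`, with the inhibitory-to-excitatory projection additionally scaled by
#' `i2e_scale` (1.5 holds excitatory firing near 1 Hz at `b = 1`; the
#' balance-sweep protocol uses 1).
#'
#' @param b balance coefficient.
#' @param w_e excitatory intracortical weight, nA.
#' @param i2e_scale multiplier on the I-to-E weight only.
#' @param w_tc thalamocortical weight, nA; see [calibrate_tc_weight()].
#' @param seed integer seed fixing the sampled connectivity.
#' @param scale population-size multiplier for scaled-down models
#'   (probabilities unchanged; balance recomputed from scaled counts).
#' @param intracortical if `FALSE`, omit all intracortical projections (the
#'   configuration used for thalamocortical weight calibration).
#' @return A `barrel_network` object.
#' @export
build_barrel <- function(b = 1, w_e = 0.1, i2e_scale = 1.5, w_tc = 0.03,
                         seed = 1, scale = 1, intracortical = TRUE) {
  stopifnot(b >= 0, w_e > 0, i2e_scale > 0, w_tc >= 0)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  bld <- new_model_builder()
  build_column_into(bld, b, w_e, i2e_scale, w_tc, scale, layers = "L4",
                    intracortical = intracortical)
  finish_model(bld, "barrel", standard_params(),
               list(seed = seed, b = b, w_e = w_e, i2e_scale = i2e_scale,
                    w_tc = w_tc, scale = scale, intracortical = intracortical))
}

#' Build one full barrel column
#'
#' Extends the barrel with the supragranular layer: L2/3E (4507) and L2/3I
#' (795) with their own recurrent `p = 0.1` projections and balance-derived
#' inhibition (computed from the L2/3 counts), plus interlayer projections
#' L4E -> L2/3E and L4E -> L2/3I at `p = 0.1`, weight `w_interlayer`
#' (0.2 nA). The `i2e_scale` factor applies to the I-to-E projection of both
#' layers.
#'
#' @inheritParams build_barrel
#' @param w_interlayer granular-to-supragranular weight, nA.
#' @return A `barrel_network` object (9671 neurons at full scale).
#' @export
build_column <- function(b = 1, w_e = 0.1, i2e_scale = 1.5, w_tc = 0.03,
                         seed = 1, scale = 1, w_interlayer = 0.2) {
  stopifnot(b >= 0, w_e > 0, i2e_scale > 0, w_tc >= 0)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  bld <- new_model_builder()
  build_column_into(bld, b, w_e, i2e_scale, w_tc, scale,
                    w_interlayer = w_interlayer)
  finish_model(bld, "column", standard_params(),
               list(seed = seed, b = b, w_e = w_e, i2e_scale = i2e_scale,
                    w_tc = w_tc, scale = scale, w_interlayer = w_interlayer))
}

#' Build a laterally connected chain of barrel columns
#'
#' `n_columns` independent barrel columns (see [build_column()]) whose
#' supragranular excitatory populations form lateral projections to their
#' immediate neighbours in both directions at `p = 0.1`, weight `w_lateral`
#' (0.1 nA). There is no wraparound: the chain has free ends. Population
#' names are prefixed `c<k>.` for column k = 0..n_columns-1.
#'
#' @inheritParams build_column
#' @param n_columns number of columns (>= 1; a single column has no lateral
#'   projections).
#' @param w_lateral lateral L2/3E -> L2/3E weight, nA.
#' @return A `barrel_network` object (48,355 neurons for five full-scale
#'   columns).
#' @export
build_chain <- function(n_columns = 5, b = 1, w_e = 0.1, i2e_scale = 1.5,
                        w_tc = 0.03, seed = 1, scale = 1,
                        w_interlayer = 0.2, w_lateral = 0.1) {
  stopifnot(n_columns >= 1)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  bld <- new_model_builder()
  for (k in seq_len(n_columns) - 1L)
    build_column_into(bld, b, w_e, i2e_scale, w_tc, scale,
                      prefix = sprintf("c%d.", k), w_interlayer = w_interlayer)
  if (n_columns >= 2) {
    for (k in seq_len(n_columns - 1L) - 1L) {
      a <- sprintf("c%d.L23E", k)
      bb <- sprintf("c%d.L23E", k + 1L)
      add_projection(bld, a, bb, 0.1, w_lateral)
      add_projection(bld, bb, a, 0.1, w_lateral)
    }
  }
  finish_model(bld, "chain", standard_params(),
               list(seed = seed, b = b, w_e = w_e, i2e_scale = i2e_scale,
                    w_tc = w_tc, scale = scale, n_columns = n_columns,
                    w_interlayer = w_interlayer, w_lateral = w_lateral))
}

#' Expected synapse count of a network model
#'
#' Sum over projection groups of `p * n_pre * n_post` — the exact expectation
#' of the independent-Bernoulli connectivity, computed arithmetically without
#' sampling. For a recurrent two-population group with uniform `p` this is
#' Brunel's `p (N_e + N_i)^2` count.
#'
#' @param model a `barrel_network`.
#' @param by_projection if `TRUE`, return the per-group expectations as a
#'   named vector instead of the total.
#' @return Expected synapse count (numeric; generally non-integer).
#' @export
expected_synapse_count <- function(model, by_projection = FALSE) {
  v <- vapply(model$projections,
              function(pr) pr$p * pr$n_pre * pr$n_post, numeric(1))
  names(v) <- vapply(model$projections, `[[`, character(1), "name")
  if (by_projection) v else sum(v)
}

#' @export
print.barrel_network <- function(x, ...) {
  cat(sprintf("barrel_network [%s]: %d neurons, %d projection groups\n",
              x$kind, x$n_neurons, length(x$projections)))
  cat(sprintf("  expected synapses: %.0f (realized: %d)\n",
              expected_synapse_count(x),
              sum(vapply(x$projections, function(p) length(p$pre), integer(1)))))
  cat(sprintf("  b = %g, w_e = %g nA, i2e_scale = %g, w_tc = %g nA, seed = %d\n",
              x$provenance$b, x$provenance$w_e, x$provenance$i2e_scale,
              x$provenance$w_tc, x$provenance$seed))
  invisible(x)
}

#' @export
summary.barrel_network <- function(object, ...) {
  cat(sprintf("barrel_network [%s], %d neurons\n", object$kind,
              object$n_neurons))
  print(object$populations)
  cat("\nProjections:\n")
  pr <- data.frame(
    name = vapply(object$projections, `[[`, character(1), "name"),
    p = vapply(object$projections, `[[`, numeric(1), "p"),
    w_nA = vapply(object$projections, `[[`, numeric(1), "w"),
    synapses = vapply(object$projections, function(p) length(p$pre), integer(1)))
  print(pr, row.names = FALSE)
  invisible(object)
}

# Resolve a population name to its (first_id, size); NULL name = all cortical
population_range <- function(model_or_pops, population = NULL) {
  pops <- if (inherits(model_or_pops, "barrel_network"))
    model_or_pops$populations else model_or_pops
  if (is.null(population)) return(pops)
  row <- pops[pops$name == population, , drop = FALSE]
  if (nrow(row) == 0)
    stop(sprintf("unknown population '%s'", population), call. = FALSE)
  row
}
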