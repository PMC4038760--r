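test_that("an undriven network at equilibrium stays silent", {
  m <- tiny_network(seed = 2)
  rec <- run_simulation(m, NULL, 200)
  expect_length(rec$time, 0)
})

test_that("spikes act on their targets one step later, never the same step", {
  # src -> A (strong), A -> B (strong): delivery chain with 1-ms delay
  bld <- barrelsim:::new_model_builder()
  barrelsim:::add_population(bld, "A", "L4", "excitatory", 1, "L4E")
  barrelsim:::add_population(bld, "B", "L4", "excitatory", 1, "L4E")
  barrelsim:::add_population(bld, "src", "thalamus", "source", 1, NA)
  barrelsim:::add_projection(bld, "src", "A", 1, 5)  # suprathreshold kick
  barrelsim:::add_projection(bld, "A", "B", 1, 5)
  m <- barrelsim:::finish_model(bld, "tiny", barrelsim:::standard_params(),
                                list(seed = 0, b = NA, w_e = NA,
                                     i2e_scale = 1, w_tc = NA))
  stim <- spike_record(5L, 2L, 100,
                       data.frame(name = "src", first_id = 2L, size = 1L))
  rec <- run_simulation(m, stim, 100)
  tA <- rec$time[rec$id == 0]
  tB <- rec$time[rec$id == 1]
  expect_equal(tA[1], 5)       # source spike at 5 acts at step 5
  expect_equal(tB[1], 6)       # A's spike acts one full step later
})

test_that("constant suprathreshold current yields the refractory-limited rate", {
  bld <- barrelsim:::new_model_builder()
  barrelsim:::add_population(bld, "A", "L4", "excitatory", 1, "L4E")
  m <- barrelsim:::finish_model(bld, "tiny", barrelsim:::standard_params(),
                                list(seed = 0, b = NA, w_e = NA,
                                     i2e_scale = 1, w_tc = NA))
  rec <- run_simulation(m, NULL, 1000, i_offset = 5)
  expect_equal(mean_rate(rec, "A"), 1000 / 10)  # exactly 100 Hz
  isi <- diff(rec$time)
  expect_true(all(isi == 10))                   # ISI pinned at t_ref
})

test_that("interspike intervals never fall below the refractory period", {
  m <- tiny_network(seed = 3)
  stim <- generate_spikes(20, 80, 1000, seed = 4, first_id = 100,
                          population = "src")
  rec <- run_simulation(m, stim, 1000)
  expect_gt(length(rec$time), 0)
  for (id in unique(rec$id)) {
    ts <- rec$time[rec$id == id]
    if (length(ts) > 1) expect_true(all(diff(ts) >= 10))
  }
})

test_that("runs are deterministic and trials are order-independent", {
  m <- tiny_network(seed = 5)
  stim <- generate_spikes(20, 60, 500, seed = 6, first_id = 100,
                          population = "src")
  r1 <- run_simulation(m, stim, 500)
  r2 <- run_simulation(m, stim, 500)
  expect_identical(r1$time, r2$time)
  expect_identical(r1$id, r2$id)
  # run_trials: identical connectivity, differing stimuli, reproducible
  sfn <- function(s) generate_spikes(20, 60, 500, seed = s, first_id = 100,
                                     population = "src")
  a <- run_trials(m, sfn, n_trials = 3, duration = 500, seed = 9)
  b <- run_trials(m, sfn, n_trials = 3, duration = 500, seed = 9)
  for (k in 1:3) {
    expect_identical(a[[k]]$time, b[[k]]$time)
    expect_identical(a[[k]]$id, b[[k]]$id)
  }
  # pairwise different stimulus realizations
  expect_false(identical(a[[1]]$time, a[[2]]$time) &&
                 identical(a[[1]]$id, a[[2]]$id))
  # any single trial reproduces in isolation from its own seed
  s3 <- attr(a, "trial_seeds")[3]
  solo <- run_simulation(m, sfn(s3), 500)
  expect_identical(solo$time, a[[3]]$time)
  expect_identical(solo$id, a[[3]]$id)
})

test_that("the engine agrees with an independent plain-R network simulation", {
  m <- tiny_network(n_e = 80, n_i = 20, n_src = 20, seed = 10)
  stim <- generate_spikes(20, 60, 1000, seed = 11, first_id = 100,
                          population = "src")
  fast <- run_simulation(m, stim, 1000)
  slow <- reference_net_run(m, stim, 1000)
  expect_gt(length(fast$time), 20)
  expect_lte(abs(length(slow$time) - length(fast$time)),
             max(2, 0.01 * length(fast$time)))
  expect_gte(spike_agreement(fast, slow, jitter = 1), 0.99)
})

test_that("input validation: short stimulus and bad states are rejected", {
  m <- tiny_network(seed = 12)
  stim <- generate_spikes(20, 60, 100, seed = 13, first_id = 100,
                          population = "src")
  expect_error(run_simulation(m, stim, 500), "shorter")
  expect_error(run_simulation(m, NULL, 100, v_init = rep(NaN, m$n_neurons)),
               "non-finite")
})
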