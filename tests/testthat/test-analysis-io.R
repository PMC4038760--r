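pops2 <- function() data.frame(name = c("A", "B"),
                               first_id = c(0L, 100L), size = c(100L, 50L))

test_that("mean rate normalizes by population size and window length", {
  rec <- spike_record(seq(0, 99), rep(0:1, 50), 1000, pops2())
  expect_equal(mean_rate(rec, "A", c(0, 1000)), 100 / (100 * 1)) # 1 Hz
  empty <- spike_record(integer(0), integer(0), 1000, pops2())
  expect_equal(mean_rate(empty, "A"), 0)
  expect_error(mean_rate(rec, "A", c(10, 10)), "window")
  expect_error(mean_rate(rec, "missing"), "unknown population")
  # duration-weighted partition equals the rate over the union
  w <- list(c(0, 250), c(250, 600), c(600, 1000))
  parts <- vapply(w, function(x) mean_rate(rec, "A", x), numeric(1))
  weights <- vapply(w, diff, numeric(1))
  expect_equal(sum(parts * weights) / sum(weights),
               mean_rate(rec, "A", c(0, 1000)))
})

test_that("PSTH normalization gives Hz per neuron per presentation", {
  # one spike per neuron at alignment + 2 ms, 500 neurons, one trial:
  # first 5-ms bin holds one spike per neuron -> 1/0.005 s = 200 Hz
  pops <- data.frame(name = "P", first_id = 0L, size = 500L)
  rec <- spike_record(rep(102L, 500), 0:499, 1000, pops)
  ps <- psth(rec, "P", align_times = 100, bin_width = 5, window = c(0, 50))
  expect_equal(ps$rate[1], 200)
  expect_true(all(ps$rate[-1] == 0))
  # empty records give an all-zero PSTH
  empty <- spike_record(integer(0), integer(0), 1000, pops)
  expect_true(all(psth(empty, "P", 100)$rate == 0))
  # duplicating identical trials leaves rates unchanged
  ps2 <- psth(list(rec, rec), "P", 100, 5, c(0, 50))
  expect_equal(ps2$rate, ps$rate)
  expect_error(psth(rec, "P", align_times = numeric(0)), "alignment")
  # conservation: integral x neurons x presentations recovers the count
  set.seed(1)
  rec2 <- spike_record(sample(0:999, 300, TRUE), sample(0:499, 300, TRUE),
                       1000, pops)
  ps3 <- psth(rec2, "P", 0, 10, c(0, 1000))
  expect_equal(sum(ps3$rate * ps3$bin_width / 1000) * 500 * 1, 300,
               tolerance = 1e-12)
  expect_equal(sum(ps3$counts), 300)
})

test_that("windowed counts use half-open windows per neuron", {
  pops <- data.frame(name = "P", first_id = 0L, size = 3L)
  rec <- spike_record(c(10L, 34L, 35L, 60L), c(0L, 0L, 1L, 2L), 100, pops)
  cm <- window_counts(rec, onset_times = 10, width = 25)
  expect_equal(as.integer(cm), c(2L, 0L, 0L))  # 35 excluded: [10, 35)
  expect_equal(sum(window_counts(rec, numeric(0))), 0)
  cm2 <- window_counts(rec, c(10, 60), width = 25)
  expect_equal(as.integer(cm2), c(2L, 0L, 1L))
  # a neuron spiking once in each window accumulates across onsets
  rec3 <- spike_record(as.integer(seq(0, 96, by = 4)), rep(0L, 25), 100,
                       data.frame(name = "P", first_id = 0L, size = 1L))
  expect_equal(as.integer(window_counts(rec3, seq(0, 96, by = 4), width = 4)),
               25L)
})

test_that("spike files round-trip losslessly and reject malformed input", {
  rec <- spike_record(c(0L, 5L, 5L, 9L), c(3L, 1L, 2L, 0L), 50, pops2())
  path <- withr::local_tempfile(fileext = ".spk")
  write_spikes(rec, path)
  back <- read_spikes(path)
  expect_identical(back$time, rec$time)
  expect_identical(back$id, rec$id)
  expect_equal(back$duration, rec$duration)
  expect_equal(back$populations, rec$populations)
  # empty record with a valid header
  write_spikes(spike_record(integer(0), integer(0), 50, pops2()), path)
  expect_length(read_spikes(path)$time, 0)
  # malformed lines raise parse errors with the line number
  writeLines(c("# barrelsim spikes v1", "# duration 50", "# dt 1",
               "# population A 0 100", "5\t1", "-3\t2"), path)
  expect_error(read_spikes(path), "line 6")
  writeLines(c("# barrelsim spikes v1", "# duration 50", "# dt 1",
               "# population A 0 100", "5\tx"), path)
  expect_error(read_spikes(path), "parse error")
  # unsorted times are a format error
  writeLines(c("# barrelsim spikes v1", "# duration 50", "# dt 1",
               "# population A 0 100", "9\t1", "5\t2"), path)
  expect_error(read_spikes(path), "sorted")
})

test_that("config files round-trip the full parameter set", {
  cfg <- default_config()
  expect_equal(cfg$n_L4E, 3471)
  expect_equal(cfg$L4E_R_m, 300)
  expect_equal(cfg$p_tc, 0.25)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back[names(cfg)], cfg)
})

test_that("spike records validate their invariants", {
  expect_error(spike_record(c(-1L), c(0L), 10), "\\[0, duration\\)")
  expect_error(spike_record(c(11L), c(0L), 10), "\\[0, duration\\)")
  r <- spike_record(c(5L, 2L), c(1L, 0L), 10)
  expect_false(is.unsorted(r$time))  # construction sorts by time
})
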