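# Expensive shared fixtures, computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

# Calibrated thalamocortical weight for the full-scale model (6-Hz drive).
cached_w_tc <- function() {
  if (is.null(.fixture_cache$w_tc))
    .fixture_cache$w_tc <- as.numeric(calibrate_tc_weight(6, seed = 1))
  .fixture_cache$w_tc
}
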