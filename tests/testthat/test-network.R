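test_that("balanced inhibitory weight follows the extended Brunel relation", {
  expect_equal(inhibitory_weight(1, 0.1, 3471, 613, 5, 15), 0.1887439,
               tolerance = 1e-6)
  expect_equal(inhibitory_weight(0, 0.1, 3471, 613), 0)
  # symmetric case reduces to w_e
  expect_equal(inhibitory_weight(1, 0.1, 500, 500, 7, 7), 0.1)
  # equal time constants reduce to the plain Brunel relation b w_e Ne/Ni
  for (b in c(0.1, 1, 10))
    expect_equal(inhibitory_weight(b, 0.1, 3471, 613, 9, 9),
                 b * 0.1 * 3471 / 613)
  # the balanced PSC-charge identity holds exactly for arbitrary inputs
  for (k in 1:20) {
    b <- runif(1, 0.1, 10); we <- runif(1, 0.01, 1)
    ne <- sample(100:5000, 1); ni <- sample(50:1000, 1)
    tse <- runif(1, 1, 10); tsi <- runif(1, 5, 30)
    wi <- inhibitory_weight(b, we, ne, ni, tse, tsi)
    expect_equal(wi * tsi, b * we * tse * ne / ni, tolerance = 1e-12)
  }
})

test_that("projection sampling matches independent-Bernoulli statistics", {
  expect_length(sample_projection(10, 10, 0, seed = 1)$pre, 0)
  cs <- sample_projection(3, 4, 1, seed = 1)
  expect_length(cs$pre, 12)  # all ordered pairs, self-pairs included
  expect_equal(sort(unique(cs$pre)), 0:2)
  expect_equal(sort(unique(cs$post)), 0:3)
  # binomial count band over repeated seeds at the thalamocortical geometry
  n <- 285 * 4084
  sd_b <- sqrt(n * 0.25 * 0.75)
  counts <- vapply(1:20, function(s)
    length(sample_projection(285, 4084, 0.25, seed = s)$pre), numeric(1))
  expect_true(all(abs(counts - n * 0.25) < 4 * sd_b))
  # bit-stable under the seed
  a <- sample_projection(50, 60, 0.1, seed = 99)
  b <- sample_projection(50, 60, 0.1, seed = 99)
  expect_identical(a$pre, b$pre)
  expect_identical(a$post, b$post)
  # indices in range
  expect_true(all(a$pre >= 0 & a$pre < 50))
  expect_true(all(a$post >= 0 & a$post < 60))
})

test_that("barrel model has the standard populations, weights and counts", {
  m <- build_barrel(b = 1, i2e_scale = 1, w_tc = 0.03, seed = 4)
  sz <- setNames(m$populations$size, m$populations$name)
  expect_equal(sz[["L4E"]], 3471)
  expect_equal(sz[["L4I"]], 613)
  expect_equal(sz[["thalamus"]], 285)
  pr <- m$projections
  names(pr) <- vapply(pr, `[[`, character(1), "name")
  expect_equal(pr[["L4I->L4E"]]$w, -0.1887439, tolerance = 1e-6)
  expect_equal(pr[["L4I->L4I"]]$w, -0.1887439, tolerance = 1e-6)
  expect_equal(pr[["L4E->L4E"]]$w, 0.1)
  expect_equal(pr[["thalamus->L4E"]]$p, 0.25)
  expect_equal(pr[["L4E->L4E"]]$p, 0.1)
  # the 1.5x scaling applies to I->E only
  m2 <- build_barrel(b = 1, i2e_scale = 1.5, w_tc = 0.03, seed = 4)
  pr2 <- m2$projections
  names(pr2) <- vapply(pr2, `[[`, character(1), "name")
  expect_equal(pr2[["L4I->L4E"]]$w, -1.5 * 0.1887439, tolerance = 1e-6)
  expect_equal(pr2[["L4I->L4I"]]$w, -0.1887439, tolerance = 1e-6)
  # expected counts: Brunel p(Ne+Ni)^2 intracortical plus thalamocortical
  v <- expected_synapse_count(m, by_projection = TRUE)
  expect_equal(sum(v[c("L4E->L4E", "L4E->L4I", "L4I->L4E", "L4I->L4I")]),
               0.1 * (3471 + 613)^2)
  expect_equal(sum(v[c("thalamus->L4E", "thalamus->L4I")]), 290985)
  expect_equal(expected_synapse_count(m), 1958890.6)
})

test_that("column model adds the supragranular layer per the architecture", {
  m <- build_column(w_tc = 0.03, seed = 5, i2e_scale = 1)
  sz <- setNames(m$populations$size, m$populations$name)
  expect_equal(sz[["L23E"]], 4507)
  expect_equal(sz[["L23I"]], 795)
  expect_equal(m$n_neurons, 9671)
  pr <- m$projections
  names(pr) <- vapply(pr, `[[`, character(1), "name")
  # L2/3 balance uses the supragranular counts
  expect_equal(pr[["L23I->L23E"]]$w, -0.1889727, tolerance = 1e-6)
  # interlayer projections: granular excitatory to both supragranular pops
  expect_equal(pr[["L4E->L23E"]]$w, 0.2)
  expect_equal(pr[["L4E->L23I"]]$w, 0.2)
  expect_equal(pr[["L4E->L23E"]]$p, 0.1)
  # supragranular neuron parameters
  expect_equal(m$populations$param_set[m$populations$name == "L23E"], "L23E")
  expect_equal(m$params$L23E$tau_m, 30)
  expect_equal(m$params$L23E$E_L, -72)
})

test_that("chain model wires bidirectional laterals without wraparound", {
  m <- build_chain(n_columns = 5, w_tc = 0.03, seed = 6, scale = 0.1)
  nm <- vapply(m$projections, `[[`, character(1), "name")
  ee <- grepl("^c[0-9]+\\.L23E->c[0-9]+\\.L23E$", nm)
  from <- sub("^c([0-9]+)\\..*$", "\\1", nm)
  to <- sub("^.*->c([0-9]+)\\..*$", "\\1", nm)
  lat <- nm[ee & from != to]
  expect_length(lat, 8)  # 4 neighbour pairs x 2 directions
  expect_true("c0.L23E->c1.L23E" %in% lat)
  expect_true("c1.L23E->c0.L23E" %in% lat)
  expect_false("c4.L23E->c0.L23E" %in% lat)  # free ends
  for (p in m$projections[nm %in% lat]) {
    expect_equal(p$w, 0.1)
    expect_equal(p$p, 0.1)
  }
  # single column: no laterals (no projection crosses a column boundary)
  m1 <- build_chain(n_columns = 1, w_tc = 0.03, seed = 6, scale = 0.1)
  nm1 <- vapply(m1$projections, `[[`, character(1), "name")
  cross <- grepl("->c", nm1) &
    sub("^c([0-9]+)\\..*$", "\\1", nm1) !=
      sub("^.*->c([0-9]+)\\..*$", "\\1", nm1)
  expect_equal(sum(cross), 0)
  # full-scale totals are pure arithmetic
  expect_equal(5 * 9671, 48355)
  expect_equal(5 * (0.1 * 4084^2 + 0.1 * 5302^2 + 0.1 * 3471 * 5302 +
                      0.25 * 285 * 4084) + 8 * 0.1 * 4507^2,
               49302115.2)
})

test_that("global neuron indices form a bijection onto 0..N-1", {
  m <- build_chain(n_columns = 3, w_tc = 0.03, seed = 7, scale = 0.05)
  ids <- unlist(lapply(seq_len(nrow(m$populations)), function(k)
    m$populations$first_id[k] + seq_len(m$populations$size[k]) - 1L))
  expect_equal(sort(ids), 0:(m$n_neurons - 1L))
  # rebuilding with the same seed reproduces the connectivity bit-for-bit
  m2 <- build_chain(n_columns = 3, w_tc = 0.03, seed = 7, scale = 0.05)
  for (k in seq_along(m$projections)) {
    expect_identical(m$projections[[k]]$pre, m2$projections[[k]]$pre)
    expect_identical(m$projections[[k]]$post, m2$projections[[k]]$post)
  }
})

test_that("realized synapse counts stay within binomial bands per group", {
  m <- build_barrel(w_tc = 0.03, seed = 8)
  for (pr in m$projections) {
    n_pairs <- pr$n_pre * pr$n_post
    mu <- pr$p * n_pairs
    sd_b <- sqrt(n_pairs * pr$p * (1 - pr$p))
    expect_lt(abs(length(pr$pre) - mu), 5 * sd_b)
  }
})

test_that("scaled-down models recompute balance from scaled counts", {
  m <- build_barrel(b = 1, i2e_scale = 1, w_tc = 0.03, seed = 9, scale = 0.5)
  sz <- setNames(m$populations$size, m$populations$name)
  expect_equal(sz[["L4E"]], round(3471 * 0.5))
  pr <- m$projections
  names(pr) <- vapply(pr, `[[`, character(1), "name")
  expect_equal(pr[["L4I->L4E"]]$w,
               -inhibitory_weight(1, 0.1, sz[["L4E"]], sz[["L4I"]]),
               tolerance = 1e-12)
  expect_equal(pr[["L4E->L4E"]]$p, 0.1)  # probabilities unscaled
})
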