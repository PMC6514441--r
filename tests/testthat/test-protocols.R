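test_that("bias current solves the holding problem", {
  cell <- rc_cell()  # 1 nS to -55 mV
  expect_equal(find_bias_current(cell, -70), -15, tolerance = 0.15)

  # at the resting potential the bias is near zero
  rest <- tspn_integrate(std_cell, rep(0, 40000),
                         init = steady_state_init(std_cell, -65))$state$v
  expect_lt(abs(find_bias_current(std_cell, round(rest, 1))), 1.5)

  # impaled cell: bias equals the steady-state current sum at -70 mV
  imp <- with_imp(std_cell, 7)
  b <- cached_bias(imp, -70, "std_imp7")
  st <- steady_state_init(imp, -70)
  i_analytic <- sum(vapply(imp$channels, channel_current, numeric(1), state = st))
  expect_equal(b, i_analytic, tolerance = 0.05)
})

test_that("firing classification distinguishes N, P and R", {
  dt <- 0.1
  n <- 20000  # 2 s trace, step window 200-1700 ms
  w <- c(200, 1700)
  flat <- manual_trace(rep(-60, n), dt, window = w)
  expect_equal(classify_firing(flat), "N")

  spike_at <- function(times_ms) {
    v <- rep(-60, n)
    for (tm in times_ms) v[round(tm / dt) + 1:3] <- 20
    manual_trace(v, dt, window = w)
  }
  expect_equal(classify_firing(spike_at(c(250, 300, 360))), "P")
  expect_equal(classify_firing(spike_at(seq(250, 1650, by = 100))), "R")
  # a lone spike in the final half counts as repetitive (documented choice)
  expect_equal(classify_firing(spike_at(1500)), "R")
})

test_that("rheobase binary search agrees with a dense sweep and flags inexcitable cells", {
  b <- cached_bias(fig5_cell, -70, "fig5")
  rb <- measure_rheobase(fig5_cell, bias = b)
  # dense 0.25-pA sweep around the search result as the exhaustive oracle
  grid <- seq(rb - 2, rb + 2, by = 0.25)
  fires <- vapply(grid, function(i) {
    tr <- run_step(fig5_cell, i, -70, 1500, bias = b)
    sp <- detect_spikes(tr)
    any(sp > tr$meta$window[1] & sp <= tr$meta$window[2])
  }, logical(1))
  oracle <- grid[which(fires)[1]]
  expect_lt(abs(rb - oracle), 0.5 + 0.25)

  expect_error(measure_rheobase(knockout(std_cell, "Na")),
               class = "tspn_not_excitable")
  expect_error(measure_rheobase(std_cell, step_dur = 500))
})

test_that("strength-duration curves are monotone and approach the rheobase", {
  sd <- strength_duration(std_cell, c(20, 100, 500, 1500), tol = 1)
  expect_true(all(diff(sd$threshold_pa) <= 0))
  rb <- measure_rheobase(std_cell, bias = cached_bias(std_cell, -70, "std"), tol = 1)
  expect_equal(sd$threshold_pa[4], rb, tolerance = 0.05)
})

test_that("a passive-plus-Na cell has an ohmic long-duration threshold", {
  toy <- tspn_neuron(g = c(Kd = 0, M = 0, KCa = 0, A = 0, H = 0, CaL = 0, leak = 1))
  b <- find_bias_current(toy, -70)
  rb <- measure_rheobase(toy, bias = b, i_max = 100)
  tr <- run_step(toy, rb + 1, -70, 1500, bias = b)
  # a low derivative criterion approximates the ignition foot on this toy cell
  v_th <- detect_threshold(tr, dvdt_criterion = 0.2)$v_th
  ohmic <- (v_th - -70) * 1  # g_in = 1 nS leak
  expect_equal(rb, ohmic, tolerance = 0.3)
})

test_that("f-I curves show adaptation and agree with independently detected spikes", {
  b <- cached_bias(std_cell, -70, "std")
  fi <- fi_curve(std_cell, c(10, 60, 100, 140), bias = b)
  expect_true(is.na(fi$max_rate[1]))          # subthreshold current
  ok <- !is.na(fi$max_rate) & !is.na(fi$sustained_rate)
  expect_true(all(fi$max_rate[ok] >= fi$sustained_rate[ok]))
  expect_gt(attr(fi, "max_slope"), 0)

  # recompute the 100 pA rates from freshly detected spike times
  tr <- run_step(std_cell, 100, -70, 3000, bias = b)
  fr <- firing_rates(detect_spikes(tr), tr$meta$window)
  i <- which(fi$current_pa == 100)
  expect_equal(fi$max_rate[i], fr$max_rate)
  expect_equal(fi$sustained_rate[i], fr$sustained_rate)
})

test_that("impalement monotonically raises rheobase and lowers input resistance", {
  rbs <- c(); rins <- c()
  for (gi in c(0, 2, 7)) {
    cell <- with_imp(std_cell, gi)
    b <- cached_bias(cell, -70, paste0("std_imp", gi))
    rbs <- c(rbs, measure_rheobase(cell, bias = b, tol = 1))
    rins <- c(rins, model_input_resistance(cell, bias = b))
  }
  expect_true(all(diff(rbs) > 0))
  expect_true(all(diff(rins) < 0))
})

test_that("input resistance matches ohmic and slope-conductance oracles", {
  expect_equal(model_input_resistance(rc_cell()), 1000, tolerance = 0.01)

  b <- cached_bias(std_cell, -70, "std")
  rin <- model_input_resistance(std_cell, bias = b, probe_ms = 2500)
  iss <- function(v) {
    st <- steady_state_init(std_cell, v)
    sum(vapply(std_cell$channels, channel_current, numeric(1), state = st))
  }
  g_slope <- (iss(-69) - iss(-73)) / 4   # nS over the probe's voltage range
  expect_equal(rin, 1000 / g_slope, tolerance = 0.1)
})

test_that("phase boundaries mark genuine classification changes", {
  pb <- phase_boundaries(fig5_cell, 0, i_max = 100, tol = 1, step_dur = 1500)
  onset <- ifelse(is.na(pb$n_to_r), pb$n_to_p, pb$n_to_r)
  expect_false(is.na(onset))
  b <- cached_bias(fig5_cell, -70, "fig5")
  below <- classify_firing(run_step(fig5_cell, onset - 2, -70, 1500, bias = b))
  above <- classify_firing(run_step(fig5_cell, onset + 2, -70, 1500, bias = b))
  expect_equal(below, "N")
  expect_true(above %in% c("P", "R"))
})
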