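test_that("passive fit recovers RC parameters exactly and behaves linearly", {
  cell <- rc_cell()  # 1 GOhm, 100 pF, tau 100 ms
  b <- find_bias_current(cell, -70)
  tr <- fit_tr <- run_step(cell, -10, -70, 2000, bias = b)
  pf <- fit_passive(tr)
  expect_equal(pf$tau_m, 100, tolerance = 0.01)
  expect_equal(pf$r_in, 1000, tolerance = 0.01)
  expect_equal(pf$c_m, 100, tolerance = 0.01)

  pf2 <- fit_passive(run_step(cell, -20, -70, 2000, bias = b))
  expect_equal(pf2$delta_v, 2 * pf$delta_v, tolerance = 0.01)
  expect_equal(pf2$r_in, pf$r_in, tolerance = 0.01)
})

test_that("passive fits tolerate recording noise", {
  cell <- rc_cell()
  b <- find_bias_current(cell, -70)
  clean <- run_step(cell, -10, -70, 2000, bias = b)
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    noisy <- clean
    noisy$v <- clean$v + rnorm(length(clean$v), sd = 0.5)
    pf <- fit_passive(noisy)
    max(abs(pf$tau_m - 100) / 100, abs(pf$r_in - 1000) / 1000)
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("threshold detection finds a constructed inflection and fails without spikes", {
  dt <- 0.1
  # slow ramp to -45, then a fast spike upstroke: inflection at -45 mV
  pre <- seq(-70, -45, length.out = 3000)          # ~0.08 mV/ms
  spike <- c(seq(-45, 30, length.out = 60), seq(30, -60, length.out = 100))
  v <- c(rep(-70, 500), pre, spike, rep(-60, 500))
  th <- detect_threshold(manual_trace(v, dt))
  expect_lt(abs(th$v_th - (-45)), 2.5)
  expect_error(detect_threshold(manual_trace(rep(-70, 1000), dt)),
               class = "tspn_detection_error")
})

test_that("threshold is insensitive to the derivative criterion on model spikes", {
  b <- cached_bias(std_cell, -70, "std")
  rb <- measure_rheobase(std_cell, bias = b)
  tr <- run_step(std_cell, rb + 2, -70, 2000, bias = b)
  th1 <- detect_threshold(tr, dvdt_criterion = 1)$v_th
  th2 <- detect_threshold(tr, dvdt_criterion = 2)$v_th
  expect_lt(abs(th2 - th1), 2)
})

test_that("calculated rheobase is plain ohmic arithmetic", {
  expect_equal(calculated_rheobase(-45, -70, 1000), 25)
  expect_equal(calculated_rheobase(-70, -70, 500), 0)
  expect_error(calculated_rheobase(-45, -70, 0), "positive")
})

test_that("measured rheobase follows the step-family rule", {
  expect_equal(measured_rheobase_from_steps(c(10, 20, 30, 40), c(0, 0, 0, 4)), 35)
  expect_equal(measured_rheobase_from_steps(c(20, 30), c(0, 1)), 30)
  expect_error(measured_rheobase_from_steps(c(10, 20), c(0, 0)),
               class = "tspn_not_excitable")
})

test_that("AP metrics recover a constructed spike shape", {
  dt <- 0.1
  # linear rise from -45 threshold to +10 peak over 3 ms, mirror-symmetric fall
  pre <- seq(-70, -45, length.out = 2500)
  up <- seq(-45, 10, length.out = 31)
  down <- seq(10, -45, length.out = 31)
  v <- c(rep(-70, 300), pre, up[-1], down[-1], rep(-60, 400))
  ap <- ap_metrics(manual_trace(v, dt))
  expect_lt(abs(ap$v_threshold - (-45)), 2.5)
  expect_equal(ap$peak, 10, tolerance = 1e-6)
  expect_equal(ap$amplitude, 10 - ap$v_threshold, tolerance = 1e-6)
  # half-width of a symmetric triangle = half the base width (6 ms base)
  expect_equal(ap$half_width, 3, tolerance = 0.15)
})

test_that("fAHP metrics match a constructed exponential undershoot", {
  dt <- 0.1
  w <- c(100, 3100)
  v_ss <- -48
  t_dec <- seq(0, 1500, by = dt)
  undershoot <- v_ss - 15 * exp(-t_dec / 115)
  spike <- c(seq(-48, 25, length.out = 20), seq(25, v_ss - 15, length.out = 20))
  v <- c(rep(-70, 1000),                      # pre-step baseline
         seq(-70, -48, length.out = 2000),    # charging
         spike, undershoot[-1])
  v <- c(v, rep(v_ss, 32000 - length(v)))     # hold at steady state to step end
  f <- fahp_metrics(manual_trace(v, dt, window = w))
  expect_equal(f$amplitude, 15, tolerance = 0.05)
  expect_equal(f$half_decay, 115 * log(2), tolerance = 0.05)
  expect_gt(f$duration, f$half_decay)

  # multi-spike minimal-suprathreshold traces yield no fAHP
  v2 <- v
  v2[25000:25030] <- 20
  expect_null(fahp_metrics(manual_trace(v2, dt, window = w)))
})

test_that("firing rates, sustained rate and SRA ratio follow their definitions", {
  w <- c(0, 3000)
  sp <- cumsum(c(100, rep(100, 9)))      # uniform 100 ms ISIs
  fr <- firing_rates(sp, w)
  expect_true(all(fr$ifr$rate == 10))
  expect_equal(fr$max_rate, 10)
  # uniform train ending early in the step: sustained undefined
  expect_null(firing_rates(cumsum(rep(100, 5)), w)$sustained_rate)

  sp2 <- 1000 + cumsum(c(0, 50, 100, 150, 200, 200, 200))
  fr2 <- firing_rates(sp2, w)
  expect_equal(fr2$max_rate, 20)
  expect_equal(fr2$sustained_rate, 5)
  expect_equal(fr2$sra_ratio, 4)

  expect_null(firing_rates(numeric(0), w)$max_rate)
})

test_that("sag detection flags H-current relaxation but not monotone RC decay", {
  cell <- rc_cell()
  b <- find_bias_current(cell, -70)
  rc <- run_step(cell, -20, -70, 2000, bias = b)
  expect_false(detect_sag(rc)$sag)
  expect_error(detect_sag(run_step(cell, 5, -70, 2000, bias = b)),
               class = "tspn_detection_error")

  f8b <- tspn_neuron("fig8b")
  b8 <- find_bias_current(f8b, -70)
  deep <- run_step(f8b, -40, -70, 2500, bias = b8)
  expect_true(detect_sag(deep)$sag)
  expect_lt(min(deep$v), -100)
})

test_that("notch detection requires a hyperpolarized hold", {
  f8a <- tspn_neuron("fig8a")
  for (hv in c(-90, -70)) {
    b <- find_bias_current(f8a, hv)
    tr <- run_step(f8a, 60, hv, 2500, bias = b)
    nt <- detect_notch(tr)
    if (hv == -90) expect_true(nt$notch) else expect_false(nt$notch)
  }
})

test_that("liquid-junction correction shifts absolute voltages only", {
  expect_equal(ljp_correct(30), 20)
  expect_equal(ljp_correct(-60), -70)
  peak <- 30; th <- -45
  expect_equal(ljp_correct(peak) - ljp_correct(th), peak - th)
})

test_that("the usAHP flag needs progressive hyperpolarization below E_K", {
  expect_true(usahp_flag(c(-60, -70, -85, -101)))
  expect_false(usahp_flag(c(-60, -61, -62, -63)))   # never below E_K
  expect_false(usahp_flag(c(-101, -100, -99)))      # no hyperpolarizing drift
})
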