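test_that("spike detection finds constructed events and nothing on flat traces", {
  flat <- make_trace(rep(-70, 5000))
  expect_equal(nrow(detect_spikes(flat)), 0)

  t <- seq(0, 100, by = 0.01)
  v <- -70 + 90 * (exp(-(t - 20)^2 / 0.5) + exp(-(t - 50)^2 / 0.5) +
                     exp(-(t - 80)^2 / 0.5))
  tr <- make_trace(v)
  sp <- detect_spikes(tr, peak_threshold = 0)
  expect_equal(nrow(sp), 3)
  expect_equal(sp$peak_time, c(20, 50, 80), tolerance = 0.02)
  expect_true(all(sp$threshold_time <= sp$peak_time))
  expect_true(all(sp$threshold_v < sp$peak_v))
})

test_that("spike count equals an independent crossing scan on a model run", {
  tr <- suprathreshold_trace()
  sp <- detect_spikes(tr)
  v <- tr$v
  crossings <- sum(v[-1] >= 0 & v[-length(v)] < 0)
  expect_equal(nrow(sp), crossings)
})

test_that("spike detection is idempotent and ignores appended subthreshold samples", {
  tr <- suprathreshold_trace()
  sp1 <- detect_spikes(tr)
  tr2 <- make_trace(c(tr$v, rep(-70, 2000)), dt = tr$dt)
  sp2 <- detect_spikes(tr2)
  expect_equal(sp2$peak_time, sp1$peak_time)
})

test_that("widths follow closed forms on constructed shapes", {
  # symmetric triangle of base width 4 ms: width at half amplitude = 2 ms
  dt <- 0.01
  up <- seq(-70, 20, length.out = 201)
  tri <- make_trace(c(rep(-70, 500), up, rev(up)[-1], rep(-70, 500)), dt)
  sp <- detect_spikes(tri)
  expect_equal(nrow(sp), 1)
  f <- ap_features(tri, sp[1, ])
  expect_equal(f$fwhm, 2, tolerance = 0.02)

  # Gaussian bump of sd sigma on a flat baseline: FWHM = 2 sigma sqrt(2 ln 2)
  sigma <- 0.5
  g <- gaussian_ap_trace(sigma = sigma)
  spg <- detect_spikes(g)
  fg <- ap_features(g, spg[1, ], baseline = "rmp", rmp_value = -70)
  expect_equal(fg$fwhm, 2 * sigma * sqrt(2 * log(2)), tolerance = dt)
})

test_that("width metrics are translation-invariant and scale with time dilation", {
  g <- gaussian_ap_trace(sigma = 0.4)
  sp <- detect_spikes(g)
  f0 <- ap_features(g, sp[1, ], baseline = "rmp", rmp_value = -70)
  shifted <- make_trace(g$v + 15, dt = g$dt)
  sps <- detect_spikes(shifted, peak_threshold = 15)
  expect_equal(ap_features(shifted, sps[1, ], baseline = "rmp",
                           rmp_value = -55)$fwhm,
               f0$fwhm, tolerance = 1e-6)
  dilated <- make_trace(g$v, dt = 2 * g$dt)
  spd <- detect_spikes(dilated)
  expect_equal(ap_features(dilated, spd[1, ], baseline = "rmp",
                           rmp_value = -70)$fwhm,
               2 * f0$fwhm, tolerance = 1e-6)
})

test_that("width is undefined when the peak does not exceed the baseline", {
  g <- gaussian_ap_trace(peak = 5)
  sp <- detect_spikes(g, peak_threshold = 0)
  expect_error(ap_features(g, sp[1, ], baseline = "rmp", rmp_value = 10),
               "width undefined")
})

test_that("firing rate is count over window length", {
  expect_equal(firing_rate(seq(50, 950, length.out = 10), c(0, 1000)), 10)
  expect_equal(firing_rate(numeric(0), c(0, 1000)), 0)
  set.seed(42)
  st <- gen_spike_train(20, 100, refractory = 0, seed = 42)
  est <- firing_rate(st, c(0, 100e3))
  expect_lt(abs(est - 20), 3 * sqrt(2000) / 100)
})

test_that("rmp averages the pre-stimulus window and matches the fixed point", {
  flat <- make_trace(rep(-70, 2000))
  expect_equal(rmp(flat, c(0, 10)), -70)
  expect_error(rmp(flat, c(-5, 10)), "outside")

  p <- default_params()
  tr <- simulate_hh(p, protocol = constant_stimulus(0, 100), T = 100)
  expect_equal(rmp(tr, c(50, 100)), resting_state(p)[["v"]],
               tolerance = 0.1)
})

test_that("resting potential is more negative under potassium scaling", {
  p <- default_params()
  tr1 <- simulate_hh(p, mod_sK(1), constant_stimulus(0, 100), T = 100)
  tr2 <- simulate_hh(p, mod_sK(1.5), constant_stimulus(0, 100), T = 100)
  expect_lt(rmp(tr2, c(50, 100)), rmp(tr1, c(50, 100)))
})

test_that("rheobase bisection matches a grid search and grows with sK", {
  p <- default_params()
  res <- 0.05
  rb <- rheobase_search(p, resolution = res, amp_range = c(0, 2))
  # exhaustive scan at the same resolution
  grid <- seq(0, 2, by = res)
  fires <- vapply(grid, function(a) {
    pr <- stimulus_protocol(data.frame(start = 5, duration = 30,
                                       amplitude = a))
    tr <- simulate_hh(p, protocol = pr, T = 55)
    nrow(detect_spikes(tr)) >= 1
  }, logical(1))
  grid_rb <- grid[which(fires)[1]]
  expect_lt(abs(rb - grid_rb), res + 1e-9)
  expect_gt(rb, 0)

  rb_scaled <- rheobase_search(p, mod_sK(1.5), resolution = res,
                               amp_range = c(0, 2))
  expect_gt(rb_scaled, rb)
})

test_that("F-I curve matches componentwise re-runs and drops under scaling", {
  p <- default_params()
  amps <- c(0.05, 0.3, 0.6, 1)
  fi <- fi_curve(p, amplitudes = amps, duration = 300)
  expect_equal(fi$amplitude, amps)
  for (i in seq_along(amps)) {
    tr <- simulate_hh(p, protocol = constant_stimulus(amps[i], 300), T = 300)
    expect_equal(fi$count[i], nrow(detect_spikes(tr)))
  }
  expect_equal(fi_curve(p, amplitudes = c(0.05, 0.1), duration = 300)$count,
               c(0, 0)) # below rheobase
  fi_s <- fi_curve(p, mod_sK(1.5), amplitudes = amps, duration = 300)
  expect_true(all(fi_s$count <= fi$count))
})

test_that("phase plot matches calculus on simple signals", {
  dt <- 0.01
  ramp <- make_trace(3 * seq(0, 10, by = dt), dt)
  pp <- phase_plot(ramp)
  expect_equal(nrow(pp), length(ramp$v) - 2)
  expect_true(all(abs(pp$dvdt - 3 * 1) < 1e-9 | abs(pp$dvdt) < 1e-9))

  t <- seq(0, 20, by = dt)
  sine <- make_trace(sin(t), dt)
  ps <- phase_plot(sine)
  i_max <- which.max(abs(ps$dvdt))
  expect_lt(abs(ps$v[i_max]), 2 * dt) # extreme slope at the midline

  # forward-difference oracle agrees to O(dt)
  v <- suprathreshold_trace()$v[1:5000]
  tr <- make_trace(v, dt)
  pc <- phase_plot(tr)
  fwd <- diff(v) / dt
  expect_lt(max(abs(pc$dvdt - fwd[-1])), max(abs(fwd)) * dt * 50)
})
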