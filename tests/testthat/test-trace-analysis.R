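# Bessel filtering, step detection, conductance statistics, seal check.

test_that("Bessel low-pass has unit DC gain and the designed cutoff", {
  fs <- 25000
  dc <- current_trace(rep(100, 2 * fs), fs, 50)
  out <- bessel_lowpass(dc, 1000, 8)
  expect_lt(max(abs(out$samples[1000:40000] - 100)), 1e-9)
  expect_match(out$filter_history[length(out$filter_history)], "bessel")

  # sinusoid at the cutoff: single-pass magnitude must sit at the analog
  # -3 dB point (1/sqrt(2)) within 2%
  t <- (0:(2 * fs - 1)) / fs
  sine <- current_trace(sin(2 * pi * 1000 * t), fs, 50)
  one <- bessel_lowpass(sine, 1000, 8)
  amp1 <- sqrt(2 * mean(one$samples[10000:40000]^2))
  expect_equal(amp1, 1 / sqrt(2), tolerance = 0.02)

  # filtering twice equals the squared transfer function
  two <- bessel_lowpass(one, 1000, 8)
  amp2 <- sqrt(2 * mean(two$samples[10000:40000]^2))
  expect_equal(amp2, 0.5, tolerance = 0.02)

  expect_error(bessel_lowpass(current_trace(rnorm(100), 1000, 50), 600),
               "Nyquist")
})

test_that("group-delay compensation keeps step edges aligned", {
  fs <- 25000
  x <- c(rep(0, fs), rep(500, fs))
  out <- bessel_lowpass(current_trace(x, fs, 50), 1000, 8)
  half_rise <- which(out$samples >= 250)[1]
  expect_lt(abs(half_rise - (fs + 1)), 3)
})

test_that("detector recovers a noiseless staircase exactly", {
  sim <- simulate_trace(sampling_rate = 2000, duration = 6,
                        holding_voltage = 50, baseline_noise_sd = 0,
                        event_times = 1:5,
                        event_conductances = c(5, 10, 3, 8, 12), seed = 1)
  ev <- detect_steps(sim$trace, min_step = 50)
  expect_equal(nrow(ev), 5)
  expect_equal(ev$delta_current, c(5, 10, 3, 8, 12) * 50, tolerance = 1e-9)
  expect_equal(ev$delta_conductance, c(5, 10, 3, 8, 12), tolerance = 1e-9)
  expect_equal(ev$time, 1:5, tolerance = 2 / 2000)
})

test_that("detection is invariant to a DC offset", {
  sim <- simulate_trace(duration = 10, seed = 3)
  ev0 <- detect_steps(sim$trace)
  shifted <- current_trace(sim$trace$samples + 500, sim$trace$sampling_rate,
                           sim$trace$holding_voltage)
  ev1 <- detect_steps(shifted)
  expect_equal(ev0$time, ev1$time)
  expect_equal(ev0$delta_current, ev1$delta_current, tolerance = 1e-9)
})

test_that("downsampling a noiseless staircase preserves events", {
  sim <- simulate_trace(sampling_rate = 2000, duration = 6,
                        holding_voltage = 50, baseline_noise_sd = 0,
                        event_times = 1:5,
                        event_conductances = c(5, 10, 3, 8, 12), seed = 1)
  down <- current_trace(sim$trace$samples[seq(1, length(sim$trace$samples), 2)],
                        1000, 50)
  ev <- detect_steps(down, min_step = 50)
  expect_equal(nrow(ev), 5)
  expect_equal(ev$delta_conductance, c(5, 10, 3, 8, 12), tolerance = 1e-9)
})

test_that("detector recall and precision hold at SNR >= 5", {
  # smaller replicate of the full acceptance run
  tps <- 0; n_true <- 0; n_det <- 0
  for (s in 1:5) {
    sim <- simulate_trace(duration = 30, seed = s)
    tr <- bessel_lowpass(sim$trace, 1000, 8)
    ev <- detect_steps(tr)
    tps <- tps + match_event_times(ev$time, sim$truth$event_times)
    n_true <- n_true + length(sim$truth$event_times)
    n_det <- n_det + nrow(ev)
  }
  expect_gte(tps / n_true, 0.95)
  expect_gte(tps / n_det, 0.95)
})

test_that("pure-noise traces yield almost no false positives", {
  fp <- vapply(1:20, function(s) {
    sim <- simulate_trace(sampling_rate = 2000, duration = 60,
                          insertion_rate = 0, baseline_noise_sd = 20,
                          seed = s)
    nrow(detect_steps(sim$trace, min_step = 6 * 20))
  }, numeric(1))
  expect_lt(mean(fp), 1)
})

test_that("conductance conversion follows Ohm's law and sign convention", {
  ev <- step_events(time = c(1, 2, 3), delta_current = c(540, 0, -540),
                    holding_voltage = 50)
  ev <- conductance_of_events(ev)
  expect_equal(ev$delta_conductance, c(10.8, 0, -10.8))
  # negative voltage with negative current gives positive conductance
  evn <- conductance_of_events(step_events(1, -540, holding_voltage = -50))
  expect_equal(evn$delta_conductance, 10.8)
  expect_error(conductance_of_events(step_events(1, 10, holding_voltage = 0)),
               "nonzero")
})

test_that("event statistics use the documented median and bin conventions", {
  ev <- conductance_of_events(step_events(1:3, c(1, 2, 3) * 50,
                                          holding_voltage = 50))
  st <- event_statistics(ev, bin_width = 1)
  expect_equal(st$median, 2)
  expect_equal(st$n, 3)
  expect_equal(sum(st$histogram$count), 3)
  # even n: lower of the two middle order statistics
  ev4 <- conductance_of_events(step_events(1:4, c(1, 2, 3, 4) * 50,
                                           holding_voltage = 50))
  expect_equal(event_statistics(ev4)$median, 2)
  # lower-inclusive bins: value 1.0 falls in [1, 2)
  expect_equal(st$histogram$bin_lower[st$histogram$count > 0][1], 1)
  # empty set flagged
  st0 <- event_statistics(step_events(numeric(0), numeric(0),
                                      holding_voltage = 50))
  expect_false(st0$median_defined)
})

test_that("sample median of lognormal amplitudes approaches the true median", {
  set.seed(21)
  g <- rlnorm(1e4, meanlog = log(10.8), sdlog = 0.5)
  ev <- step_events(seq_along(g), g * 50, holding_voltage = 50)
  ev <- conductance_of_events(ev)
  expect_equal(event_statistics(ev)$median, 10.8, tolerance = 0.03)
  # and the lower-interpolation median agrees with a sort-based oracle
  expect_equal(event_statistics(ev)$median, sort(g)[5000])
})

test_that("seal check estimates leak conductance by regression", {
  mk <- function(v, leak_nS = 0, noise = 0, seed = 1) {
    set.seed(seed)
    current_trace(leak_nS * v + rnorm(2000, 0, noise), 1000, v)
  }
  clean <- lapply(c(-40, -20, 0, 20, 40), mk)
  sc <- seal_check(clean)
  expect_equal(sc$conductance_nS, 0, tolerance = 1e-12)
  expect_true(sc$pass)
  # injected 10 pS leak must be recovered and fail a 1 pS threshold
  leaky <- lapply(c(-40, -20, 0, 20, 40),
                  function(v) mk(v, leak_nS = 0.010, noise = 0.5, seed = v + 50))
  sl <- seal_check(leaky, threshold_pS = 1)
  expect_equal(sl$conductance_pS, 10, tolerance = 0.2)
  expect_false(sl$pass)
  expect_error(seal_check(list(mk(10), mk(10))), "distinct")
})
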