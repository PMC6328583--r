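test_that("twitch detection finds every paced beat with equal amplitudes", {
  fx <- paced_fixture(duration = 60, noise = FALSE)
  ev <- detect_twitches(fx$trace, fx$schedule)
  expect_equal(nrow(ev), 12)
  expect_lt(diff(range(ev$amplitude)) / mean(ev$amplitude), 0.01)
  expect_equal(ev$diastolic_force, rep(1, 12), tolerance = 1e-6)
  expect_true(all(ev$peak_time >= ev$onset & ev$onset >= ev$stimulus_time))

  # an unstimulated trace yields no events
  flat <- simulate_run(fx$tissue, NULL, run_config(duration = 10,
                                                   noise = FALSE))
  flat <- trace_to_force(flat)
  expect_equal(nrow(detect_twitches(flat, fx$schedule)), 0)
  expect_equal(nrow(detect_twitches(fx$trace, NULL)), 0)
})

test_that("twitch amplitude is invariant to a constant flux offset", {
  fx <- paced_fixture(duration = 30, noise = FALSE)
  ev1 <- detect_twitches(fx$trace, fx$schedule)
  shifted <- fx$trace
  shifted$flux <- shifted$flux + 2e-4
  ev2 <- detect_twitches(shifted, fx$schedule)
  expect_equal(ev2$amplitude, ev1$amplitude, tolerance = 1e-9)
  expect_equal(ev2$diastolic_force - ev1$diastolic_force,
               rep(75 * 2e-4 / 7 * 1e3, nrow(ev1)), tolerance = 1e-6)
})

test_that("pair classification is monotone in the extra-stimulus interval", {
  tp <- tissue_params(refractory_period = 425)
  proto <- paired_pulse_protocol(fine_refine = FALSE)
  sched <- paired_pulse_schedule(proto)
  tr <- simulate_run(tp, sched, run_config(duration = 31 * 30,
                                           noise = FALSE))
  res <- refractory_period(tr, sched)
  steps <- res$steps[order(res$steps$interval_ms), ]
  two <- steps$classification == "two_contractions"
  # once an interval elicits two contractions, every longer interval does
  expect_true(all(diff(two) >= 0))
  expect_equal(res$refractory_period, 425)
  expect_equal(res$precision, 25)
})

test_that("subthreshold extra stimuli never count as second contractions", {
  tp <- tissue_params(threshold_current = 20)
  proto <- paired_pulse_protocol(start_interval = 900, end_interval = 800,
                                 decrement = 50, fine_refine = FALSE)
  weak <- make_pulse(amplitude = 30)
  sched <- paired_pulse_schedule(proto, pulse = weak)
  # make only the extras subthreshold
  sched$amplitude[sched$tag == "extra"] <- 10
  tr <- simulate_run(tp, sched, run_config(duration = 3 * 30, noise = FALSE))
  res <- refractory_period(tr, sched)
  expect_true(all(res$steps$classification == "one_contraction"))
  expect_equal(res$censored, "high")
})

test_that("contracture reports the diastolic baseline drift over the window", {
  tt <- seq(0, 1200, by = 0.2)
  ramp <- tibble::tibble(time = tt, force = 1 + 2 * tt / 1200)
  expect_equal(contracture(ramp), 2, tolerance = 0.01)
  flat <- tibble::tibble(time = tt, force = rep(1, length(tt)))
  expect_equal(contracture(flat), 0, tolerance = 1e-9)
  neg <- tibble::tibble(time = tt, force = 1 - 0.5 * tt / 1200)
  expect_equal(contracture(neg), -0.5, tolerance = 0.01)
})

test_that("long-term summaries track the medium-exchange envelope", {
  # constant-amplitude stream: identical cycles
  const <- tibble::tibble(stimulus_time = seq(0, 84 * 3600, by = 60),
                          peak_force = 7.14, diastolic_force = 1,
                          amplitude = 6.14)
  s <- longterm_summary(const, exchange_interval_h = 42)
  expect_equal(nrow(s), 3)
  expect_equal(unique(round(s$min_amplitude, 9)), 6.14)
  expect_equal(unique(round(s$max_amplitude, 9)), 6.14)
  # diastolic 1 mN against systolic 7.14 mN is a 14% ratio
  expect_equal(s$dia_sys_ratio_pct[1], 14, tolerance = 0.01)

  # modulated stream: per-cycle envelope matches the generator
  ev <- simulate_longterm_events(days = 7, exchange_interval_h = 42,
                                 depth = 0.3, ratio_start = 0.2,
                                 ratio_end = 0.2)
  amp_full <- 1 / 0.2 - 1
  s2 <- longterm_summary(ev, exchange_interval_h = 42)
  full_cycles <- s2[seq_len(nrow(s2) - 1), ] # last cycle may be partial
  expect_equal(full_cycles$min_amplitude,
               rep(0.7 * amp_full, nrow(full_cycles)), tolerance = 0.02)
  expect_equal(full_cycles$max_amplitude,
               rep(amp_full, nrow(full_cycles)), tolerance = 0.02)
})
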