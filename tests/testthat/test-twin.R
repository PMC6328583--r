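test_that("twitch waveform starts at zero, peaks at the calibrated force, decays", {
  tp <- tissue_params()
  expect_equal(active_force(0, tp), 0)
  expect_lt(active_force(20000, tp), 1e-12)
  pk <- optimize(function(t) active_force(t, tp), c(1, 2000), maximum = TRUE)
  expect_equal(pk$objective, tp$peak_twitch_force, tolerance = 1e-6)
  expect_equal(pk$maximum, tp$time_to_peak, tolerance = 0.01)
  expect_error(active_force(-1, tp), class = "myoslice_domain_error")
  # single-peaked: derivative changes sign once
  tt <- seq(1, 2000, by = 1)
  ds <- sign(diff(active_force(tt, tp)))
  expect_equal(sum(diff(ds) != 0), 1)
})

test_that("excitation needs suprathreshold charge and a post-refractory interval", {
  tp <- tissue_params(refractory_period = 425, threshold_current = 20)
  st <- chamber_state(last_activation_time = 0)

  # interval exactly equal to the refractory period fails
  ex <- excitable(tp, st, t = 0.425, stimulus_current = 50)
  expect_false(ex$activated)
  # one millisecond beyond it succeeds
  ex <- excitable(tp, st, t = 0.426, stimulus_current = 50)
  expect_true(ex$activated)
  expect_equal(ex$state$last_activation_time, 0.426)
  # subthreshold current never activates, whatever the interval
  ex <- excitable(tp, st, t = 100, stimulus_current = 10)
  expect_false(ex$activated)
  # constant-charge strength-duration: 10 mA at 2 ms carries enough charge
  ex <- excitable(tp, st, t = 100, stimulus_current = 10, pulse_width = 2)
  expect_true(ex$activated)
})

test_that("drug mechanisms follow their Hill and onset laws", {
  t0 <- tissue_params()

  # zero dose leaves the tissue unchanged
  expect_equal(apply_drug(t0, drug_dofetilide(0))$refractory_period,
               t0$refractory_period)
  # Hill midpoint: half the ceiling at C = EC50
  t_mid <- apply_drug(t0, drug_dofetilide(3))
  expect_equal(t_mid$refractory_period - t0$refractory_period, 80)
  # the delayed mechanism is inert on day 0
  pent <- drug_pentamidine(1)
  expect_equal(apply_drug(t0, pent, elapsed_days = 0)$refractory_period,
               t0$refractory_period)
  # ... monotone non-decreasing in exposure time ...
  days <- c(0, 1, 3, 7, 14, 28, 60)
  rp <- vapply(days, function(d) {
    apply_drug(t0, pent, elapsed_days = d)$refractory_period
  }, numeric(1))
  expect_true(all(diff(rp) >= 0))
  # ... and converges to the acute Hill effect
  acute <- drug_effect("pent-acute", "rp_acute_hill", ec50 = pent$ec50,
                       emax = pent$emax, concentration = 1)
  expect_equal(apply_drug(t0, pent, elapsed_days = 1000)$refractory_period,
               apply_drug(t0, acute)$refractory_period, tolerance = 1e-9)

  # saturating inotropy reaches the Emax factor
  iso <- apply_drug(t0, drug_isoprenaline(1e7))
  expect_equal(iso$peak_twitch_force / t0$peak_twitch_force, 5.5,
               tolerance = 1e-4)

  broken <- drug_dofetilide(1)
  broken$mechanism <- "not_a_mechanism"
  expect_error(apply_drug(t0, broken), class = "myoslice_domain_error")
})

test_that("preload adjustment reaches the target and the calibrated length", {
  tp <- tissue_params()
  st <- adjust_preload(chamber_state(), tp, target = 1)
  expect_equal(st$preload, 1, tolerance = 0.01)
  # 1 mN preload sits at 83% of the length of maximal active force
  expect_equal(myoslice:::operating_fraction(st, tp), 0.83, tolerance = 1e-6)

  slack <- adjust_preload(chamber_state(), tp, target = 0)
  expect_equal(slack$preload, 0, tolerance = 1e-9)

  expect_error(adjust_preload(chamber_state(), tp, target = 1e5),
               class = "myoslice_limit_error")
})

test_that("simulated runs honour preload, pacing count and determinism", {
  tp <- tissue_params()
  # unstimulated noise-free trace is flat at the diastolic preload
  flat <- simulate_run(tp, NULL, run_config(duration = 5, noise = FALSE))
  f <- trace_to_force(flat)
  expect_equal(range(f$force), c(1, 1), tolerance = 1e-9)

  # 60 s at 0.2 Hz gives 12 twitch events
  fx <- paced_fixture(duration = 60, noise = FALSE)
  ev <- detect_twitches(fx$trace, fx$schedule)
  expect_equal(nrow(ev), 12)

  # forces never drop below zero at non-negative preload
  expect_true(all(f$force >= 0))
  expect_true(all(trace_to_force(fx$trace)$force >= 0))

  # bit-reproducible under a fixed seed
  a <- simulate_run(tp, fx$schedule, run_config(duration = 60, seed = 9))
  b <- simulate_run(tp, fx$schedule, run_config(duration = 60, seed = 9))
  expect_identical(a$flux, b$flux)

  expect_error(
    simulate_run(tp, pacing_schedule(0.2, 60), run_config(duration = 10,
                                                          noise = FALSE)),
    class = "myoslice_format_error")
})

test_that("run configs demand a seed for stochastic runs", {
  expect_error(run_config(noise = TRUE, seed = NULL),
               class = "myoslice_domain_error")
  expect_silent(run_config(noise = FALSE, seed = NULL))
})
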