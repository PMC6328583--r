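test_that("pulses are charge balanced and respect device ceilings", {
  p <- make_pulse()
  expect_equal(p$phase_charge, 50) # 50 mA x 1 ms = 50 uC per phase
  expect_equal(p$net_charge, 0)

  # escalation limit is accepted, beyond it is not
  expect_s3_class(make_pulse(75, 3, 1, 3), "pulse_shape")
  expect_error(make_pulse(80), class = "myoslice_limit_error")
  expect_error(make_pulse(50, charge_width = 3.5),
               class = "myoslice_limit_error")
})

test_that("sampled waveforms integrate to zero net charge", {
  for (amp in c(20, 50, 75)) {
    for (w in c(0.5, 1, 3)) {
      wf <- pulse_waveform(make_pulse(amp, w, gap = 1), dt = 0.01)
      charge <- sum(wf$current_ma) * 0.01
      expect_equal(charge, 0, tolerance = 1e-12)
      expect_equal(sum(wf$current_ma[wf$current_ma > 0]) * 0.01, amp * w,
                   tolerance = 1e-9)
    }
  }
})

test_that("pacing schedules have floor(duration x rate) evenly spaced events", {
  expect_equal(nrow(pacing_schedule(0.2, 60)), 12)
  expect_equal(nrow(pacing_schedule(1, 10)), 10)
  expect_equal(nrow(pacing_schedule(0.2, 30)), 6)
  s <- pacing_schedule(0.2, 60)
  expect_equal(unique(diff(s$time)), 5)
  # pure generation: identical inputs give identical schedules
  expect_identical(pacing_schedule(0.2, 60), pacing_schedule(0.2, 60))
})

test_that("paired-pulse schedules descend from 1000 to 250 ms", {
  sched <- paired_pulse_schedule(paired_pulse_protocol())
  iv <- sched$interval_ms[sched$tag == "extra"]
  expect_equal(length(unique(iv)), 31) # (1000 - 250) / 25 + 1
  expect_equal(unique(iv)[1], 1000)
  expect_equal(min(iv), 250)
  expect_true(all(diff(unique(iv)) < 0))

  # every extra trails its regular by the step interval
  ex <- which(sched$tag == "extra")
  expect_true(all(sched$time[ex] > sched$time[ex - 1]))
  expect_equal((sched$time[ex] - sched$time[ex - 1]) * 1000,
               sched$interval_ms[ex], tolerance = 1e-9)

  two <- paired_pulse_schedule(paired_pulse_protocol(decrement = 750))
  expect_equal(sort(unique(two$interval_ms[two$tag == "extra"])), c(250, 1000))

  expect_error(
    paired_pulse_schedule(paired_pulse_protocol(start_interval = 6000,
                                                end_interval = 250)),
    class = "myoslice_domain_error")
})

test_that("electric field calibration reproduces the printed anchors", {
  e20 <- electric_field(20)
  e50 <- electric_field(50)
  expect_gte(e20, 0.15); expect_lte(e20, 0.16)
  expect_gte(e50, 0.39 - 1e-12); expect_lte(e50, 0.40)
  expect_equal(electric_field(0), 0)
})
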