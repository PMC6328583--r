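test_that("wall stress reproduces the chamber design points", {
  expect_equal(wall_stress(22.5), 15)
  expect_equal(wall_stress(1), 0.667, tolerance = 1e-3)
  expect_equal(wall_stress(0), 0)
  # linear in force, inverse-linear in cross-section
  expect_equal(wall_stress(45), 2 * wall_stress(22.5))
  g2 <- slice_geometry(width = 10, thickness = 0.3)
  expect_equal(wall_stress(22.5, g2), wall_stress(22.5) / 2)

  expect_equal(systolic_design_check(75, 0.06), 15)
  expect_equal(systolic_design_check(75, 0), 0)
  expect_equal(systolic_design_check(150, 0.06), 30)
})

test_that("length-tension analysis recovers optimum and preload fraction", {
  # twin default sweep: 1 mN preload at 83% of the optimal length
  tp <- tissue_params()
  sweep <- sweep_length_tension(tp)
  res <- length_tension_analysis(sweep)
  expect_false(res$degenerate)
  expect_equal(res$fraction_at_preload, 0.83, tolerance = 0.02)
  expect_equal(res$l_max, tp$l_max, tolerance = 0.01)

  # constructed parabola with a known peak is recovered exactly
  stretch <- seq(4, 6, by = 0.1)
  par <- tibble::tibble(stretch = stretch,
                        active = 5 - (stretch - 5.2)^2,
                        passive = exp(stretch - 5) / 2)
  resp <- length_tension_analysis(par)
  expect_equal(resp$l_max, 5.2, tolerance = 1e-9)

  flat <- tibble::tibble(stretch = stretch, active = 1,
                         passive = exp(stretch - 5) / 2)
  expect_true(length_tension_analysis(flat)$degenerate)
})

test_that("Hill fits recover generating parameters on noiseless data", {
  doses <- c(0.3, 1, 3, 10, 30, 100)
  d <- tibble::tibble(concentration = doses,
                      response = hill_response(doses, 3, 160, 1))
  fit <- hill_fit(d)
  expect_equal(fit$ec50, 3, tolerance = 1e-6)
  expect_equal(fit$emax, 160, tolerance = 1e-6)

  # parameter sweep, free Hill coefficient where generated with n != 1
  for (ec50 in c(1, 3, 30)) {
    for (emax in c(50, 160)) {
      for (n in c(1, 2)) {
        dd <- tibble::tibble(
          concentration = doses,
          response = hill_response(doses, ec50, emax, n))
        ff <- hill_fit(dd, fix_hill_n = if (n == 1) 1 else NULL)
        expect_equal(ff$ec50, ec50, tolerance = 1e-4)
        expect_equal(ff$emax, emax, tolerance = 1e-4)
      }
    }
  }
})

test_that("Hill fit is invariant to concentration unit rescaling", {
  d <- simulate_dose_response(seed = 3)
  f_nm <- hill_fit(d)
  d_um <- d
  d_um$concentration <- d_um$concentration / 1000
  f_um <- hill_fit(d_um)
  expect_equal(f_um$ec50 * 1000, f_nm$ec50, tolerance = 1e-4)
  expect_equal(f_um$emax, f_nm$emax, tolerance = 1e-6)
})

test_that("degenerate dose-response data is flagged, not fitted", {
  d0 <- tibble::tibble(concentration = c(0.3, 1, 3, 10),
                       response = rep(0, 4))
  f0 <- hill_fit(d0)
  expect_equal(f0$emax, 0)
  expect_true("ec50_unidentifiable" %in% f0$flags)
  expect_error(hill_fit(tibble::tibble(concentration = c(1, 3),
                                       response = c(10, 20))),
               class = "myoslice_domain_error")
})

test_that("force-frequency analysis classifies curve shapes", {
  pos <- tibble::tibble(rate = c(30, 60, 120, 180),
                        amplitude = c(2, 3, 4, 5))
  expect_equal(ffr_analysis(pos)$classification, "positive")

  # twin "cultured" set: decline above 60 bpm but gain at bradycardia
  tp <- tissue_params()
  rates <- c(12, 30, 60, 120, 180)
  amps <- vapply(rates, function(r) {
    max(active_force(seq(1, 1500, 2), tp, length_fraction = 0.83, rate = r))
  }, numeric(1))
  res <- ffr_analysis(tibble::tibble(rate = rates, amplitude = amps))
  expect_true(res$bradycardia_gain)
  expect_equal(res$classification, "negative")
  expect_equal(res$curve$normalized[res$curve$rate == 60], 1)

  expect_error(ffr_analysis(tibble::tibble(rate = 60, amplitude = 3)),
               class = "myoslice_domain_error")
})
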