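test_that("detected activity reproduces the printed coefficients", {
  m <- instrument_model()
  both <- placzek_invariants(1, 1, 1, 0, 0)
  dep <- placzek_invariants(0, 1, 1, 0, 0)
  expect_equal(detected_activity(both, m, "ideal")$value, 52)  # 45 + 4 + 3
  expect_equal(detected_activity(dep, m)$value, 4.1133 + 3.1142)
  # finite-aperture correction changes the polarised/depolarised ratio by ~3%
  r_pol <- detected_activity(both, m)$value / detected_activity(both, m, "ideal")$value
  r_dep <- detected_activity(dep, m)$value / detected_activity(dep, m, "ideal")$value
  expect_equal(round(100 * (r_dep / r_pol - 1)), 3)
  # transmittance factor divides only the parallel component
  m2 <- instrument_model(transmittance_factor = 2)
  expect_equal(detected_activity(both, m2, "ideal")$value, 45 + 4 + 3 / 2)
  expect_error(instrument_model(transmittance_factor = 0.5), ">= 1")
})

test_that("temperature factor matches direct evaluation of the formula", {
  expect_equal(temperature_factor(132, 0), 1)
  expect_equal(temperature_factor(132, 180), 1.534, tolerance = 1e-3)
  avg <- mean(c(temperature_factor(132, 20), temperature_factor(132, 180)))
  expect_equal(avg, 1.267, tolerance = 1e-3)
  expect_error(temperature_factor(-5, 100), "nu")
  # always >= 1, increasing in T, decreasing in nu
  nus <- c(50, 132, 600, 1800)
  expect_true(all(temperature_factor(nus, 150) >= 1))
  expect_true(all(diff(temperature_factor(nus, 150)) < 0))
  expect_true(temperature_factor(132, 180) > temperature_factor(132, 20))
})

test_that("thermal_scale converts between temperature conventions", {
  expect_equal(thermal_scale(5, 900, "zero_K", to_T = 0), 5)
  expect_equal(thermal_scale(27.3, 312), 33.56, tolerance = 1e-3)
  # identity when target matches the single source temperature
  x <- thermal_scale(2, 444, "zero_K", to_T = 77) /
       temperature_factor(444, 77)
  expect_equal(x, 2)
})

test_that("excitation_scale applies the fourth-power law", {
  expect_equal(excitation_scale(1, 1000, 18787.4, 18787.4), 1)
  f <- excitation_scale(1, 1000, 1e7 / 488.0, 1e7 / 532.27)
  expect_equal(f, ((18787.4 - 1000) / (20491.8 - 1000))^4, tolerance = 1e-4)
  nus <- seq(200, 3000, by = 200)
  fs <- excitation_scale(1, nus, 1e7 / 488.0, 1e7 / 532.27)
  expect_true(all(diff(fs) < 0))
  expect_error(excitation_scale(1, 20000, 18787.4, 18787.4), "anti-Stokes")
})

test_that("error budget composes additively as specified", {
  m <- instrument_model()
  zeroed <- instrument_model(illumination_error = 0, polarisation_error = 0,
                             impurity_floor = 0, T_vib_low = 20,
                             T_vib_high = 20)
  expect_equal(error_budget(10, 0.5, 900, 50, zeroed), 0.5)
  expect_equal(error_budget(10, 0.5, 900, 50, m), 1.303, tolerance = 1e-3)
  # monotone non-decreasing in every argument
  base <- error_budget(10, 0.5, 900, 50, m)
  expect_gte(error_budget(12, 0.5, 900, 50, m), base)
  expect_gte(error_budget(10, 0.7, 900, 50, m), base)
  expect_gte(error_budget(10, 0.5, 900, 60, m), base)
  # temperature term negligible at high wavenumber
  t_term <- function(nu) 0.5 * (temperature_factor(nu, 180) -
                                temperature_factor(nu, 20))
  expect_lt(t_term(1500), 1e-3)
  expect_gt(t_term(300), 0.04)
})

test_that("epsilon deviation clamps at the error bar and uses the stated denominator", {
  expect_equal(epsilon_deviation(c(10, 20), c(10, 20)), c(0, 0))
  expect_equal(epsilon_deviation(10, 10.5, sigma_exp = 1), 0)
  # strong low-frequency outlier of the bundled intensity table
  t1 <- reference_tables()$methanoate_intensities
  eps <- epsilon_deviation(t1$B3LYP_def2QZVPP, t1$I_exp, t1$I_err, t1$nu_exp)
  expect_equal(sum(t1$B3LYP_def2QZVPP), 175.3)
  expect_equal(eps[t1$mode == "nu17_16"], 0.077, tolerance = 1e-2)
  expect_error(epsilon_deviation(numeric(0), numeric(0)), "empty")
})

test_that("normalisation set iterates to the stated fixed point", {
  single <- normalisation_set(42, 900)
  expect_equal(single$normalised, 100)
  r <- normalisation_set(c(60, 30, 9), c(600, 700, 800))
  expect_equal(r$selected, c("1", "2"))
  expect_equal(r$normalised[1:2], c(200 / 3, 100 / 3), tolerance = 1e-9)
  expect_equal(sum(r$normalised[1:2]), 100, tolerance = 1e-9)
  # the bundled experimental strong set sums to 100 by construction
  t1 <- reference_tables()$methanoate_intensities
  strong <- c("nu5", "nu8_7_6", "nu9", "nu14")
  ex <- normalisation_set(t1$I_exp, t1$nu_exp, labels = t1$mode, set = strong)
  expect_equal(sum(ex$normalised[match(strong, t1$mode)]), 100,
               tolerance = 1e-9)
  expect_equal(ex$scale, 1)
  # low-wavenumber modes never enter the automatic iteration
  auto <- normalisation_set(t1$I_exp, t1$nu_exp, labels = t1$mode)
  expect_false("nu18" %in% auto$selected)
})
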