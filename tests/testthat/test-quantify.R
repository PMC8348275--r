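test_that("assignment matches self-generated spectra at zero offset", {
  fx <- mixture_fixture(seed = 21, noise_sd = 0)
  asg <- assign_signals(fx$mix, fx$specs)
  expect_true(all(asg$matched))
  ok <- !asg$ambiguous
  expect_true(all(abs(asg$nu_peak[ok] - asg$nu_pred[ok]) <= 0.2))
})

test_that("bands far from any peak are flagged unmatched", {
  fx <- mixture_fixture(seed = 22, noise_sd = 0)
  shifted <- fx$specs
  # predict a band in a region where the mixture has no signal at all
  shifted$alpha$bands[[1]]$nu_calc <- 2500
  asg <- assign_signals(fx$mix, shifted, tolerance = 15)
  row <- asg$conformer == "alpha" & asg$band == shifted$alpha$bands[[1]]$label
  expect_false(any(asg$matched[row]))
})

test_that("two bands over one peak raise the ambiguity flag, not an error", {
  rc <- toy_rotor()
  b1 <- vib_band("x1", 500, tensor = polarizability_tensor(1, 1, 1))
  b2 <- vib_band("x2", 503, tensor = polarizability_tensor(1, 1, 1))
  spec1 <- conformer_spec("c1", rc, list(b1))
  spec2 <- conformer_spec("c2", rc, list(b2))
  mix <- synthetic_mixture_spectrum(list(spec1, spec2), c(0.5, 0.5),
                                    noise_sd = 0, sigma = 2.5)
  asg <- assign_signals(mix, list(c1 = spec1, c2 = spec2))
  expect_true(any(asg$ambiguous))
})

test_that("factors recover a constructed global scale exactly", {
  sA <- synthetic_molecule(31, n_bands = 3, name = "alpha")
  sim <- simulate_conformer(sA, use_experimental_centers = FALSE)
  exp_spectrum <- raman_spectrum(sim$wavenumber, 0.7 * sim$intensity)
  specs <- list(alpha = sA, beta = synthetic_molecule(32, n_bands = 2,
                                                      name = "beta"))
  asg <- assign_signals(exp_spectrum, specs["alpha"])
  # pin the assignment at the exact predicted positions so that the
  # re-simulation is identical to the construction
  asg$nu_peak[asg$matched] <- asg$nu_pred[asg$matched]
  asg <- fit_peak_factors(exp_spectrum, asg, specs["alpha"])
  f <- asg$factor[!is.na(asg$factor)]
  expect_gte(length(f), 2L)
  expect_equal(f, rep(0.7, length(f)), tolerance = 1e-6)
  # scale invariance: doubling both spectra leaves factors unchanged
  exp2 <- raman_spectrum(sim$wavenumber, 1.4 * sim$intensity)
  asg2 <- assign_signals(exp2, specs["alpha"])
  asg2$nu_peak[asg2$matched] <- asg2$nu_pred[asg2$matched]
  asg2 <- fit_peak_factors(exp2, asg2, specs["alpha"])
  expect_equal(asg2$factor[!is.na(asg2$factor)], 2 * f, tolerance = 1e-6)
})

test_that("a two-conformer mixture with mild noise recovers the shares", {
  fx <- mixture_fixture(seed = 33, shares = c(0.6, 0.4), noise_sd = 0.01)
  asg <- fit_peak_factors(fx$mix, assign_signals(fx$mix, fx$specs), fx$specs)
  res <- shares_from_factors(asg)
  expect_lt(abs(res$share[res$conformer == "alpha"] - 60), 5)
  expect_lt(abs(res$share[res$conformer == "beta"] - 40), 5)
  expect_equal(sum(res$share), 100, tolerance = 1e-9)
})

test_that("share normalisation and propagation follow the stated formulas", {
  r <- shares_from_stats(c(ttg = 1.09, ttt = 0.92), c(0.39, 0.09))
  expect_equal(round(r$share), c(54, 46))
  expect_equal(round(r$share_sd), c(9, 9))
  expect_equal(sum(r$share), 100, tolerance = 1e-9)
  # two-conformer closed form
  x <- c(1.09, 0.92); s <- c(0.39, 0.09)
  expect_equal(r$share_sd[1],
               100 * sqrt((x[2] * s[1])^2 + (x[1] * s[2])^2) / sum(x)^2)
  # symmetry
  sym <- shares_from_stats(c(a = 2, b = 2), c(0.3, 0.3))
  expect_equal(sym$share, c(50, 50))
  expect_equal(sym$share_sd[1], sym$share_sd[2])
  expect_error(shares_from_stats(c(a = 0, b = 0), c(0, 0)), "zero")
})

test_that("population SD uses divisor N, as printed", {
  r <- shares_from_factors(list(a = c(1, 2, 3), b = c(2, 2)))
  expect_equal(r$mean_factor[r$conformer == "a"], 2)
  expect_equal(r$factor_sd[r$conformer == "a"], sqrt(2 / 3))
  # label permutation permutes outputs
  r2 <- shares_from_factors(list(b = c(2, 2), a = c(1, 2, 3)))
  expect_equal(r2$share[r2$conformer == "a"], r$share[r$conformer == "a"])
})

test_that("integral-method shares normalise to the reference signal", {
  df <- data.frame(conformer = c("A", "A", "B", "B"),
                   signal = c("s1", "s2", "s3", "s4"),
                   integral = c(4, 6, 3, 5),
                   error = c(0.2, 0.3, 0.2, 0.2))
  # all integral/cross-section quotients equal -> 50/50
  xs <- c(2, 3, 1.5, 2.5)
  r <- shares_from_integrals(df, xs, reference = "s3")
  expect_equal(sum(r$share), 100, tolerance = 1e-9)
  expect_equal(r$share, c(50, 50))
  expect_true(all(r$share_sd_with_errors >= r$share_sd))
  # unequal quotients: shares follow the per-conformer mean quotients
  r2 <- shares_from_integrals(df, c(2, 3, 3, 5), reference = "s3")
  expect_equal(r2$share, c(200 / 3, 100 / 3), tolerance = 1e-9)
  expect_equal(r2$mean_factor[r2$conformer == "B"], 1)  # reference scaled to 1
  expect_error(shares_from_integrals(df, xs, reference = "nope"), "unknown")
  df$excluded <- c(FALSE, FALSE, TRUE, FALSE)
  expect_error(shares_from_integrals(df, xs, reference = "s3"), "excluded")
})

test_that("peak-height and integral methods agree on a clean mixture", {
  fx <- mixture_fixture(seed = 44, shares = c(0.55, 0.45), noise_sd = 0)
  asg <- fit_peak_factors(fx$mix, assign_signals(fx$mix, fx$specs), fx$specs)
  peaks <- shares_from_factors(asg)
  # integral route: integrate isolated signals, divide by cross sections
  rows <- which(!is.na(asg$factor) & asg$foreign_frac < 0.01)
  ints <- do.call(rbind, lapply(rows, function(r) {
    sp <- fx$specs[[asg$conformer[r]]]
    res <- bounded_integrate(fx$mix, asg$nu_peak[r] + c(-12, 12))
    data.frame(conformer = asg$conformer[r], signal = asg$band[r],
               integral = res$mean,
               cross_section = band_cross_section(sp$bands[[asg$band[r]]]))
  }))
  if (length(unique(ints$conformer)) == 2) {
    integrals <- shares_from_integrals(ints)
    for (cn in integrals$conformer) {
      d <- abs(integrals$share[integrals$conformer == cn] -
               peaks$share[peaks$conformer == cn])
      tol <- 2 * (integrals$share_sd[integrals$conformer == cn] +
                  peaks$share_sd[peaks$conformer == cn]) + 3
      expect_lt(d, tol)
    }
  }
})
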