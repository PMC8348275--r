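test_that("line list conserves the detected activity for any rotor and T", {
  rc <- toy_rotor()
  for (band in list(toy_band(), polarised_band(),
                    vib_band("dep", 300, tensor = polarizability_tensor(xz = 1)))) {
    for (T_rot in c(5, 30, 120)) {
      ll <- build_linelist(band, rc, T_rot = T_rot)
      iv <- band$invariants
      expected <- attr(ll, "coverage") * (45 * iv$a_prime^2 + 7 * iv$gamma2)
      expect_equal(sum(ll$intensity), expected, tolerance = 1e-9)
      expect_true(all(ll$intensity >= 0))
      # Q0 lines sit exactly at the band origin (rigid-rotor identity)
      q0 <- ll$dJ == 0 & ll$dK == 0
      expect_true(all(ll$position[q0] == band$nu_calc))
    }
  }
})

test_that("purely polarised band gives a single line at the origin", {
  ll <- build_linelist(polarised_band(700), toy_rotor(), T_rot = 30)
  expect_true(all(ll$position == 700))
  expect_equal(sum(ll$intensity), attr(ll, "coverage") * 45, tolerance = 1e-9)
})

test_that("line list matches a brute-force double-loop oracle at low T", {
  # oracle: enumerate (J, K) states and all branches directly, with the
  # closed-form Delta-K = 0 strengths and explicit Boltzmann weights
  rc <- toy_rotor()
  band <- vib_band("ax", 400, tensor = polarizability_tensor(0, 0, 2))
  # axially symmetric tensor: anisotropy purely in Delta-K = 0
  T_rot <- 10
  # near-complete population coverage so that truncation does not enter
  ll <- build_linelist(band, rc, T_rot = T_rot, coverage = 1 - 1e-12)
  expect_true(all(ll$dK[!ll$iso] == 0))
  beta <- physical_constants()$hc_over_k / T_rot
  E <- function(J, K) 0.5 * J * (J + 1) + 0.5 * K^2
  Z <- 0; Jmax <- 80
  for (J in 0:Jmax) for (K in 0:J)
    Z <- Z + (2 - (K == 0)) * (2 * J + 1) * exp(-beta * E(J, K))
  oracle <- list()
  for (J in 0:40) for (K in 0:J) {
    p <- (2 - (K == 0)) * (2 * J + 1) * exp(-beta * E(J, K)) / Z
    for (dJ in -2:2) {
      Jp <- J + dJ
      if (Jp < 0 || Jp < K) next
      b <- switch(as.character(dJ),
        `0` = if (J == 0) 0 else pt_closed_q(J, K),
        `1` = if (J == 0) 0 else pt_closed_r(J, K),
        `2` = pt_closed_s(J, K),
        `-1` = if (J - 1 < max(K, 1)) 0 else
          pt_closed_r(J - 1, K) * (2 * (J - 1) + 1) / (2 * J + 1),
        `-2` = if (J - 2 < K || J < 2) 0 else
          pt_closed_s(J - 2, K) * (2 * (J - 2) + 1) / (2 * J + 1))
      if (b <= 0) next
      key <- sprintf("%.6f", 400 + E(Jp, K) - E(J, K))
      oracle[[key]] <- (oracle[[key]] %||% 0) + p * 7 * 4 * b
    }
  }
  # compare the few strongest aggregated line positions
  agg <- tapply(ll$intensity[!ll$iso],
                sprintf("%.6f", ll$position[!ll$iso]), sum)
  top <- names(sort(agg, decreasing = TRUE))[1:10]
  for (key in top)
    expect_equal(unname(agg[[key]]), oracle[[key]], tolerance = 1e-6)
})

test_that("gaussian_fold preserves intensity and merges rounded positions", {
  one <- data.frame(position = 500.123, intensity = 2.5)
  s <- gaussian_fold(one, sigma = 0.8)
  expect_equal(spectrum_integral(s), 2.5, tolerance = 1e-4 * 2.5)
  expect_equal(s$wavenumber[which.max(s$intensity)], 500.1, tolerance = 0.11)
  # two lines 0.004 cm-1 apart co-add to one rounded position
  two <- data.frame(position = c(500.102, 500.098), intensity = c(1, 1))
  s2 <- gaussian_fold(two, sigma = 0.5)
  expect_equal(max(s2$intensity), 2 * stats::dnorm(0, sd = 0.5),
               tolerance = 1e-3)
  expect_error(gaussian_fold(one, sigma = -1), "sigma")
})

test_that("folding many random lines conserves the summed intensity", {
  set.seed(7)
  n <- 5e4
  lines <- data.frame(position = runif(n, 100, 300),
                      intensity = rexp(n))
  s <- gaussian_fold(lines, sigma = 1.0)
  expect_equal(spectrum_integral(s), sum(lines$intensity),
               tolerance = 1e-4)
  # grid is anchored at multiples of the spacing
  expect_equal(s$wavenumber[1] / 0.1, round(s$wavenumber[1] / 0.1),
               tolerance = 1e-9)
})

test_that("simulate_conformer puts the Q0 peak of a polarised band at its centre", {
  rc <- toy_rotor()
  spec <- conformer_spec("t", rc, list(polarised_band(650, "p1")))
  for (T_rot in c(10, 30, 60)) {
    s <- simulate_conformer(spec, T_rot = T_rot)
    expect_equal(s$wavenumber[which.max(s$intensity)], 650, tolerance = 0.2)
  }
})

test_that("experimental centers are honoured and their absence is an error", {
  rc <- toy_rotor()
  b1 <- vib_band("with", 500, nu_exp = 488, tensor = polarizability_tensor(1, 1, 1))
  b2 <- vib_band("without", 900, tensor = polarizability_tensor(1, 1, 1))
  spec <- conformer_spec("c", rc, list(b1, b2))
  s <- simulate_conformer(spec, use_experimental_centers = TRUE, bands = "with")
  expect_equal(s$wavenumber[which.max(s$intensity)], 488, tolerance = 0.2)
  expect_error(simulate_conformer(spec, use_experimental_centers = TRUE),
               "without")
})

test_that("doubling gamma'^2 doubles the anisotropic wings exactly", {
  rc <- toy_rotor()
  t1 <- polarizability_tensor(xz = 1)
  t2 <- polarizability_tensor(xz = sqrt(2))  # gamma2 doubled
  s1 <- simulate_conformer(conformer_spec("a", rc, list(vib_band("b", 400, tensor = t1))),
                           frequency_factor = FALSE, thermal = "none")
  s2 <- simulate_conformer(conformer_spec("a", rc, list(vib_band("b", 400, tensor = t2))),
                           frequency_factor = FALSE, thermal = "none")
  expect_equal(spectrum_integral(s2), 2 * spectrum_integral(s1),
               tolerance = 1e-9)
})

test_that("raising T_rot never increases the Q0 peak-height fraction", {
  rc <- toy_rotor()
  spec <- conformer_spec("t", rc, list(toy_band(500)))
  frac <- vapply(c(10, 20, 40, 80), function(T_rot) {
    s <- simulate_conformer(spec, T_rot = T_rot, frequency_factor = FALSE,
                            thermal = "none")
    max(s$intensity) / spectrum_integral(s)
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})

test_that("band_cross_section honours precomputed values and factors", {
  b <- toy_band(500)
  iv <- b$invariants
  m <- instrument_model()
  raw <- band_cross_section(b, instrument = m, geometry = "ideal",
                            thermal = "none", frequency_factor = FALSE)
  expect_equal(raw, 45 * iv$a_prime^2 + 7 * iv$gamma2)
  b$cross_section <- 3.14
  expect_equal(band_cross_section(b), 3.14)
})
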