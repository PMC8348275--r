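# Synthetic molecules and mixture spectra. Real transition polarisabilities
# for the target esters are not tabulated anywhere in machine-readable form,
# so end-to-end pipeline tests run on generated, physically plausible
# near-prolate rotors with random band positions and tensors; they are
# labelled synthetic throughout.

.with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic near-prolate conformer
#'
#' Deterministically (per seed) generates a near-prolate rotor with the
#' requested Ray asymmetry, `n_bands` random band positions in
#' 100-1800 cm-1, and random symmetric transition-polarisability tensors. A
#' fraction `polarisation_mix` of the bands is polarised (isotropic-dominant
#' tensor, sharp Q branch), the rest depolarised (traceless tensor). The
#' default rotational constants emulate an ester-sized chain molecule
#' (C around 0.05-0.09 cm-1).
#'
#' @param seed Integer seed; equal seeds give identical specs.
#' @param kappa_target Asymmetry in \[-1, 0\]; positive (oblate) targets are
#'   not implemented.
#' @param n_bands Number of vibrational bands (default 5).
#' @param polarisation_mix Fraction of polarised bands (default 0.7).
#' @param name Conformer name (default `"synth<seed>"`).
#' @return A [conformer_spec].
#' @export
synthetic_molecule <- function(seed, kappa_target = -0.9, n_bands = 5L,
                               polarisation_mix = 0.7, name = NULL) {
  if (!.is_number(kappa_target) || kappa_target < -1 || kappa_target > 0)
    .stopf("kappa_target must lie in [-1, 0] (oblate generation not implemented)")
  if (is.null(name)) name <- paste0("synth", seed)
  .with_seed(seed, {
    C <- stats::runif(1, 0.05, 0.09)
    A <- C * stats::runif(1, 3, 5)
    B <- (kappa_target * (A - C) + A + C) / 2
    rotor <- rotor_constants(A, B, C)
    nu <- sort(stats::runif(n_bands, 100, 1800))
    pol <- stats::runif(n_bands) < polarisation_mix
    bands <- lapply(seq_len(n_bands), function(i) {
      S <- matrix(stats::rnorm(9), 3L, 3L)
      S <- (S + t(S)) / 2
      G <- S - diag(3) * sum(diag(S)) / 3   # traceless (depolarised) part
      scale <- stats::runif(1, 0.5, 2)
      M <- if (pol[i]) scale * (diag(3) + 0.3 * G) else scale * G
      vib_band(sprintf("b%02d", i), nu_calc = nu[i],
               tensor = .tensor_from_matrix(M))
    })
    conformer_spec(name, rotor, bands,
                   provenance = sprintf("synthetic (seed %d)", seed))
  })
}

#' Generate a synthetic two-or-more-conformer mixture spectrum
#'
#' Sums the simulated contours of the given conformers weighted by the true
#' shares, then adds a linear baseline drift and i.i.d. Gaussian noise. The
#' returned spectrum carries a `truth` entry in its metadata with everything
#' needed to score a recovery: the shares, the seeds, the noise level and
#' the drift. With zero noise and drift and a single conformer the output
#' equals [simulate_conformer] exactly.
#'
#' @param specs List of [conformer_spec] objects.
#' @param true_shares Fractions summing to 1, one per conformer.
#' @param T_rot,sigma,instrument,... Passed to [simulate_conformer].
#' @param noise_sd Noise standard deviation as a fraction of the noise-free
#'   maximum (default 0.01).
#' @param baseline_drift Linear drift amplitude over the full range, as a
#'   fraction of the maximum (default 0).
#' @param seed Seed for the noise.
#' @return A [raman_spectrum] with `meta$truth`.
#' @export
synthetic_mixture_spectrum <- function(specs, true_shares, T_rot = 30,
                                       sigma = 1.0,
                                       instrument = instrument_model(),
                                       noise_sd = 0.01, baseline_drift = 0,
                                       seed = 1L, ...) {
  if (abs(sum(true_shares) - 1) > 1e-9) .stopf("shares must sum to 1")
  if (length(true_shares) != length(specs))
    .stopf("one share per conformer required")
  sims <- lapply(specs, simulate_conformer, T_rot = T_rot, sigma = sigma,
                 instrument = instrument, ...)
  spacing <- sims[[1L]]$meta$grid_spacing
  if (is.null(spacing)) spacing <- 0.1
  lo <- min(vapply(sims, function(s) s$wavenumber[1L], numeric(1)))
  hi <- max(vapply(sims, function(s) max(s$wavenumber), numeric(1)))
  i0 <- round(lo / spacing); i1 <- round(hi / spacing)
  grid <- (i0:i1) * spacing
  total <- numeric(length(grid))
  for (i in seq_along(sims)) {
    s <- sims[[i]]
    off <- round(s$wavenumber[1L] / spacing) - i0
    idx <- off + seq_along(s$wavenumber)
    total[idx] <- total[idx] + true_shares[i] * s$intensity
  }
  peak <- max(total)
  if (baseline_drift != 0)
    total <- total + baseline_drift * peak *
      (grid - grid[1L]) / (grid[length(grid)] - grid[1L])
  if (noise_sd > 0)
    total <- total + .with_seed(seed,
      stats::rnorm(length(grid), sd = noise_sd * peak))
  raman_spectrum(grid, total, meta = list(
    truth = list(shares = true_shares,
                 conformers = vapply(specs, `[[`, "", "name"),
                 noise_sd = noise_sd, baseline_drift = baseline_drift,
                 seed = seed, T_rot = T_rot, sigma = sigma)))
}
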