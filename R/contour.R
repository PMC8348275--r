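#' Build the rovibrational line list of one band
#'
#' Enumerates the thermally populated rotational states of a near-symmetric
#' top (see [rot_populations]) and emits, per state of normalised weight p:
#' an isotropic line at the band origin with intensity `p C_a a'^2`, and for
#' each Delta-K channel m in 0, +/-1, +/-2 and each allowed Delta-J branch a
#' line at `nu0 + E(J', K + m) - E(J, K)` with intensity
#' `p C_g g(m) b(J, K, dJ, m)`, where `g(0) = gamma0^2`,
#' `g(+/-1) = gamma1^2 / 2`, `g(+/-2) = gamma2^2 / 2` (the equal +/-m split is
#' exact for real symmetric tensors) and b is the Placzek-Teller factor. The
#' completeness sum rule makes the summed line intensity equal
#' `coverage * (C_a a'^2 + C_g gamma'^2)` to machine precision, mirroring the
#' invariance of the total band intensity under the rigid-rotor sum.
#'
#' Hot bands are not simulated line-by-line; vibrational thermal effects
#' enter only through the scalar temperature factor (see
#' [temperature_factor]).
#'
#' @param band A [vib_band].
#' @param rc A [rotor_constants] object.
#' @param T_rot Rotational temperature in K.
#' @param coverage,J_cap Passed to [rot_populations].
#' @param C_a,C_g Detection coefficients for the isotropic/anisotropic parts
#'   (ideal 90-degree values 45 and 7; see [detected_activity]).
#' @param origin Band origin in cm-1; defaults to `band$nu_calc`.
#' @param states Optional precomputed state table from [rot_populations]
#'   (reused across the bands of one conformer).
#' @return A data.frame of class `raman_linelist` with columns `position`,
#'   `intensity`, `J`, `K`, `dJ`, `dK`, `iso`, and attributes `band`,
#'   `coverage`, `C_a`, `C_g`.
#' @export
build_linelist <- function(band, rc, T_rot = 30, coverage = 0.9999,
                           J_cap = 200L, C_a = 45, C_g = 7, origin = NULL,
                           states = NULL) {
  stopifnot(inherits(band, "vib_band"), inherits(rc, "rotor_constants"))
  if (is.null(origin)) origin <- band$nu_calc
  inv <- band$invariants
  if (is.null(states))
    states <- rot_populations(rc, T_rot, coverage = coverage, J_cap = J_cap)
  nS <- nrow(states)
  gam <- inv$gamma2
  g_channel <- c(`-2` = inv$gamma2_dk2 / 2, `-1` = inv$gamma2_dk1 / 2,
                 `0` = inv$gamma2_dk0, `1` = inv$gamma2_dk1 / 2,
                 `2` = inv$gamma2_dk2 / 2)
  pieces <- vector("list", 26L)
  k <- 0L
  # isotropic Q lines (all exactly at the origin)
  if (inv$a_prime != 0) {
    k <- k + 1L
    pieces[[k]] <- data.frame(position = origin,
                              intensity = states$p * C_a * inv$a_prime^2,
                              J = states$J, K = states$K, dJ = 0L, dK = 0L,
                              iso = TRUE)
  }
  if (gam > 0) {
    for (m in -2:2) {
      gm <- g_channel[[as.character(m)]]
      if (gm == 0) next
      Kp <- states$K + m
      for (dJ in -2:2) {
        Jp <- states$J + dJ
        ok <- Jp >= 0 & abs(Kp) <= Jp
        if (!any(ok)) next
        b <- numeric(nS)
        b[ok] <- placzek_teller_b(states$J[ok], states$K[ok], dJ, m)
        keep <- b > 0
        if (!any(keep)) next
        Eup <- rot_energy(rc, Jp[keep], abs(Kp[keep]))
        k <- k + 1L
        pieces[[k]] <- data.frame(
          position = origin + Eup - states$energy[keep],
          intensity = states$p[keep] * C_g * gm * b[keep],
          J = states$J[keep], K = states$K[keep], dJ = dJ, dK = m,
          iso = FALSE)
      }
    }
  }
  lines <- do.call(rbind, pieces[seq_len(k)])
  if (is.null(lines))
    lines <- data.frame(position = numeric(0), intensity = numeric(0),
                        J = integer(0), K = integer(0), dJ = integer(0),
                        dK = integer(0), iso = logical(0))
  rownames(lines) <- NULL
  structure(lines, class = c("raman_linelist", "data.frame"),
            band = band$label, coverage = attr(states, "coverage"),
            C_a = C_a, C_g = C_g, origin = origin)
}

#' Fold a line list into a Gaussian band contour
#'
#' Line positions are rounded to 0.01 cm-1 and co-added, then every line
#' contributes an area-preserving Gaussian of standard deviation `sigma`,
#' truncated at +/-5 sigma, on a uniform wavenumber grid anchored at integer
#' multiples of the spacing. The rounding and truncation follow the usual
#' speed-ups for folding millions of rovibrational lines; the integral of
#' the folded spectrum matches the summed line intensity to ~1e-6 relative
#' (truncation loss).
#'
#' @param lines A `raman_linelist` (or any data.frame with `position` and
#'   `intensity`).
#' @param sigma Gaussian standard deviation in cm-1 (> 0).
#' @param grid_spacing Grid spacing in cm-1 (default 0.1).
#' @param grid_range Optional `c(lo, hi)` to force the output range.
#' @return A [raman_spectrum]; intensities are spectral densities so that
#'   the trapezoidal integral reproduces the line intensities.
#' @export
gaussian_fold <- function(lines, sigma = 1.0, grid_spacing = 0.1,
                          grid_range = NULL) {
  if (!.is_number(sigma) || sigma <= 0) .stopf("sigma must be > 0")
  if (!.is_number(grid_spacing) || grid_spacing <= 0)
    .stopf("grid_spacing must be > 0")
  pos <- round(lines$position * 100) / 100
  I <- lines$intensity
  if (!length(pos)) .stopf("empty line list")
  agg <- rowsum(I, group = pos)        # co-add identical rounded positions
  pos <- as.numeric(rownames(agg))
  I <- as.numeric(agg)
  if (is.null(grid_range))
    grid_range <- c(min(pos) - 5 * sigma, max(pos) + 5 * sigma)
  i0 <- floor(grid_range[1L] / grid_spacing)
  i1 <- ceiling(grid_range[2L] / grid_spacing)
  grid <- (i0:i1) * grid_spacing
  n <- length(grid)
  half <- ceiling(5 * sigma / grid_spacing)
  # nearest grid index per line; scatter-add one kernel offset at a time
  ic <- round(pos / grid_spacing) - i0
  spec <- numeric(n)
  for (s in (-half):half) {
    idx <- ic + s
    ok <- idx >= 0L & idx < n
    if (!any(ok)) next
    x <- grid[idx[ok] + 1L] - pos[ok]
    ok2 <- abs(x) <= 5 * sigma
    if (!any(ok2)) next
    val <- I[ok][ok2] * stats::dnorm(x[ok2], sd = sigma)
    tgt <- idx[ok][ok2] + 1L
    acc <- rowsum(val, group = tgt)
    spec[as.integer(rownames(acc))] <- spec[as.integer(rownames(acc))] + acc
  }
  raman_spectrum(grid, spec,
                 meta = list(sigma = sigma, grid_spacing = grid_spacing,
                             band = attr(lines, "band")))
}

#' Simulate the Raman band contour spectrum of one conformer
#'
#' Sums the folded rovibrational contours of all bands of a conformer. Band
#' centres come from the experimental wavenumbers when
#' `use_experimental_centers = TRUE` (erroring, by name, on any selected band
#' that lacks one), otherwise from the harmonic wavenumbers, optionally
#' multiplied by `scale_factor`. Per-band intensities are weighted by the
#' detection coefficients of `instrument` (finite-aperture geometry and
#' monochromator transmittance, see [detected_activity]), by the vibrational
#' temperature factor in the 20/180 K-average convention, and by the
#' `(nu0 - nu_k)^4 / nu_k` frequency factor converting scattering activities
#' to relative cross sections. The defaults `T_rot = 30` K and
#' `sigma = 1.0` cm-1 are the standard choice for jet spectra.
#'
#' @param spec A [conformer_spec].
#' @param T_rot Rotational temperature in K (default 30).
#' @param sigma Gaussian folding standard deviation in cm-1 (default 1.0).
#' @param use_experimental_centers Use `nu_exp` as band origins.
#' @param instrument An [instrument_model].
#' @param geometry `"corrected"` (default) or `"ideal"` detection
#'   coefficients.
#' @param bands Optional character vector restricting which bands are
#'   simulated.
#' @param scale_factor Multiplier on harmonic wavenumbers (default 1).
#' @param thermal `"avg_low_high"` (default; divide nothing, multiply by the
#'   mean temperature factor at `T_vib_low`/`T_vib_high`) or `"none"`.
#' @param frequency_factor Apply `(nu0 - nu_k)^4 / nu_k` (default TRUE).
#' @param coverage,J_cap,grid_spacing Passed through to [rot_populations]
#'   and [gaussian_fold].
#' @return A [raman_spectrum] covering all bands.
#' @export
simulate_conformer <- function(spec, T_rot = 30, sigma = 1.0,
                               use_experimental_centers = FALSE,
                               instrument = instrument_model(),
                               geometry = c("corrected", "ideal"),
                               bands = NULL, scale_factor = 1,
                               thermal = c("avg_low_high", "none"),
                               frequency_factor = TRUE,
                               coverage = 0.9999, J_cap = 200L,
                               grid_spacing = 0.1) {
  stopifnot(inherits(spec, "conformer_spec"))
  geometry <- match.arg(geometry)
  thermal <- match.arg(thermal)
  states <- rot_populations(spec$rotor, T_rot, coverage = coverage,
                            J_cap = J_cap)
  use <- spec$bands
  if (!is.null(bands)) {
    missing_bands <- setdiff(bands, names(use))
    if (length(missing_bands))
      .stopf("unknown band(s): %s", paste(missing_bands, collapse = ", "))
    use <- use[bands]
  }
  all_lines <- lapply(use, function(b) {
    if (use_experimental_centers) {
      if (is.null(b$nu_exp))
        .stopf("band '%s' of conformer '%s' has no experimental wavenumber",
               b$label, spec$name)
      origin <- b$nu_exp
    } else {
      origin <- b$nu_calc * scale_factor
    }
    da <- detected_activity(b$invariants, instrument, geometry)
    if (da$value <= 0)
      .stopf("band '%s' has zero detected activity", b$label)
    w <- band_cross_section(b, origin = origin, instrument = instrument,
                            geometry = geometry, thermal = thermal,
                            frequency_factor = frequency_factor) / da$value
    ll <- build_linelist(b, spec$rotor, T_rot = T_rot, coverage = coverage,
                         J_cap = J_cap, C_a = da$C_a, C_g = da$C_g,
                         origin = origin, states = states)
    ll$intensity <- ll$intensity * w
    ll[c("position", "intensity")]
  })
  lines <- do.call(rbind, all_lines)
  out <- gaussian_fold(lines, sigma = sigma, grid_spacing = grid_spacing)
  out$meta <- list(conformer = spec$name, T_rot = T_rot, sigma = sigma,
                   geometry = geometry,
                   centers = if (use_experimental_centers) "exp" else "calc")
  out
}

#' Relative Raman cross section of one band
#'
#' The per-band weight used by [simulate_conformer]: the detected activity
#' `C_a a'^2 + C_g gamma'^2` of the instrument geometry, times the
#' vibrational temperature factor in the chosen convention, times the
#' `(nu0 - nu_k)^4 / nu_k` frequency factor (scaled by 1e-12 to keep the
#' numbers of order one). A band's precomputed `cross_section` field, when
#' set, takes precedence. Integral-method quantification divides measured
#' integrals by exactly this quantity.
#'
#' @param band A [vib_band].
#' @param origin Band origin in cm-1 (default `nu_exp` if present, else
#'   `nu_calc`).
#' @param instrument An [instrument_model].
#' @param geometry,thermal,frequency_factor As in [simulate_conformer].
#' @return Scalar relative cross section.
#' @export
band_cross_section <- function(band, origin = NULL,
                               instrument = instrument_model(),
                               geometry = c("corrected", "ideal"),
                               thermal = c("avg_low_high", "none"),
                               frequency_factor = TRUE) {
  stopifnot(inherits(band, "vib_band"))
  geometry <- match.arg(geometry)
  thermal <- match.arg(thermal)
  if (!is.null(band$cross_section)) return(band$cross_section)
  if (is.null(origin))
    origin <- if (!is.null(band$nu_exp)) band$nu_exp else band$nu_calc
  w <- detected_activity(band$invariants, instrument, geometry)$value
  if (thermal == "avg_low_high")
    w <- w * mean(c(temperature_factor(origin, instrument$T_vib_low),
                    temperature_factor(origin, instrument$T_vib_high)))
  if (frequency_factor) {
    nu0 <- instrument$laser_wavenumber
    if (nu0 <= origin)
      .stopf("band '%s' lies beyond the excitation wavenumber", band$label)
    w <- w * (nu0 - origin)^4 / origin * 1e-12
  }
  w
}
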