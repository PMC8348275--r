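#' Instrument model: detection coefficients and error fractions
#'
#' Collects the detection-side parameters of a 90-degree Raman setup:
#' \itemize{
#'   \item Finite-aperture geometry coefficients of the two detected
#'     polarisation components, `A(perp_i, perp_s) = c_perp_a a'^2 +
#'     c_perp_g gamma'^2` and `A(perp_i, par_s) = c_par_a a'^2 +
#'     c_par_g gamma'^2`. Defaults are the finite-collection-angle values
#'     45 / 4.1133 and 0.0423 / 3.1142; the ideal 90-degree alternative is
#'     45 / 4 and 0 / 3.
#'   \item Monochromator transmittance factor `f` (>= 1): vertically
#'     polarised light is transmitted f times less than horizontal; the
#'     calculated parallel component is divided by f rather than correcting
#'     the experiment. Its wavelength dependence (roughly 1.5-2.5) is
#'     collapsed to one scalar per analysis with a homogeneous +/-0.05
#'     uncertainty routed into the error budget.
#'   \item Flat fractional error terms: `illumination_error` (CCD
#'     inhomogeneity, 1.5%), `polarisation_error` (transmittance-factor
#'     uncertainty, 1.5%), `impurity_floor` (reproducibility/dimer floor, 1%
#'     of the strongest signal).
#'   \item Vibrational-temperature bracket `T_vib_low` = 20 K,
#'     `T_vib_high` = 180 K used for the thermal correction and its error.
#' }
#'
#' @param c_perp_a,c_perp_g,c_par_a,c_par_g Geometry coefficients.
#' @param transmittance_factor Scalar f >= 1 (default 1).
#' @param transmittance_error Uncertainty of f (default 0.05).
#' @param laser_wavenumber Excitation wavenumber in cm-1 (default
#'   1e7/532.27).
#' @param illumination_error,polarisation_error,impurity_floor Fractions.
#' @param T_vib_low,T_vib_high Vibrational temperature bracket in K.
#' @return Object of class `instrument_model`.
#' @export
instrument_model <- function(c_perp_a = 45, c_perp_g = 4.1133,
                             c_par_a = 0.0423, c_par_g = 3.1142,
                             transmittance_factor = 1,
                             transmittance_error = 0.05,
                             laser_wavenumber = 1e7 / 532.27,
                             illumination_error = 0.015,
                             polarisation_error = 0.015,
                             impurity_floor = 0.01,
                             T_vib_low = 20, T_vib_high = 180) {
  coefs <- c(c_perp_a, c_perp_g, c_par_a, c_par_g)
  if (any(!is.finite(coefs)) || any(coefs < 0))
    .stopf("geometry coefficients must be >= 0")
  if (!.is_number(transmittance_factor) || transmittance_factor < 1)
    .stopf("transmittance factor must be >= 1")
  fr <- c(illumination_error, polarisation_error, impurity_floor)
  if (any(fr < 0) || any(fr > 1)) .stopf("error fractions must be in [0, 1]")
  structure(list(c_perp_a = c_perp_a, c_perp_g = c_perp_g,
                 c_par_a = c_par_a, c_par_g = c_par_g,
                 transmittance_factor = transmittance_factor,
                 transmittance_error = transmittance_error,
                 laser_wavenumber = laser_wavenumber,
                 illumination_error = illumination_error,
                 polarisation_error = polarisation_error,
                 impurity_floor = impurity_floor,
                 T_vib_low = T_vib_low, T_vib_high = T_vib_high),
            class = "instrument_model")
}

#' Detected Raman activity of a band
#'
#' Without a polarisation analyser the recorded intensity is proportional to
#' `A(perp_i, perp_s) + A(perp_i, par_s)`, with the parallel component
#' divided by the monochromator transmittance factor f. This gives effective
#' coefficients `C_a = c_perp_a + c_par_a / f` and
#' `C_g = c_perp_g + c_par_g / f`; with the ideal geometry and f = 1 the
#' classical `45 a'^2 + 7 gamma'^2` is recovered.
#'
#' @param inv A [placzek_invariants] object.
#' @param model An [instrument_model].
#' @param geometry `"corrected"` (finite aperture, default) or `"ideal"`.
#' @return List with `C_a`, `C_g` and `value = C_a a'^2 + C_g gamma'^2`.
#' @export
#' @examples
#' detected_activity(placzek_invariants(1, 1, 1, 0, 0),
#'                   instrument_model(), "ideal")$value  # 52
detected_activity <- function(inv, model = instrument_model(),
                              geometry = c("corrected", "ideal")) {
  stopifnot(inherits(inv, "placzek_invariants"),
            inherits(model, "instrument_model"))
  geometry <- match.arg(geometry)
  f <- model$transmittance_factor
  if (geometry == "ideal") {
    C_a <- 45 + 0 / f
    C_g <- 4 + 3 / f
  } else {
    C_a <- model$c_perp_a + model$c_par_a / f
    C_g <- model$c_perp_g + model$c_par_g / f
  }
  list(C_a = C_a, C_g = C_g,
       value = C_a * inv$a_prime^2 + C_g * inv$gamma2)
}

#' Vibrational temperature (visibility) factor
#'
#' `I_T(nu, T) = 1 / (1 - exp(-hc nu / kB T))` for a single harmonic mode,
#' assuming hot transitions coincide with the cold ones. Returns exactly 1
#' at T = 0. Always >= 1, increasing in T and decreasing in nu.
#'
#' @param nu Wavenumber in cm-1 (> 0, vectorised).
#' @param T_vib Vibrational temperature in K (>= 0).
#' @return Dimensionless factor.
#' @export
#' @examples
#' temperature_factor(132, 180)  # 1.534
temperature_factor <- function(nu, T_vib) {
  if (any(nu <= 0)) .stopf("nu must be > 0")
  if (!.is_number(T_vib) || T_vib < 0) .stopf("T_vib must be >= 0")
  if (T_vib == 0) return(rep(1, length(nu)))
  1 / (1 - exp(-.const$hc_over_k * nu / T_vib))
}

#' Rescale an intensity between vibrational-temperature conventions
#'
#' Multiplies I by `I_T(nu, to_T)` divided by the factor already contained in
#' the source convention: 1 for a 0 K (cold) intensity, or the mean of
#' `I_T(nu, 20 K)` and `I_T(nu, 180 K)` for the jet-average convention. Used
#' e.g. to extrapolate integrated jet intensities to 298 K.
#'
#' @param I Intensity (vectorised with `nu_used`).
#' @param nu_used Wavenumber in cm-1 at which the factor is evaluated.
#' @param from_convention `"zero_K"` or `"avg_20_180"`.
#' @param to_T Target temperature in K.
#' @param T_low,T_high Bracket for the average convention (defaults 20/180).
#' @return Scaled intensity.
#' @export
thermal_scale <- function(I, nu_used,
                          from_convention = c("avg_20_180", "zero_K"),
                          to_T = 298, T_low = 20, T_high = 180) {
  from_convention <- match.arg(from_convention)
  if (any(nu_used <= 0)) .stopf("nu_used must be > 0")
  src <- switch(from_convention,
    zero_K = 1,
    avg_20_180 = (temperature_factor(nu_used, T_low) +
                  temperature_factor(nu_used, T_high)) / 2)
  I * temperature_factor(nu_used, to_T) / src
}

#' Correct an intensity for a different excitation wavelength
#'
#' Scattered intensity scales with the fourth power of the scattered-photon
#' wavenumber; moving a Stokes band at `nu_k` from excitation `nu0_from` to
#' `nu0_to` multiplies it by `((nu0_to - nu_k)/(nu0_from - nu_k))^4`.
#'
#' @param I Intensity.
#' @param nu_k Band wavenumber in cm-1.
#' @param nu0_from,nu0_to Excitation wavenumbers in cm-1 (> `nu_k`).
#' @return Scaled intensity.
#' @export
excitation_scale <- function(I, nu_k, nu0_from, nu0_to) {
  if (any(nu0_from <= nu_k) || any(nu0_to <= nu_k))
    .stopf("anti-Stokes regime: excitation must exceed the band wavenumber")
  I * ((nu0_to - nu_k) / (nu0_from - nu_k))^4
}

#' Additive experimental error budget for one signal
#'
#' Total uncertainty = integration error + 1.5% of the signal for
#' non-uniform illumination + 1.5% for polarisation-selectivity uncertainty
#' + the vibrational-temperature half-spread
#' `I * 0.5 (I_T(nu, T_high) - I_T(nu, T_low))` + 1% of the strongest signal
#' in the spectral window (reproducibility and trace-impurity floor). The
#' terms are combined additively (a deliberately conservative budget), so
#' the result is monotone non-decreasing in every argument.
#'
#' @param I_signal Signal intensity (>= 0).
#' @param sigma_integration Absolute integration error.
#' @param nu_exp Experimental wavenumber in cm-1.
#' @param I_strongest Strongest signal in the covered window.
#' @param model An [instrument_model].
#' @return Total uncertainty, same units as `I_signal`.
#' @export
error_budget <- function(I_signal, sigma_integration, nu_exp, I_strongest,
                         model = instrument_model()) {
  stopifnot(inherits(model, "instrument_model"))
  if (any(c(I_signal, sigma_integration, nu_exp, I_strongest) < 0))
    .stopf("all inputs must be >= 0")
  temp_spread <- 0.5 * (temperature_factor(nu_exp, model$T_vib_high) -
                        temperature_factor(nu_exp, model$T_vib_low))
  sigma_integration +
    I_signal * model$illumination_error +
    I_signal * model$polarisation_error +
    I_signal * temp_spread +
    I_strongest * model$impurity_floor
}

#' Relative deviation between calculated and experimental intensities
#'
#' Per band: `eps_k = max(0, |I_calc - I_exp| - sigma_exp) / sum(I_calc over
#' bands with nu_calc < nu_max)`. The deviation is clamped to zero when
#' theory lies inside the experimental error bar, and referenced to the
#' total calculated fundamental intensity below `nu_max` (default
#' 1800 cm-1), giving a global-spectrum perspective.
#'
#' @param I_calc,I_exp Aligned calculated and experimental intensities.
#' @param sigma_exp Experimental uncertainties (default 0).
#' @param nu_calc Calculated wavenumbers, used for the denominator cut.
#' @param nu_max Denominator cutoff in cm-1 (default 1800).
#' @return Fraction per band.
#' @export
epsilon_deviation <- function(I_calc, I_exp, sigma_exp = 0, nu_calc = NULL,
                              nu_max = 1800) {
  if (!length(I_calc)) .stopf("empty calculated set")
  if (length(I_exp) != length(I_calc))
    .stopf("I_calc and I_exp must be aligned")
  sigma_exp <- rep_len(sigma_exp, length(I_calc))
  denom_set <- if (is.null(nu_calc)) rep(TRUE, length(I_calc))
               else nu_calc < nu_max
  denom <- sum(I_calc[denom_set])
  if (denom <= 0) .stopf("denominator set has no intensity")
  pmax(0, abs(I_calc - I_exp) - sigma_exp) / denom
}

#' Iterative selection of the normalisation set of fundamentals
#'
#' Normalises relative intensities on the subset of strong fundamentals:
#' starting from all fundamentals above `nu_min` (default 500 cm-1), their
#' sum is set to 100, members contributing less than `share_min` (default
#' 10%) are dropped, and the procedure repeats to a fixed point. Strong
#' bands are predicted more reliably and the low-wavenumber modes carry
#' large thermal uncertainty, hence the cut. An explicit `set` of band
#' indices or names bypasses the iteration.
#'
#' @param intensity Intensities per band.
#' @param nu Wavenumbers per band in cm-1.
#' @param labels Optional band names.
#' @param nu_min Lower wavenumber cut (default 500).
#' @param share_min Minimum fractional contribution (default 0.10).
#' @param set Optional explicit selection (indices or labels).
#' @return List with `selected` (labels or indices), `normalised` (full
#'   intensity vector rescaled so the selected subset sums to 100) and
#'   `scale` (the multiplier applied).
#' @export
normalisation_set <- function(intensity, nu, labels = NULL, nu_min = 500,
                              share_min = 0.10, set = NULL) {
  n <- length(intensity)
  if (length(nu) != n) .stopf("intensity and nu must be aligned")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (!is.null(set)) {
    sel <- if (is.character(set)) match(set, labels) else as.integer(set)
    if (anyNA(sel)) .stopf("unknown band in explicit set")
  } else {
    sel <- which(nu > nu_min)
    if (!length(sel)) .stopf("no fundamental above %g cm-1", nu_min)
    repeat {
      tot <- sum(intensity[sel])
      keep <- intensity[sel] >= share_min * tot
      if (all(keep)) break
      sel <- sel[keep]
      if (!length(sel))
        .stopf("normalisation set is empty; supply an explicit set")
    }
  }
  scale <- 100 / sum(intensity[sel])
  list(selected = labels[sel], normalised = intensity * scale, scale = scale)
}
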