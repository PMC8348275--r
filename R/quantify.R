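#' Assign predicted bands to experimental peaks
#'
#' First step of the two-step analysis: each conformer's harmonically
#' predicted band positions (optionally scaled) are matched to the nearest
#' experimental peak within `tolerance`. Unmatched bands are flagged, and so
#' are ambiguous cases where two predicted bands claim the same experimental
#' peak (overlapping simulated contours cannot be separated by peak height).
#' Ambiguity is a flag, not an error — it marks signals for manual exclusion.
#'
#' @param exp_spectrum A [raman_spectrum] of the measurement.
#' @param specs List of [conformer_spec] objects.
#' @param tolerance Maximum |predicted - observed| in cm-1 (default 15,
#'   about the size of typical anharmonic shifts).
#' @param scale_factor Multiplier on harmonic wavenumbers (default 1).
#' @param min_prominence Minimum peak intensity, as a fraction of the
#'   spectrum maximum, for a local maximum to count as a peak (default
#'   0.005).
#' @return A data.frame of class `signal_assignment` with one row per
#'   predicted band: `conformer`, `band`, `nu_calc`, `nu_peak` (matched
#'   experimental position or NA), `matched`, `ambiguous`.
#' @export
assign_signals <- function(exp_spectrum, specs, tolerance = 15,
                           scale_factor = 1, min_prominence = 0.005) {
  stopifnot(inherits(exp_spectrum, "raman_spectrum"))
  if (tolerance <= 0) .stopf("tolerance must be > 0")
  y <- exp_spectrum$intensity
  x <- exp_spectrum$wavenumber
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1L)] > y[1:(n - 2L)] &
                      y[2:(n - 1L)] >= y[3:n], FALSE) &
             y >= min_prominence * max(y)
  peaks <- x[is_peak]
  rows <- do.call(rbind, lapply(specs, function(sp) {
    do.call(rbind, lapply(sp$bands, function(b) {
      nu <- b$nu_calc * scale_factor
      d <- abs(peaks - nu)
      i <- which.min(d)
      hit <- length(i) == 1L && d[i] <= tolerance
      data.frame(conformer = sp$name, band = b$label, nu_calc = b$nu_calc,
                 nu_pred = nu,
                 nu_peak = if (hit) peaks[i] else NA_real_,
                 matched = hit, stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  # two bands matched to one peak -> ambiguous
  dup <- !is.na(rows$nu_peak) & (duplicated(rows$nu_peak) |
                                 duplicated(rows$nu_peak, fromLast = TRUE))
  rows$ambiguous <- dup
  structure(rows, class = c("signal_assignment", "data.frame"))
}

#' Per-signal scale factors from simulated peak heights
#'
#' Second step of the two-step analysis: each conformer is re-simulated with
#' its band centres at the experimental wavenumbers, and for every matched,
#' unambiguous assignment the factor by which the simulated peak height must
#' be multiplied to reach the experimental peak height is computed within a
#' window around the signal. For a mixture, each conformer's factor set
#' estimates its abundance times any residual cross-section error, so the
#' spread over several signals of one conformer measures the reliability of
#' the quantification.
#'
#' @param exp_spectrum A [raman_spectrum] of the measurement.
#' @param assignments A `signal_assignment` from [assign_signals].
#' @param specs List of [conformer_spec] objects (band `nu_exp` fields are
#'   filled from the matched peak positions before simulation).
#' @param window Half-width in cm-1 of the peak search window (default 3).
#' @param overlap_threshold A signal is excluded when the summed simulated
#'   contours of the other conformers, at the signal's peak position, exceed
#'   this fraction of the signal's own simulated height (default 0.25) — the
#'   peak height of such a signal measures the neighbour as much as itself.
#' @param snr_min A signal is excluded when its experimental height is below
#'   `snr_min` times the noise level (default 5); its factor would be noise.
#'   The noise level is estimated robustly from the point-to-point
#'   differences of the experimental spectrum.
#' @param T_rot,sigma,instrument,... Passed to [simulate_conformer].
#' @details The simulated peak position within the window defines where both
#'   heights are read; the experimental height is interpolated at that
#'   position rather than taken as the window maximum, which would be biased
#'   upward by noise for broad signals.
#' @return The assignments data.frame with columns `factor`, `sim_height`,
#'   `exp_height`, `foreign_frac` and `excluded` added (factors are NA for
#'   unmatched, ambiguous or excluded rows).
#' @export
fit_peak_factors <- function(exp_spectrum, assignments, specs, window = 3,
                             overlap_threshold = 0.25, snr_min = 3,
                             T_rot = 30, sigma = 1.0,
                             instrument = instrument_model(), ...) {
  stopifnot(inherits(assignments, "signal_assignment"))
  assignments$factor <- NA_real_
  assignments$sim_height <- NA_real_
  assignments$exp_height <- NA_real_
  assignments$foreign_frac <- NA_real_
  assignments$factor_error <- NA_real_
  assignments$excluded <- FALSE
  assignments$exclude_reason <- NA_character_
  noise_level <- stats::mad(diff(exp_spectrum$intensity)) / sqrt(2)
  conformers <- unique(assignments$conformer)
  sims <- stats::setNames(vector("list", length(conformers)), conformers)
  for (cname in conformers) {
    sp <- specs[[cname]]
    if (is.null(sp)) .stopf("no conformer spec named '%s'", cname)
    rows <- which(assignments$conformer == cname & assignments$matched &
                  !assignments$ambiguous)
    if (!length(rows)) next
    # pin band centres at the observed positions, then re-simulate
    for (r in rows)
      sp$bands[[assignments$band[r]]]$nu_exp <- assignments$nu_peak[r]
    sims[[cname]] <- simulate_conformer(
      sp, T_rot = T_rot, sigma = sigma, use_experimental_centers = TRUE,
      instrument = instrument, bands = assignments$band[rows], ...)
  }
  for (cname in conformers) {
    sim <- sims[[cname]]
    if (is.null(sim)) next
    rows <- which(assignments$conformer == cname & assignments$matched &
                  !assignments$ambiguous)
    others <- Filter(Negate(is.null), sims[setdiff(conformers, cname)])
    for (r in rows) {
      pk <- peak_height(sim, assignments$nu_peak[r], window)
      hs <- pk$height
      if (hs <= 0)
        .stopf("simulated height is zero for band '%s' of '%s'",
               assignments$band[r], cname)
      he <- .spectrum_at(exp_spectrum, pk$position)
      foreign <- if (length(others))
        sum(vapply(others, .spectrum_at, numeric(1), nu = pk$position))
      else 0
      assignments$sim_height[r] <- hs
      assignments$exp_height[r] <- he
      assignments$foreign_frac[r] <- foreign / hs
      if (foreign > overlap_threshold * hs) {
        assignments$excluded[r] <- TRUE
        assignments$exclude_reason[r] <- "overlap"
      } else if (he < snr_min * noise_level) {
        assignments$excluded[r] <- TRUE
        assignments$exclude_reason[r] <- "below noise floor"
      } else {
        assignments$factor[r] <- he / hs
        # measurement error of the factor: noise at the read-out point plus
        # the (worst-case) neighbour-contour contamination
        assignments$factor_error[r] <- (noise_level + foreign) / hs
      }
    }
  }
  assignments
}

# core share computation from per-conformer means and their uncertainties
.shares_from_stats <- function(means, sds, n_signals) {
  if (all(means == 0)) .stopf("all conformer means are zero")
  tot <- sum(means)
  shares <- 100 * means / tot
  # first-order propagation, conformer means independent with sigma = sds:
  # dp_i/dx_j = 100 (delta_ij tot - x_i) / tot^2
  share_sd <- vapply(seq_along(means), function(i) {
    grad <- -means[i] / tot^2 * rep(1, length(means))
    grad[i] <- (tot - means[i]) / tot^2
    100 * sqrt(sum((grad * sds)^2))
  }, numeric(1))
  structure(
    data.frame(conformer = names(means), mean_factor = unname(means),
               factor_sd = unname(sds), n_signals = unname(n_signals),
               share = unname(shares), share_sd = unname(share_sd),
               stringsAsFactors = FALSE),
    class = c("quant_result", "data.frame"))
}

#' @export
print.quant_result <- function(x, ...) {
  cat("Conformer shares (%):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-8s %3.0f +/- %.0f   (factor %.3g +/- %.2g from %d signals)\n",
                x$conformer[i], x$share[i], x$share_sd[i],
                x$mean_factor[i], x$factor_sd[i], x$n_signals[i]))
  invisible(x)
}

#' Conformer shares from per-signal peak-height factors
#'
#' For each conformer, the mean and the population standard deviation
#' (divisor N, not N-1) of its per-signal factors are formed; shares are the
#' means normalised to 100%, with the uncertainty propagated to first order
#' treating the conformer means as independent with sigma equal to the
#' population SD. For two conformers this reduces to
#' `sigma_p1 = 100 sqrt((x2 s1)^2 + (x1 s2)^2) / (x1 + x2)^2`.
#'
#' @param factors Either a named list of numeric factor vectors (one entry
#'   per conformer) or the data.frame returned by [fit_peak_factors] (rows
#'   with NA factors are dropped).
#' @return A `quant_result` data.frame: per conformer `mean_factor`,
#'   `factor_sd` (population SD), `n_signals`, `share` (%), `share_sd`.
#'   When per-signal factor errors are available (data.frame input from
#'   [fit_peak_factors]) an additional column `share_sd_with_errors` adds
#'   them in quadrature to the conformer-mean variance, mirroring the
#'   with/without reporting of the integral method.
#' @export
#' @examples
#' shares_from_factors(list(ttg = c(1.48, 0.7, 1.2), ttt = c(0.9, 0.94)))
shares_from_factors <- function(factors) {
  errors <- NULL
  if (is.data.frame(factors)) {
    keep <- !is.na(factors$factor)
    if (!is.null(factors$factor_error))
      errors <- split(factors$factor_error[keep], factors$conformer[keep])
    factors <- split(factors$factor[keep], factors$conformer[keep])
  }
  if (length(factors) < 2L) .stopf("need at least two conformers")
  if (any(!lengths(factors))) .stopf("every conformer needs >= 1 factor")
  means <- vapply(factors, mean, numeric(1))
  sds <- vapply(factors, function(x)
    sqrt(mean((x - mean(x))^2)), numeric(1))
  out <- .shares_from_stats(means, sds, lengths(factors))
  if (!is.null(errors)) {
    sds2 <- sqrt(sds^2 + vapply(errors, function(e)
      sum(e^2), numeric(1)) / lengths(factors)^2)
    out$share_sd_with_errors <- .shares_from_stats(means, sds2,
                                                   lengths(factors))$share_sd
  }
  out
}

#' Conformer shares from precomputed means and standard deviations
#'
#' Same normalisation and propagation as [shares_from_factors], entered at
#' the level of per-conformer summary statistics.
#'
#' @param means Named vector of per-conformer mean factors.
#' @param sds Matching uncertainties (population SDs).
#' @param n_signals Optional signal counts (for reporting only).
#' @return A `quant_result` data.frame.
#' @export
#' @examples
#' shares_from_stats(c(ttg = 1.09, ttt = 0.92), c(0.39, 0.09))
shares_from_stats <- function(means, sds, n_signals = NA_integer_) {
  if (length(means) < 2L) .stopf("need at least two conformers")
  if (length(sds) != length(means)) .stopf("means and sds must be aligned")
  if (is.null(names(means))) names(means) <- paste0("c", seq_along(means))
  .shares_from_stats(means, sds, rep_len(n_signals, length(means)))
}

#' Conformer shares from integrated intensities and cross sections
#'
#' Integral-method quantification: each signal's integral is divided by its
#' calculated Raman cross section, all quotients are rescaled so the
#' reference signal's quotient is 1, and shares are formed per conformer as
#' in [shares_from_factors]. Two uncertainties are reported: one from the
#' population SD of the per-signal quotients alone, and one that adds the
#' individual per-signal errors (e.g. from [error_budget]) in quadrature to
#' the conformer-mean variance.
#'
#' @param integrals Data.frame with columns `conformer`, `signal`,
#'   `integral`, optionally `error`, and logical `excluded` (optional).
#' @param cross_sections Numeric vector aligned with rows (or column
#'   `cross_section` in `integrals`).
#' @param reference Signal name whose quotient is scaled to 1.
#' @return A `quant_result` with extra column `share_sd_with_errors` when
#'   per-signal errors are given.
#' @export
shares_from_integrals <- function(integrals, cross_sections = NULL,
                                  reference = NULL) {
  df <- integrals
  if (!is.null(cross_sections)) df$cross_section <- cross_sections
  if (is.null(df$cross_section)) .stopf("cross sections are required")
  if (any(df$cross_section <= 0)) .stopf("cross sections must be > 0")
  if (is.null(df$excluded)) df$excluded <- FALSE
  df$X <- df$integral / df$cross_section
  if (!is.null(reference)) {
    i <- match(reference, df$signal)
    if (is.na(i)) .stopf("unknown reference signal '%s'", reference)
    if (df$excluded[i]) .stopf("reference signal '%s' is excluded", reference)
    sc <- df$X[i]
    df$X <- df$X / sc
    if (!is.null(df$error)) df$error <- df$error / df$cross_section / sc
  } else if (!is.null(df$error)) {
    df$error <- df$error / df$cross_section
  }
  keep <- !df$excluded
  grp <- split(df[keep, ], df$conformer[keep])
  means <- vapply(grp, function(g) mean(g$X), numeric(1))
  sds <- vapply(grp, function(g) sqrt(mean((g$X - mean(g$X))^2)), numeric(1))
  out <- .shares_from_stats(means, sds, vapply(grp, nrow, 0L))
  if (!is.null(df$error)) {
    sds2 <- vapply(grp, function(g)
      sqrt(mean((g$X - mean(g$X))^2) + sum(g$error^2) / nrow(g)^2),
      numeric(1))
    out$share_sd_with_errors <-
      .shares_from_stats(means, sds2, vapply(grp, nrow, 0L))$share_sd
  }
  out
}
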