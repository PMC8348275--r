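#' Raman spectrum container
#'
#' A spectrum is a strictly increasing wavenumber axis with one intensity per
#' point and a free-form metadata list (temperatures, folding width,
#' provenance of processing steps). Simulated spectra live on a uniform grid
#' (default spacing 0.1 cm-1) anchored at integer multiples of the spacing so
#' that repeated runs are bit-identical.
#'
#' @param wavenumber Numeric axis in cm-1, strictly increasing.
#' @param intensity Numeric intensities, same length.
#' @param meta Named list of metadata.
#' @return Object of class `raman_spectrum` with fields `wavenumber`,
#'   `intensity`, `meta`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  if (length(wavenumber) != length(intensity))
    .stopf("wavenumber and intensity lengths differ")
  if (any(!is.finite(wavenumber)) || any(!is.finite(intensity)))
    .stopf("spectrum values must be finite")
  if (length(wavenumber) > 1L && any(diff(wavenumber) <= 0))
    .stopf("wavenumber axis must be strictly increasing")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  n <- length(x$wavenumber)
  cat(sprintf("Raman spectrum: %d points, %.4g to %.4g cm-1\n",
              n, x$wavenumber[1L], x$wavenumber[n]))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Integrate a spectrum by the trapezoidal rule
#'
#' @param s A [raman_spectrum].
#' @param bounds Optional `c(lo, hi)` in cm-1; defaults to the full axis.
#' @return The integral (intensity times cm-1).
#' @export
spectrum_integral <- function(s, bounds = NULL) {
  stopifnot(inherits(s, "raman_spectrum"))
  x <- s$wavenumber; y <- s$intensity
  if (!is.null(bounds)) {
    keep <- x >= bounds[1L] & x <= bounds[2L]
    x <- x[keep]; y <- y[keep]
  }
  .trapz(x, y)
}

# interpolate spectrum intensity at arbitrary wavenumbers
.spectrum_at <- function(s, nu) {
  stats::approx(s$wavenumber, s$intensity, xout = nu, rule = 2)$y
}

# record a processing step in the metadata
.add_provenance <- function(s, step) {
  s$meta$provenance <- c(s$meta$provenance, step)
  s
}
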