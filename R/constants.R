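#' Physical constants used throughout the package
#'
#' A fixed table of the conversion factors the package relies on, so that
#' numerical results are bit-stable across platforms:
#' \describe{
#'   \item{hc_over_k}{Second radiation constant hc/kB in cm K (1.4387770).}
#'   \item{mhz_per_cm1}{MHz per cm-1 (29979.2458); rotational constants given
#'     in MHz are divided by this.}
#'   \item{inertia_to_cm1}{Conversion from a moment of inertia in amu A^2 to a
#'     rotational constant in cm-1: X = 16.8576304 / I.}
#'   \item{gas_constant_kj}{Molar gas constant R in kJ/(mol K)
#'     (8.314462618e-3), for Boltzmann factors of energies in kJ/mol.}
#' }
#'
#' @return Named list of constants.
#' @export
#' @examples
#' physical_constants()$hc_over_k
physical_constants <- function() {
  list(
    hc_over_k      = 1.4387770,
    mhz_per_cm1    = 29979.2458,
    inertia_to_cm1 = 16.8576304,
    gas_constant_kj = 8.314462618e-3
  )
}

# internal shortcuts
.const <- physical_constants()

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
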