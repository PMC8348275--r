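#' Rotational constants of a near-symmetric top
#'
#' Bundles the three rotational constants with Ray's asymmetry parameter and
#' the effective symmetric-top constants used by the rigid-rotor energy
#' expression. Chain molecules are usually near-prolate (kappa close to -1);
#' the boundary case kappa = 0 is assigned to the near-prolate branch by
#' convention.
#'
#' @param A,B,C Rotational constants, `A >= B >= C > 0`.
#' @param unit Either `"cm-1"` (default) or `"MHz"`; MHz values are converted
#'   on construction.
#' @return An object of class `rotor_constants` with fields `A`, `B`, `C`
#'   (cm-1), `kappa`, `top_type` (`"near_prolate"` or `"near_oblate"`),
#'   `B_bar` (effective perpendicular constant) and `axis_constant` (the
#'   unique-axis constant: `A` for prolate, `C` for oblate).
#' @export
#' @examples
#' rotor_constants(0.3, 0.12, 0.1)
rotor_constants <- function(A, B, C, unit = c("cm-1", "MHz")) {
  unit <- match.arg(unit)
  for (v in list(A, B, C))
    if (!.is_number(v)) .stopf("rotational constants must be finite scalars")
  if (unit == "MHz") {
    A <- A / .const$mhz_per_cm1
    B <- B / .const$mhz_per_cm1
    C <- C / .const$mhz_per_cm1
  }
  if (!(A >= B && B >= C && C > 0))
    .stopf("rotational constants must satisfy A >= B >= C > 0 (got %g, %g, %g)",
           A, B, C)
  kappa <- ray_kappa(A, B, C)
  top_type <- if (kappa <= 0) "near_prolate" else "near_oblate"
  if (top_type == "near_prolate") {
    B_bar <- (B + C) / 2
    axis_constant <- A
  } else {
    B_bar <- (A + B) / 2
    axis_constant <- C
  }
  structure(
    list(A = A, B = B, C = C, kappa = kappa, top_type = top_type,
         B_bar = B_bar, axis_constant = axis_constant),
    class = "rotor_constants"
  )
}

#' @export
print.rotor_constants <- function(x, ...) {
  cat(sprintf("Rotor constants (cm-1): A = %.6g, B = %.6g, C = %.6g\n",
              x$A, x$B, x$C))
  cat(sprintf("  kappa = %.4f (%s), B_bar = %.6g, axis constant = %.6g\n",
              x$kappa, sub("_", "-", x$top_type), x$B_bar, x$axis_constant))
  invisible(x)
}

#' Ray's asymmetry parameter
#'
#' kappa = (2B - A - C)/(A - C); -1 for a prolate symmetric top (B = C),
#' +1 for an oblate one (A = B).
#'
#' @param A,B,C Rotational constants in consistent units, `A >= B >= C > 0`.
#' @return Dimensionless kappa in \[-1, 1\].
#' @export
#' @examples
#' ray_kappa(10, 2, 1)  # -7/9, near-prolate
ray_kappa <- function(A, B, C) {
  if (!(.is_number(A) && .is_number(B) && .is_number(C)))
    .stopf("A, B, C must be finite scalars")
  if (!(A >= B && B >= C && C > 0))
    .stopf("constants must satisfy A >= B >= C > 0")
  if (A == C)
    .stopf("degenerate input: A == C (spherical top), kappa undefined")
  (2 * B - A - C) / (A - C)
}

#' Rotational constants from an atomic geometry
#'
#' Diagonalises the inertia tensor about the centre of mass and converts the
#' principal moments to rotational constants, X = 16.8576304 / I with I in
#' amu A^2 and X in cm-1. The returned rotation matrix maps input coordinates
#' into the principal frame ordered so that z is the unique rotor axis
#' (a-axis for near-prolate, c-axis for near-oblate tops).
#'
#' @param coordinates Numeric n x 3 matrix of Cartesian coordinates in
#'   Angstrom.
#' @param masses Numeric vector of n atomic masses in amu.
#' @return List with elements `constants` (a [rotor_constants] object) and
#'   `rotation` (3 x 3 matrix; rows are the x, y, z principal axes).
#' @export
constants_from_geometry <- function(coordinates, masses) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) .stopf("coordinates must be an n x 3 matrix")
  n <- nrow(coordinates)
  if (n < 3L) .stopf("need at least 3 atoms")
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0))
    .stopf("masses must be %d positive finite values", n)
  com <- colSums(coordinates * masses) / sum(masses)
  xyz <- sweep(coordinates, 2L, com)
  # inertia tensor
  x <- xyz[, 1L]; y <- xyz[, 2L]; z <- xyz[, 3L]
  I <- matrix(c(
    sum(masses * (y^2 + z^2)), -sum(masses * x * y),     -sum(masses * x * z),
    -sum(masses * x * y),       sum(masses * (x^2 + z^2)), -sum(masses * y * z),
    -sum(masses * x * z),      -sum(masses * y * z),      sum(masses * (x^2 + y^2))
  ), 3L, 3L)
  eig <- eigen(I, symmetric = TRUE)
  mom <- eig$values  # decreasing
  tol <- max(mom) * 1e-10
  if (min(mom) < tol)
    .stopf("linear rotor: one principal moment of inertia is zero")
  # constants sorted A >= B >= C correspond to increasing moments
  consts <- .const$inertia_to_cm1 / mom   # increasing A..? mom decreasing -> consts increasing
  A <- consts[3L]; B <- consts[2L]; C <- consts[1L]
  rc <- rotor_constants(A, B, C)
  # principal axes: eig vectors columns match mom order (decreasing moment)
  # a-axis = smallest moment = column 3; c-axis = largest moment = column 1
  a_axis <- eig$vectors[, 3L]; b_axis <- eig$vectors[, 2L]
  c_axis <- eig$vectors[, 1L]
  if (rc$top_type == "near_prolate") {
    R <- rbind(x = b_axis, y = c_axis, z = a_axis)
  } else {
    R <- rbind(x = a_axis, y = b_axis, z = c_axis)
  }
  if (det(R) < 0) R[1L, ] <- -R[1L, ]  # keep a proper rotation
  list(constants = rc, rotation = R)
}

#' Rigid-rotor energy of a near-symmetric top
#'
#' Prolate: `B_bar J(J+1) + (A - B_bar) K^2`; oblate:
#' `B_bar J(J+1) + (C - B_bar) K^2`. The same constants are used for the
#' lower and upper vibrational state, so pure Q-branch lines are unshifted.
#'
#' @param rc A [rotor_constants] object.
#' @param J,K Rotational quantum numbers, `0 <= K <= J` (vectorised).
#' @return Energy in cm-1.
#' @export
rot_energy <- function(rc, J, K) {
  stopifnot(inherits(rc, "rotor_constants"))
  if (any(J < 0) || any(K < 0) || any(K > J))
    .stopf("quantum numbers must satisfy 0 <= K <= J")
  rc$B_bar * J * (J + 1) + (rc$axis_constant - rc$B_bar) * K^2
}

#' Thermal populations of rotational states
#'
#' Enumerates states J = 0..J_max, K = 0..J with Boltzmann weights
#' `(2 - delta_K0) (2J + 1) exp(-hc E / kB T)`; the factor 2 for K > 0
#' accounts for the +/-K degeneracy (K is enumerated non-negative). Nuclear
#' spin statistical weights are taken as unity (appropriate for C1/Cs
#' molecules). J_max is the smallest J whose cumulative population reaches
#' `coverage` of the full partition function, capped at `J_cap` (with a
#' warning if the cap binds).
#'
#' @param rc A [rotor_constants] object.
#' @param T_rot Rotational temperature in K (> 0).
#' @param coverage Population fraction to retain (default 0.9999).
#' @param J_cap Hard cap on J (default 200).
#' @return A data.frame with columns `J`, `K`, `energy` (cm-1), `weight`
#'   (unnormalised) and `p` (weight / partition function), with attributes
#'   `partition_function` and `coverage` (fraction actually retained).
#' @export
rot_populations <- function(rc, T_rot, coverage = 0.9999, J_cap = 200L) {
  stopifnot(inherits(rc, "rotor_constants"))
  if (!.is_number(T_rot) || T_rot <= 0) .stopf("T_rot must be > 0")
  if (!.is_number(coverage) || coverage <= 0 || coverage > 1)
    .stopf("coverage must be in (0, 1]")
  beta <- .const$hc_over_k / T_rot
  per_J <- function(J) {
    K <- 0:J
    w <- (2 - (K == 0L)) * (2 * J + 1) * exp(-beta * rot_energy(rc, rep(J, J + 1L), K))
    sum(w)
  }
  # full partition sum: extend until the per-J contribution is negligible
  Z <- 0
  contrib <- numeric(0)
  J <- 0L
  hard <- max(J_cap * 5L, 2000L)
  repeat {
    cJ <- per_J(J)
    contrib <- c(contrib, cJ)
    Z <- Z + cJ
    if (J >= 5L && cJ < Z * 1e-13) break
    if (J >= hard) break
    J <- J + 1L
  }
  cum <- cumsum(contrib) / Z
  J_max <- which(cum >= coverage)[1L] - 1L
  if (is.na(J_max)) J_max <- length(contrib) - 1L
  if (J_max > J_cap) {
    .warnf("J cap %d binds (coverage %.6f would need J_max = %d)",
           J_cap, coverage, J_max)
    J_max <- as.integer(J_cap)
  }
  Js <- rep.int(0:J_max, 0:J_max + 1L)
  Ks <- unlist(lapply(0:J_max, function(J) 0:J), use.names = FALSE)
  E <- rot_energy(rc, Js, Ks)
  w <- (2 - (Ks == 0L)) * (2 * Js + 1) * exp(-beta * E)
  out <- data.frame(J = Js, K = Ks, energy = E, weight = w, p = w / Z)
  attr(out, "partition_function") <- Z
  attr(out, "coverage") <- sum(w) / Z
  out
}
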