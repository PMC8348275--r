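#' Transition-polarisability tensor
#'
#' Symmetric 3 x 3 transition-polarisability tensor stored by its six
#' independent components, expressed in the principal inertia frame with z
#' along the unique rotor axis. Units are arbitrary but must be consistent
#' across bands of one analysis (relative intensities only).
#'
#' @param xx,yy,zz,xy,xz,yz Tensor components.
#' @return Object of class `polarizability_tensor`.
#' @export
#' @examples
#' polarizability_tensor(1, 1, 1)           # isotropic
#' polarizability_tensor(0, 0, 0, xz = 1)   # fully depolarised
polarizability_tensor <- function(xx = 0, yy = 0, zz = 0,
                                  xy = 0, xz = 0, yz = 0) {
  v <- c(xx = xx, yy = yy, zz = zz, xy = xy, xz = xz, yz = yz)
  if (any(!is.finite(v))) .stopf("tensor components must be finite")
  structure(as.list(v), class = "polarizability_tensor")
}

.tensor_matrix <- function(t) {
  matrix(c(t$xx, t$xy, t$xz,
           t$xy, t$yy, t$yz,
           t$xz, t$yz, t$zz), 3L, 3L)
}

.tensor_from_matrix <- function(M) {
  polarizability_tensor(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
}

#' Placzek invariants of a transition-polarisability tensor
#'
#' Computes the isotropic invariant `a' = (a_xx + a_yy + a_zz)/3`, the
#' anisotropic invariant
#' `gamma'^2 = 1/2 [(a_xx - a_yy)^2 + (a_yy - a_zz)^2 + (a_zz - a_xx)^2]
#'  + 3 (a_xy^2 + a_xz^2 + a_yz^2)`,
#' the depolarisation ratio `3 gamma'^2 / (45 a'^2 + 4 gamma'^2)` and the
#' spherical-tensor partition of the anisotropy into the Delta-K = 0, +/-1,
#' +/-2 scattering channels (see [channel_partition]).
#'
#' @param t A [polarizability_tensor], or an object with precomputed fields.
#' @return Object of class `placzek_invariants` with fields `a_prime`,
#'   `gamma2`, `gamma2_dk0`, `gamma2_dk1`, `gamma2_dk2`, `depol_ratio`.
#' @export
#' @examples
#' invariants(polarizability_tensor(2, 0, 0))
invariants <- function(t) {
  stopifnot(inherits(t, "polarizability_tensor"))
  a_prime <- (t$xx + t$yy + t$zz) / 3
  gamma2 <- 0.5 * ((t$xx - t$yy)^2 + (t$yy - t$zz)^2 + (t$zz - t$xx)^2) +
    3 * (t$xy^2 + t$xz^2 + t$yz^2)
  ch <- channel_partition(t)
  placzek_invariants(a_prime, gamma2,
                     gamma2_dk0 = ch[[1L]], gamma2_dk1 = ch[[2L]],
                     gamma2_dk2 = ch[[3L]])
}

#' Construct Placzek invariants directly
#'
#' For conformer-spec files that carry precomputed invariants instead of the
#' tensor. When the channel split is not given, the anisotropy is assigned
#' entirely to the Delta-K = 0 channel (axially symmetric assumption) with a
#' warning.
#'
#' @param a_prime Isotropic invariant.
#' @param gamma2 Anisotropic invariant (>= 0).
#' @param gamma2_dk0,gamma2_dk1,gamma2_dk2 Channel weights summing to
#'   `gamma2`.
#' @return Object of class `placzek_invariants`.
#' @export
placzek_invariants <- function(a_prime, gamma2,
                               gamma2_dk0 = NULL, gamma2_dk1 = NULL,
                               gamma2_dk2 = NULL) {
  if (!.is_number(a_prime) || !.is_number(gamma2) || gamma2 < -1e-12)
    .stopf("invalid invariants")
  gamma2 <- max(gamma2, 0)
  if (is.null(gamma2_dk0)) {
    if (gamma2 > 0)
      .warnf("no channel split given; assigning all anisotropy to Delta-K = 0")
    gamma2_dk0 <- gamma2; gamma2_dk1 <- 0; gamma2_dk2 <- 0
  }
  s <- gamma2_dk0 + gamma2_dk1 + gamma2_dk2
  if (abs(s - gamma2) > 1e-8 * max(gamma2, 1))
    .stopf("channel weights (sum %g) do not sum to gamma2 (%g)", s, gamma2)
  denom <- 45 * a_prime^2 + 4 * gamma2
  depol <- if (denom == 0) 0 else 3 * gamma2 / denom
  structure(list(a_prime = a_prime, gamma2 = gamma2,
                 gamma2_dk0 = gamma2_dk0, gamma2_dk1 = gamma2_dk1,
                 gamma2_dk2 = gamma2_dk2, depol_ratio = depol),
            class = "placzek_invariants")
}

#' @export
print.placzek_invariants <- function(x, ...) {
  cat(sprintf("Placzek invariants: a' = %.6g, gamma'^2 = %.6g (rho = %.4f)\n",
              x$a_prime, x$gamma2, x$depol_ratio))
  cat(sprintf("  Delta-K channels: %.6g (0), %.6g (+/-1), %.6g (+/-2)\n",
              x$gamma2_dk0, x$gamma2_dk1, x$gamma2_dk2))
  invisible(x)
}

#' Partition the anisotropy into Delta-K scattering channels
#'
#' For a tensor in the principal frame with z along the unique rotor axis,
#' forms the rank-2 spherical components
#' `a_20 = (2 a_zz - a_xx - a_yy)/sqrt(6)`,
#' `a_2+-1 = -+(a_xz +- i a_yz)`, `a_2+-2 = (a_xx - a_yy +- 2 i a_xy)/2`,
#' and returns the channel weights `(3/2)|a_20|^2`,
#' `(3/2)(|a_2+1|^2 + |a_2-1|^2)`, `(3/2)(|a_2+2|^2 + |a_2-2|^2)`.
#' They sum to `gamma'^2`, which keeps the total band intensity invariant
#' when all Delta-K transitions of an asymmetric (C1) vibration are
#' simulated.
#'
#' @param t A [polarizability_tensor] in the rotor principal frame.
#' @return Named numeric vector `c(dk0 = , dk1 = , dk2 = )`.
#' @export
channel_partition <- function(t) {
  stopifnot(inherits(t, "polarizability_tensor"))
  a20_sq <- (2 * t$zz - t$xx - t$yy)^2 / 6
  a21_sq <- 2 * (t$xz^2 + t$yz^2)            # |a_2+1|^2 + |a_2-1|^2
  a22_sq <- 2 * ((t$xx - t$yy)^2 / 4 + t$xy^2)
  c(dk0 = 1.5 * a20_sq, dk1 = 1.5 * a21_sq, dk2 = 1.5 * a22_sq)
}

#' Rotate a polarisability tensor
#'
#' Returns `R a R^T`. Tensors exported from quantum-chemistry programs arrive
#' in an arbitrary frame; rotate them into the rotor principal frame (e.g.
#' with the rotation returned by [constants_from_geometry]) before the
#' channel partition, which is frame-dependent. The invariants `a'` and
#' `gamma'^2` are rotation-invariant.
#'
#' @param t A [polarizability_tensor].
#' @param R Orthogonal 3 x 3 rotation matrix.
#' @return Rotated [polarizability_tensor].
#' @export
rotate_tensor <- function(t, R) {
  stopifnot(inherits(t, "polarizability_tensor"))
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8)
    .stopf("R must be orthogonal within 1e-8")
  .tensor_from_matrix(R %*% .tensor_matrix(t) %*% t(R))
}
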