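# Wigner 3j symbols via the Racah formula, evaluated with log-factorials.
# Only integer angular momenta with one rank fixed at 2 are needed (Raman
# transitions of a symmetric top); the alternating sum then has at most five
# terms and double precision is ample up to the J ~ few hundred used in
# contours. The hot loop is vectorised over (J, K) so that a full line list
# costs 25 vector evaluations instead of one call per line.

.lfact <- function(n) lgamma(n + 1)

# vectorised 3j for integer arguments (recycled to a common length)
.wigner3j_vec <- function(j1, j2, j3, m1, m2, m3) {
  n <- max(lengths(list(j1, j2, j3, m1, m2, m3)))
  j1 <- rep_len(j1, n); j2 <- rep_len(j2, n); j3 <- rep_len(j3, n)
  m1 <- rep_len(m1, n); m2 <- rep_len(m2, n); m3 <- rep_len(m3, n)
  out <- numeric(n)
  ok <- (m1 + m2 + m3 == 0) &
    j3 >= abs(j1 - j2) & j3 <= j1 + j2 & j3 >= 0 &
    abs(m1) <= j1 & abs(m2) <= j2 & abs(m3) <= j3
  if (!any(ok)) return(out)
  j1 <- j1[ok]; j2 <- j2[ok]; j3 <- j3[ok]
  m1 <- m1[ok]; m2 <- m2[ok]; m3 <- m3[ok]
  tmin <- pmax(0, j2 - j3 - m1, j1 - j3 + m2)
  tmax <- pmin(j1 + j2 - j3, j1 - m1, j2 + m2)
  lg <- 0.5 * (.lfact(j1 + j2 - j3) + .lfact(j1 - j2 + j3) +
               .lfact(-j1 + j2 + j3) - .lfact(j1 + j2 + j3 + 1) +
               .lfact(j1 + m1) + .lfact(j1 - m1) +
               .lfact(j2 + m2) + .lfact(j2 - m2) +
               .lfact(j3 + m3) + .lfact(j3 - m3))
  acc <- numeric(length(j1))
  for (k in 0:(max(tmax - tmin))) {
    tt <- tmin + k
    live <- tt <= tmax
    if (!any(live)) break
    i <- which(live)
    t_i <- tt[i]
    term <- (-1)^t_i * exp(lg[i] - .lfact(t_i) -
                           .lfact(j3[i] - j2[i] + t_i + m1[i]) -
                           .lfact(j3[i] - j1[i] + t_i - m2[i]) -
                           .lfact(j1[i] + j2[i] - j3[i] - t_i) -
                           .lfact(j1[i] - t_i - m1[i]) -
                           .lfact(j2[i] - t_i + m2[i]))
    acc[i] <- acc[i] + term
  }
  res <- (-1)^(j1 - j2 - m3) * acc
  res[tmax < tmin] <- 0
  out[ok] <- res
  out
}

.wigner3j <- function(j1, j2, j3, m1, m2, m3) {
  .wigner3j_vec(j1, j2, j3, m1, m2, m3)[1L]
}

#' Placzek-Teller line-strength factor
#'
#' Rotational line strength of a rank-2 (anisotropic) Raman transition of a
#' symmetric top, computed as the squared Clebsch-Gordan coefficient
#' `<J K; 2 dK | J' K + dK>^2 = (2J' + 1) [3j(J 2 J'; K dK -(K + dK))]^2`
#' with `J' = J + dJ`. One expression covers all `dJ, dK` in -2..2 and obeys
#' the completeness sum rule `sum_J' b = 1` for every `(J, K, dK)`.
#' Triangle-forbidden combinations return 0.
#'
#' @param J,K Lower-state quantum numbers, `0 <= |K| <= J` (vectorised).
#' @param dJ,dK Branch, each in -2..2 (vectorised).
#' @return Dimensionless factor in \[0, 1\].
#' @export
#' @examples
#' placzek_teller_b(1, 0, 0, 0)  # 0.4
placzek_teller_b <- function(J, K, dJ, dK) {
  n <- max(length(J), length(K), length(dJ), length(dK))
  J <- rep_len(J, n); K <- rep_len(K, n)
  dJ <- rep_len(dJ, n); dK <- rep_len(dK, n)
  if (any(J < 0) || any(abs(K) > J))
    .stopf("need 0 <= |K| <= J")
  if (any(abs(dJ) > 2) || any(abs(dK) > 2))
    .stopf("dJ and dK must lie in -2..2")
  Jp <- J + dJ
  Kp <- K + dK
  w <- .wigner3j_vec(J, 2, Jp, K, dK, -Kp)
  b <- (2 * Jp + 1) * w^2
  b[Jp < 0 | abs(Kp) > Jp] <- 0
  b
}
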