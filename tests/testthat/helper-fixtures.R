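# Shared fixtures: small toy rotors, tensors and bands used across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_rotor <- function() rotor_constants(1.0, 0.6, 0.4)

toy_tensor <- function() polarizability_tensor(0.3, -1.2, 0.5,
                                               xy = 0.7, xz = -0.2, yz = 0.9)

polarised_band <- function(nu = 500, label = "pol")
  vib_band(label, nu, tensor = polarizability_tensor(1, 1, 1))

toy_band <- function(nu = 500, label = "toy")
  vib_band(label, nu, tensor = toy_tensor())

# independent closed-form Placzek-Teller factors for the Delta-K = 0
# branches (classical symmetric-top line-strength expressions), used as an
# oracle for the Clebsch-Gordan route
pt_closed_q <- function(J, K)
  (J * (J + 1) - 3 * K^2)^2 / (J * (J + 1) * (2 * J - 1) * (2 * J + 3))
pt_closed_r <- function(J, K)
  3 * K^2 * (J + 1 + K) * (J + 1 - K) / (J * (J + 1) * (J + 2) * (2 * J + 1))
pt_closed_s <- function(J, K)
  3 * (J + 1 + K) * (J + 2 + K) * (J + 1 - K) * (J + 2 - K) /
    (2 * (J + 1) * (J + 2) * (2 * J + 1) * (2 * J + 3))

# a reproducible random rotation matrix (QR of a seeded Gaussian matrix)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# two small synthetic conformers + their mixture, shared by quantify tests
mixture_fixture <- function(seed = 1, shares = c(0.57, 0.43),
                            noise_sd = 0.01, n_bands = 5) {
  sA <- synthetic_molecule(seed * 2 + 1, kappa_target = -0.92,
                           n_bands = n_bands, name = "alpha")
  sB <- synthetic_molecule(seed * 2 + 2, kappa_target = -0.88,
                           n_bands = n_bands, name = "beta")
  specs <- list(alpha = sA, beta = sB)
  mix <- synthetic_mixture_spectrum(list(sA, sB), shares,
                                    noise_sd = noise_sd, seed = seed)
  list(specs = specs, mix = mix, shares = shares)
}
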