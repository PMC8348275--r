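---
title: "Rovibrational contour simulation and conformer quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rovibrational contour simulation and conformer quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jetraman)
```

## Scope and model

`jetraman` determines the relative abundances of coexisting conformers of a
flexible molecule from a linear Raman spectrum recorded in a supersonic jet
expansion. Its inputs are, per conformer, the rotational constants, the
harmonic band positions and the transition-polarisability tensors of the
relevant fundamentals — quantities exported from any standard Raman
frequency calculation — plus the measured spectrum. Its outputs are
per-signal scale factors, normalised conformer shares with propagated
uncertainties, and Boltzmann/jet-relaxation reference populations.

The physical model is deliberately minimal and its assumptions should be
kept in mind:

* **Rigid near-symmetric top.** Rotational levels are
  $E(J,K) = \bar B J(J+1) + (A-\bar B)K^2$ for near-prolate tops
  ($\bar B = (B+C)/2$), with the *same* constants in both vibrational
  states. Consequences: Q-branch lines with $\Delta J = \Delta K = 0$ are
  exactly unshifted (sharp Q$_0$ peaks at the band origin), and there is no
  centrifugal distortion, Coriolis coupling or vibrational dependence of the
  constants. The approximation degrades with asymmetry; it is usable for
  $\kappa \lesssim -0.8$ at jet resolution, and chain molecules rarely
  deviate more. The $\kappa = 0$ boundary is assigned to near-prolate by
  convention.
* **Raman selection rules with a channel-partitioned anisotropy.** A true
  symmetric top selects a single $\Delta K$ channel by symmetry. A C$_1$
  molecule has no such selectivity; summing all channels naively would
  overcount the intensity. The anisotropic invariant $\gamma'^2$ is
  therefore split via the rank-2 spherical components of the tensor
  ($\tfrac32|\alpha_{20}|^2$, $\tfrac32\sum_\pm|\alpha_{2\pm1}|^2$,
  $\tfrac32\sum_\pm|\alpha_{2\pm2}|^2$) into parts feeding exclusively
  $\Delta K = 0, \pm1, \pm2$. The three parts sum to $\gamma'^2$ exactly,
  so the total band intensity is preserved — the package's central
  invariant, tested to 1e−9. This spherical-tensor construction is the
  mathematically canonical partition "based on the tensor components"; it
  is frame-dependent, so tensors must be rotated into the principal inertia
  frame (z = unique axis) first, which `constants_from_geometry()` +
  `rotate_tensor()` automate. For near-oblate tops the axis mapping
  (z = c) is applied before partitioning.
* **Line strengths as squared Clebsch–Gordan coefficients.**
  $b_{J,K}^{\Delta J,\Delta K} = \langle J\,K;2\,\Delta K\,|\,J'\,K{+}\Delta
  K\rangle^2$, one expression for all 25 branches, verifiable through the
  completeness sum rule $\sum_{J'} b = 1$ and equal to the classical
  closed-form Placzek–Teller factors where those are tabulated. The
  alternating Racah sum has at most five terms at rank 2, so double
  precision is ample to $J$ of a few hundred.
* **Thermal effects.** Rotational populations are Boltzmann at an effective
  `T_rot` with $(2-\delta_{K0})(2J{+}1)$ degeneracy ($\pm K$ folded into
  $K \ge 0$); nuclear-spin weights are unity (correct for C$_1$/C$_s$
  molecules). Vibrational hot bands are *not* simulated as separate lines:
  they are assumed to coincide with the cold band, entering as the scalar
  visibility factor $I_T(\tilde\nu, T) = (1 - e^{-hc\tilde\nu/k_BT})^{-1}$.
  Because the vibrational temperature in a jet is mode-dependent and poorly
  known, calculated intensities use the mean of $I_T$ at 20 K and 180 K and
  half the spread enters the error budget; the window is generous on
  purpose and the term is negligible above roughly 600 cm$^{-1}$.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `T_rot` | 30 K | effective rotational temperature of jet spectra; 20–40 K all give plausible contours, 30 K is the standard compromise |
| `sigma` | 1.0 cm⁻¹ | Gaussian folding width, interpreted as the **standard deviation** (not FWHM); 0.5 shows unresolved sub-structure, 1.5 over-smooths |
| `grid_spacing` | 0.1 cm⁻¹ | output grid, anchored at integer multiples so runs are bit-identical |
| `coverage` | 0.9999 | retained fraction of the rotational partition function; a population-coverage cutoff (capped at `J_cap = 200`) was preferred over a fixed maximum J because it adapts to rotor size and temperature |
| geometry coefficients | 45 / 4.1133, 0.0423 / 3.1142 | finite-aperture detection; treated as configurable data (their solid-angle derivation is out of scope); `geometry = "ideal"` restores 45/4 + 0/3 |
| `transmittance_factor` | 1 | monochromator polarisation bias; applied as one scalar per analysis with a ±0.05 uncertainty routed into the error budget, not sampled |
| assignment `tolerance` | 15 cm⁻¹ | harmonic-to-experimental matching window, sized to typical anharmonic shifts |

Line positions are rounded to 0.01 cm⁻¹ and co-added before folding, and
Gaussians are truncated at ±5σ — the standard speed-ups for line lists in
the million range; the folded integral then matches the summed line
intensity to better than 1e−4.

## The quantification procedure

The two-step peak-height analysis follows the field's practice: first
assign signals by simulating with harmonic centres, then re-simulate at the
experimental centres and fit per-signal factors. Three numerical choices
deviate from a naive implementation and matter in practice:

1. **Heights are read at the simulated peak position**, interpolating the
   experimental spectrum there. Taking the maximum over a window of noisy
   points instead biases every height upward by roughly the expected
   maximum of the window's noise, inflating weak signals by 10% and more.
2. **Signals are excluded** when the summed simulated contours of the
   *other* conformers exceed 25% of the signal's own simulated height
   (`overlap_threshold`), or when the experimental height is below 3 times
   the robust noise level (`snr_min`; noise estimated as
   `mad(diff(intensity))/sqrt(2)`). Both mirror the practice of quantifying
   only sufficiently separated signals; without them single contaminated or
   noise-floor signals can dominate a conformer mean.
3. **Two uncertainties are reported.** The population standard deviation
   (divisor N, exactly as the field prints it) spreads the per-signal
   factors; `share_sd_with_errors` additionally adds each signal's
   measurement error (noise plus worst-case foreign contamination, divided
   by the simulated height) in quadrature to the conformer-mean variance.
   The second is the honest uncertainty when a conformer has few usable
   signals — with one signal the population SD is identically zero.

Shares are means normalised to 100%, with first-order propagation treating
conformer means as independent; for two conformers
$\sigma_{p_1} = 100\sqrt{(\bar x_2 s_1)^2 + (\bar x_1 s_2)^2}/(\bar x_1+\bar x_2)^2$.
Rounding to integer percent happens only at print time.

The integral route divides Monte-Carlo integrals by computed cross
sections. Each of the 10,000 draws adds i.i.d. Gaussian noise per grid
point, draws both integration bounds uniformly in user ranges, subtracts
the chord through the noisy spectrum at the drawn bounds, and integrates by
the trapezoidal rule. Noise is added before the bounds are drawn (the order
is statistically immaterial at these levels). Note a subtlety: with fixed
bounds the spread is dominated by the chord's noisy endpoints
($\sigma \approx$ noise · width/$\sqrt2$), not by the accumulated
point noise; the tests check the spread against a direct simulation of
that estimator rather than a closed form. Correlated noise and non-linear
baselines are out of scope.

## Population models

Boltzmann weights $g_i e^{-\Delta E_i/RT}$ use degeneracy 2 for chiral
enantiomeric pairs (indistinguishable in linear Raman) and accept energies
relative to any reference. Jet relaxation is modelled by pooling families
whose internal barriers are surmountable; the bundled energy table for the
four methyl butanoate conformers supports the standard barrier rule of
thumb (< 5 kJ/mol relaxes, > 10 kJ/mol freezes, in between partial).
Gibbs-energy inputs are consumed as data; computing thermal corrections
from frequencies is out of scope, as is kinetic (master-equation)
modelling of the expansion.

## What the synthetic generator emulates — and what it does not

`synthetic_molecule()` draws ester-sized near-prolate rotors
(C ≈ 0.05–0.09 cm⁻¹, A/C ≈ 3–5, κ set exactly), 100–1800 cm⁻¹ band
positions, and random symmetric tensors of which a fraction
(`polarisation_mix`, default 0.7) is polarised (isotropic-dominant, sharp
Q$_0$) and the rest depolarised (traceless). `synthetic_mixture_spectrum()`
sums share-weighted contours and adds linear drift and i.i.d. Gaussian
noise (default 1% of the maximum — the reproducibility floor of good jet
spectra). Oblate generation is intentionally unimplemented (chain molecules
are prolate).

End-to-end tests on these mixtures demonstrate that the pipeline recovers
known shares within its reported uncertainty (98% of 50 seeded 57:43 runs).
They do **not** demonstrate robustness to what real spectra add: anharmonic
shifts between predicted and true band centres beyond the assignment
tolerance, hot-band and combination structure, Fermi resonances and
tunnelling splittings, cross-section errors of the underlying electronic
structure (typically ~20% harmonic error), aggregation signals, or
wavenumber-calibration drift. The synthetic truth shares exact cross
sections with the fitting model; on real data the cross-section error is
the accuracy floor.

## Numerical and degenerate-input conventions

Spherical tops (A = C) make κ undefined and error out; linear geometries
error as linear rotors. Zero detected activity of a band is an error rather
than a silent zero. The partition function is summed until a per-J
contribution falls below 1e−13 of the running total, making the reported
coverage exact to ~1e−6 against a brute-force sum. Ambiguous assignments
(two bands on one experimental peak) are flags, never exceptions, and are
simply omitted from factor fitting. All randomness (generators, Monte-Carlo
integration) is seeded explicitly, and generator calls restore the caller's
RNG state.

## Problem sizes used in the shipped tests

Unit and property tests run on toy rotors (constants of order
0.1–1 cm⁻¹) with populations at 10–120 K, sum rules to J = 50, 1000-tensor
channel checks, and 50 end-to-end mixture recoveries with 5 bands per
conformer — sizes chosen so the full suite completes in a few minutes on
one core while still exercising every branch of the line-list machinery at
the temperatures and widths used for real jet spectra.
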