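#' Conformer energetics record
#'
#' Relative energies (any consistent reference; only differences matter) and
#' the statistical degeneracy of one conformer. Chiral enantiomeric pairs
#' carry g = 2 — Raman spectroscopy cannot distinguish enantiomers, so one
#' member represents the pair with a twofold statistical advantage.
#'
#' @param name Conformer label.
#' @param degeneracy Integer g >= 1.
#' @param energies Named numeric vector in kJ/mol (e.g. `c(E0 = 3.2,
#'   Eel = 2.2, G300 = 2.5)`).
#' @param family Optional pooling label (e.g. the surviving torsional
#'   family after jet relaxation).
#' @return Object of class `conformer_energetics`.
#' @export
conformer_energetics <- function(name, degeneracy = 1L, energies,
                                 family = NULL) {
  if (!.is_number(degeneracy) || degeneracy < 1)
    .stopf("degeneracy must be >= 1")
  if (!length(energies) || is.null(names(energies)))
    .stopf("at least one named energy is required")
  structure(list(name = as.character(name),
                 degeneracy = as.integer(degeneracy),
                 energies = energies,
                 family = family),
            class = "conformer_energetics")
}

#' Boltzmann populations of conformers
#'
#' `p_i = g_i exp(-E_i / RT) / sum_j g_j exp(-E_j / RT)` with R =
#' 8.314462618e-3 kJ/(mol K). Energies are shifted to their minimum before
#' exponentiation, so any common reference is acceptable.
#'
#' @param confs List of [conformer_energetics] (or a
#'   list of [conformer_spec] objects carrying energetics).
#' @param energy_key Which named energy to use (e.g. `"E0"`).
#' @param T Temperature in K (> 0).
#' @return Named vector of fractions summing to 1.
#' @export
#' @examples
#' confs <- list(
#'   conformer_energetics("ttt", 1, c(E0 = 0)),
#'   conformer_energetics("ttg", 2, c(E0 = 0)))
#' boltzmann_populations(confs, "E0", 300)
boltzmann_populations <- function(confs, energy_key, T) {
  if (!.is_number(T) || T <= 0) .stopf("T must be > 0")
  confs <- lapply(confs, function(cf)
    if (inherits(cf, "conformer_spec")) cf$energetics else cf)
  stopifnot(all(vapply(confs, inherits, TRUE, "conformer_energetics")))
  E <- vapply(confs, function(cf) {
    if (!energy_key %in% names(cf$energies) ||
        is.na(cf$energies[[energy_key]]))
      .stopf("conformer '%s' has no energy '%s'", cf$name, energy_key)
    cf$energies[[energy_key]]
  }, numeric(1))
  g <- vapply(confs, `[[`, 0L, "degeneracy")
  w <- g * exp(-(E - min(E)) / (.const$gas_constant_kj * T))
  p <- w / sum(w)
  names(p) <- vapply(confs, `[[`, "", "name")
  p
}

#' Pool conformer populations into relaxation families
#'
#' In a supersonic expansion, conformers separated by low barriers collapse
#' into their family's most stable member; the observable abundances are the
#' pooled family sums. Pooling preserves the total.
#'
#' @param populations Named fractions (e.g. from [boltzmann_populations]).
#' @param family_map Named character vector mapping every conformer to a
#'   family label.
#' @return Named vector of pooled fractions.
#' @export
#' @examples
#' pool_families(c(ttt = 0.24, tgt = 0.13, ttg = 0.48, tgg = 0.15),
#'               c(ttt = "ttt", tgt = "ttt", ttg = "ttg", tgg = "ttg"))
pool_families <- function(populations, family_map) {
  missing_map <- setdiff(names(populations), names(family_map))
  if (length(missing_map))
    .stopf("unmapped conformer(s): %s", paste(missing_map, collapse = ", "))
  fam <- unname(family_map[names(populations)])
  agg <- tapply(populations, fam, sum)
  # preserve first-appearance order of families, drop the tapply dim
  out <- as.numeric(agg[unique(fam)])
  names(out) <- unique(fam)
  out
}

#' Classify an interconversion barrier for jet relaxation
#'
#' Rule of thumb for collisional cooling in a supersonic expansion: barriers
#' below ~5 kJ/mol are easily overcome (the conformer relaxes away), barriers
#' above ~10 kJ/mol are largely insurmountable (the conformer freezes), and
#' the range in between gives partial relaxation.
#'
#' @param barrier Barrier height in kJ/mol (>= 0, vectorised).
#' @param easy,hard Thresholds in kJ/mol (defaults 5 and 10).
#' @return Character vector: `"relaxes"`, `"partial"` or `"frozen"`.
#' @export
#' @examples
#' classify_relaxation(c(3.1, 6.8, 10.4))
classify_relaxation <- function(barrier, easy = 5, hard = 10) {
  if (any(barrier < 0)) .stopf("barrier must be >= 0")
  ifelse(barrier < easy, "relaxes",
         ifelse(barrier > hard, "frozen", "partial"))
}
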