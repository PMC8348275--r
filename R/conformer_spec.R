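#' Vibrational band of a conformer
#'
#' One fundamental with its harmonic (and optionally experimental) band
#' origin and either the transition-polarisability tensor (in the rotor
#' principal frame) or precomputed Placzek invariants.
#'
#' @param label Band name (e.g. `"nu14"`).
#' @param nu_calc Harmonic wavenumber in cm-1 (> 0).
#' @param nu_exp Optional experimental wavenumber in cm-1.
#' @param tensor Optional [polarizability_tensor].
#' @param invariants Optional [placzek_invariants]; computed from `tensor`
#'   when absent.
#' @param symmetry Optional symmetry label.
#' @param cross_section Optional precomputed relative Raman cross section.
#' @return Object of class `vib_band`.
#' @export
vib_band <- function(label, nu_calc, nu_exp = NULL, tensor = NULL,
                     invariants = NULL, symmetry = NULL,
                     cross_section = NULL) {
  if (!.is_number(nu_calc) || nu_calc <= 0) .stopf("nu_calc must be > 0")
  if (!is.null(nu_exp) && (!.is_number(nu_exp) || nu_exp <= 0))
    .stopf("nu_exp must be > 0 when present")
  if (is.null(invariants)) {
    if (is.null(tensor))
      .stopf("band '%s' needs a tensor or precomputed invariants", label)
    invariants <- invariants(tensor)
  }
  stopifnot(inherits(invariants, "placzek_invariants"))
  structure(list(label = as.character(label), nu_calc = nu_calc,
                 nu_exp = nu_exp, symmetry = symmetry, tensor = tensor,
                 invariants = invariants, cross_section = cross_section),
            class = "vib_band")
}

#' Conformer specification
#'
#' A named conformer with its rotational constants, vibrational bands and
#' (optionally) energetics for population modelling. This is the unit the
#' contour simulation and the quantification pipeline operate on; the values
#' are normally exported from a quantum-chemistry frequency calculation.
#'
#' @param name Conformer label (e.g. `"ttt"`).
#' @param rotor A [rotor_constants] object.
#' @param bands List of [vib_band] objects (>= 1).
#' @param energetics Optional [conformer_energetics].
#' @param provenance Optional free-text origin note.
#' @return Object of class `conformer_spec`.
#' @export
conformer_spec <- function(name, rotor, bands, energetics = NULL,
                           provenance = NULL) {
  stopifnot(inherits(rotor, "rotor_constants"))
  if (!length(bands)) .stopf("conformer '%s' needs at least one band", name)
  if (!all(vapply(bands, inherits, TRUE, "vib_band")))
    .stopf("bands must be vib_band objects")
  names(bands) <- vapply(bands, `[[`, "", "label")
  structure(list(name = as.character(name), rotor = rotor, bands = bands,
                 energetics = energetics, provenance = provenance),
            class = "conformer_spec")
}

#' @export
print.conformer_spec <- function(x, ...) {
  cat(sprintf("Conformer '%s': %d bands, kappa = %.3f\n",
              x$name, length(x$bands), x$rotor$kappa))
  invisible(x)
}

#' Read conformer specifications from a YAML file
#'
#' The file holds one conformer or a list of conformers. Each entry carries
#' `name`, a `rotor` block (`A`, `B`, `C` and an optional `unit` key,
#' `"cm-1"` or `"MHz"`), a `bands` list (each with `label`, `nu_calc`,
#' optional `nu_exp`, `cross_section`, and either a `tensor` block with keys
#' `xx yy zz xy xz yz` plus optional `frame: rotated` handled upstream, or an
#' `invariants` block with `a_prime`, `gamma2` and optional channel weights),
#' and an optional `energetics` block (`degeneracy`, `family`, `energies`
#' with named keys in kJ/mol).
#'
#' @param path Path to the YAML file.
#' @return A named list of [conformer_spec] objects.
#' @export
read_conformer_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$name)) doc <- list(doc)
  if (!is.null(doc$conformers)) doc <- doc$conformers
  specs <- lapply(doc, .parse_conformer_entry)
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

.parse_conformer_entry <- function(e) {
  if (is.null(e$name) || is.null(e$rotor) || is.null(e$bands))
    .stopf("conformer entry needs 'name', 'rotor' and 'bands'")
  r <- e$rotor
  rotor <- rotor_constants(r$A, r$B, r$C,
                           unit = if (is.null(r$unit)) "cm-1" else r$unit)
  bands <- lapply(e$bands, function(b) {
    tensor <- NULL; inv <- NULL
    if (!is.null(b$tensor)) {
      tt <- b$tensor
      g <- function(k) if (is.null(tt[[k]])) 0 else tt[[k]]
      tensor <- polarizability_tensor(g("xx"), g("yy"), g("zz"),
                                      g("xy"), g("xz"), g("yz"))
    } else if (!is.null(b$invariants)) {
      iv <- b$invariants
      inv <- placzek_invariants(iv$a_prime, iv$gamma2,
                                iv$gamma2_dk0, iv$gamma2_dk1, iv$gamma2_dk2)
    }
    vib_band(b$label, b$nu_calc, nu_exp = b$nu_exp, tensor = tensor,
             invariants = inv, symmetry = b$symmetry,
             cross_section = b$cross_section)
  })
  energetics <- NULL
  if (!is.null(e$energetics)) {
    en <- e$energetics
    energetics <- conformer_energetics(
      name = e$name,
      degeneracy = if (is.null(en$degeneracy)) 1L else en$degeneracy,
      energies = unlist(en$energies),
      family = en$family
    )
  }
  conformer_spec(e$name, rotor, bands, energetics = energetics,
                 provenance = e$provenance)
}

#' Write conformer specifications to a YAML file
#'
#' Inverse of [read_conformer_spec]; bands are written with their tensor when
#' available, otherwise with their invariants (including the channel split).
#'
#' @param specs A [conformer_spec] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conformer_spec <- function(specs, path) {
  if (inherits(specs, "conformer_spec")) specs <- list(specs)
  entries <- lapply(specs, function(s) {
    bands <- lapply(s$bands, function(b) {
      out <- list(label = b$label, nu_calc = b$nu_calc)
      if (!is.null(b$nu_exp)) out$nu_exp <- b$nu_exp
      if (!is.null(b$symmetry)) out$symmetry <- b$symmetry
      if (!is.null(b$cross_section)) out$cross_section <- b$cross_section
      if (!is.null(b$tensor)) {
        out$tensor <- b$tensor[c("xx", "yy", "zz", "xy", "xz", "yz")]
      } else {
        iv <- b$invariants
        out$invariants <- list(a_prime = iv$a_prime, gamma2 = iv$gamma2,
                               gamma2_dk0 = iv$gamma2_dk0,
                               gamma2_dk1 = iv$gamma2_dk1,
                               gamma2_dk2 = iv$gamma2_dk2)
      }
      out
    })
    entry <- list(name = s$name,
                  rotor = list(A = s$rotor$A, B = s$rotor$B, C = s$rotor$C,
                               unit = "cm-1"),
                  bands = unname(bands))
    if (!is.null(s$energetics)) {
      en <- s$energetics
      entry$energetics <- list(degeneracy = en$degeneracy,
                               family = en$family,
                               energies = as.list(en$energies))
    }
    if (!is.null(s$provenance)) entry$provenance <- s$provenance
    entry
  })
  yaml::write_yaml(list(conformers = unname(entries)), path, precision = 12)
  invisible(path)
}
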