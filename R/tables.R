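#' Bundled reference data tables
#'
#' The printed benchmark data the package's arithmetic is validated against,
#' as structured data frames:
#' \describe{
#'   \item{methanoate_intensities}{Experimental jet Raman intensities of the
#'     methyl methanoate fundamentals (normalised so that the strong
#'     fundamentals nu5 + nu8/7/6 + nu9 + nu14 sum to 100) with their
#'     uncertainties, next to harmonic double-harmonic predictions at five
#'     levels of theory (B3LYP and PBE0 with def2-QZVPP, def2-QZVPPD,
#'     aug-cc-pVQZ). Combined columns (nu17/16, nu12/11, nu8/7/6) are single
#'     rows.}
#'   \item{methanoate_reference}{The five strong scattering regions of
#'     methyl methanoate: early gas-phase literature values (488 nm
#'     excitation), this setup's gas-phase and jet values (jet intensities
#'     extrapolated from the 20-180 K convention to 298 K), and
#'     298 K-adjusted B3LYP/def2-QZVPP predictions; each block normalised to
#'     100 over the five regions.}
#'   \item{butanoate_energies}{Relative energies (kJ/mol) of the methyl
#'     butanoate minima and interconversion transition states at
#'     CCSD(F12*)(T*)//B3LYP, with and without ZPE, with and without the
#'     CCSD(T) correction, plus two literature columns (B3LYP/6-31G(d) dEel;
#'     B2PLYP-D3BJ/aug-cc-pVTZ dE0).}
#'   \item{butanoate_ratios}{ttt:ttg conformational ratios of methyl
#'     butanoate in supersonic expansions from Raman integrals, Raman peak
#'     heights, microwave spectroscopy, and Boltzmann models on several
#'     energy surfaces.}
#' }
#'
#' @return Named list of data frames, each with a `source` attribute
#'   describing its content.
#' @export
reference_tables <- function() {
  t1 <- data.frame(
    mode = c("nu18", "nu17_16", "nu15", "nu14", "nu13", "nu12_11",
             "nu10", "nu9", "nu8_7_6", "nu5"),
    nu_exp = c(132, 312, 769, 928, 1024, 1167, 1210, 1370, 1438, 1755),
    I_exp = c(1.9, 27.3, 5.1, 47.2, 2.9, 4.3, 3.0, 10.2, 17.1, 25.5),
    I_err = c(1.2, 2.9, 0.9, 2.3, 0.8, 1.0, 0.8, 1.1, 1.5, 1.5),
    B3LYP_def2QZVPP  = c(6.7, 43.7, 8.6, 46.4, 3.9, 8.4, 3.9, 12.2, 23.1, 18.4),
    B3LYP_def2QZVPPD = c(5.7, 42.1, 6.3, 47.9, 3.8, 6.4, 3.8, 9.6, 18.5, 24.0),
    B3LYP_augccpVQZ  = c(5.1, 42.5, 6.3, 47.9, 3.8, 6.4, 3.9, 9.6, 18.5, 24.0),
    PBE0_def2QZVPP   = c(7.3, 44.6, 8.4, 43.2, 4.0, 7.0, 5.1, 12.7, 25.2, 18.9),
    PBE0_augccpVQZ   = c(5.6, 43.7, 6.3, 44.9, 3.9, 4.7, 5.7, 10.4, 20.5, 24.2),
    stringsAsFactors = FALSE)
  attr(t1, "source") <- paste(
    "Methyl methanoate fundamentals: experimental jet Raman intensities",
    "(strong-set normalisation nu5+nu8/7/6+nu9+nu14 = 100) vs harmonic",
    "predictions, thermally adjusted to the 20/180 K-average convention")

  t2 <- data.frame(
    mode = c("nu17_16", "nu14", "nu10", "nu9", "nu5"),
    nu_lit = c(313, 919, 1207, 1368, 1751),
    I_lit = c(13, 38, 6, 10, 34),
    I_lit_err = c(3, 3, 3, 3, 3),
    nu_gas = c(311, 926, 1209, 1371, 1755),
    I_gas = c(32.6, 38.4, 3.1, 8.7, 17.1),
    I_gas_err = c(4.6, 4.3, 2.6, 4.5, 2.3),
    nu_jet = c(312, 928, 1210, 1370, 1755),
    I_jet = c(28, 39.7, 2.5, 8.5, 21.2),
    I_jet_err = c(4.5, 1.8, 0.6, 0.8, 1.2),
    nu_calc = c(301, 928, 1229, 1399, 1790),
    I_calc = c(40, 34.6, 2.9, 9, 13.5),
    stringsAsFactors = FALSE)
  attr(t2, "source") <- paste(
    "Five strong scattering regions of methyl methanoate: 488 nm gas-phase",
    "literature, this setup's gas phase and 298 K-extrapolated jet values,",
    "and 298 K-adjusted B3LYP/def2-QZVPP; each block normalised to 100")

  t4 <- data.frame(
    species = c("tgt", "tgt-ttt", "ttt", "ttt-ttg", "ttg", "ttg-tgg",
                "tgg", "tgg-tgt"),
    is_ts = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    dEel       = c(2.2, 2.3, 0, 10.5, -0.6, 5.9, 1.8, 15.5),
    dEel_noT   = c(1.8, 1.9, 0, 9.9, -0.6, 5.4, 1.8, 14.7),
    dE0        = c(3.2, 3.1, 0, 10.4, 0.0, 6.8, 2.9, 16.3),
    dE0_noT    = c(2.8, 2.7, 0, 9.8, 0.1, 6.4, 2.9, 15.5),
    dEel_B3LYP631Gd = c(3.1, NA, 0, 11.3, 0.2, NA, 3.9, NA),
    dE0_B2PLYP = c(2.6, 4.4, 0.1, 11.1, 0, 7.2, 2.5, NA),
    stringsAsFactors = FALSE)
  attr(t4, "source") <- paste(
    "Methyl butanoate minima and transition states, relative energies in",
    "kJ/mol at CCSD(F12*)(T*)//B3LYP (dE0 = ZPE-corrected; _noT = without",
    "the CCSD(T) correction) plus literature B3LYP/6-31G(d) and",
    "B2PLYP-D3BJ/aug-cc-pVTZ columns")

  t5 <- data.frame(
    method = c("Raman integrals", "Raman peak heights",
               "CCSD(T)//B3LYP dG(300 K)", "CCSD(T)//B3LYP dG(200 K)",
               "CCSD(T)//B3LYP dG(100 K)", "CCSD(T)//B3LYP dE0(300 K)",
               "Microwave", "B2PLYP dG(300 K)", "B2PLYP dE0(300 K)",
               "MP2 dG(300 K)", "MP2 dE0(300 K)"),
    ttt = c(43, 46, 51, 47, 40, 37, 41, 51, 38, 34, 30),
    ttt_err = c(8, 9, NA, NA, NA, NA, 4, NA, NA, NA, NA),
    ttg = c(57, 54, 49, 53, 60, 63, 59, 49, 62, 66, 70),
    ttg_err = c(8, 9, NA, NA, NA, NA, 6, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  attr(t5, "source") <- paste(
    "ttt:ttg conformational ratio of methyl butanoate in supersonic",
    "expansions, by experimental method and Boltzmann model (populations",
    "pooled after full relaxation of the second torsional angle)")

  list(methanoate_intensities = t1, methanoate_reference = t2,
       butanoate_energies = t4, butanoate_ratios = t5)
}

#' Methyl butanoate conformer energetics from the bundled energy table
#'
#' Convenience constructor: the four minima as [conformer_energetics]
#' records, with the twofold degeneracy of the chiral (gauche-containing)
#' conformers and the `ttt`/`ttg` relaxation families (the second torsional
#' angle relaxes fully; tgt pools into ttt, tgg into ttg).
#'
#' @param column Energy column of the bundled table (default `"dE0"`;
#'   `"dE0_B2PLYP"` selects the literature B2PLYP values).
#' @return List of four [conformer_energetics] objects.
#' @export
butanoate_conformers <- function(column = "dE0") {
  t4 <- reference_tables()$butanoate_energies
  minima <- t4[!t4$is_ts, ]
  fam <- c(ttt = "ttt", tgt = "ttt", ttg = "ttg", tgg = "ttg")
  lapply(seq_len(nrow(minima)), function(i) {
    nm <- minima$species[i]
    conformer_energetics(
      name = nm,
      degeneracy = if (grepl("g", nm)) 2L else 1L,
      energies = stats::setNames(minima[[column]][i], column),
      family = fam[[nm]])
  })
}
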