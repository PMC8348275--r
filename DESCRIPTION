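Package: jetraman
Title: Rovibrational Raman Band Contours and Conformer Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies coexisting conformers of flexible chain molecules
    from linear Raman spectra of supersonic jet expansions. Simulates
    rigid-rotor rovibrational band contours of near-symmetric top molecules
    from computed transition polarisabilities (Placzek invariants with a
    spherical-tensor partition of the anisotropy into Delta-K channels),
    applies detection-geometry, transmittance and vibrational-temperature
    corrections with an additive error budget, integrates signals with
    Monte-Carlo uncertainty estimation, converts per-signal scale factors
    into conformer abundances, and models equilibrium and jet-relaxed
    conformer populations from quantum-chemical energy tables.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
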