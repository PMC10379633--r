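Package: tpasos
Title: Sum-over-States Two-Photon Absorption Cross-Sections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes two-photon absorption (TPA) tensors, few-state-model
    strengths, and rotationally averaged cross-sections in Goeppert-Mayer
    units from tables of electronic-state energies and permanent/transition
    dipole moment vectors. Implements the sum-over-states formalism with
    N-level truncations and the two-level closed form for charge-transfer
    chromophores such as the GFP chromophore anion, Lorentzian and Gaussian
    lineshape conversion to peak cross-sections, internal-field and
    induced-dipole diagnostics, and ensemble statistics of cross-sections
    over protein conformers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
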