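Package: quenchr
Title: Stern-Volmer Analysis of Tryptophan Fluorescence Quenching by
    Macromolecular Crowding Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the mechanism of tryptophan fluorescence
    quenching by synthetic crowding agents. Processes emission spectra
    (blank correction, barycentric mean emission wavelength and its
    crowder-induced shift), fits the linear, combined static/dynamic and
    sphere-of-action Stern-Volmer models to titration data, classifies the
    quenching mechanism from concentration series measured at two
    temperatures, evaluates thermodynamic cycles that decompose aqueous
    binding free energies into gas-phase and solvation contributions, and
    generates synthetic spectra and titration series for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
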