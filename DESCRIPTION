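Package: vusfold
Title: Prioritizing Variants of Uncertain Significance with Folding
    Stability and CADD Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reclassifies missense variants of uncertain significance (VUS)
    as likely pathogenic from predicted folding free energy differences
    (ddG_Fold) and CADD deleteriousness scores. Provides the thermodynamic
    derivation of a destabilization threshold from a target fold change in
    the folded:unfolded equilibrium, PPV-targeted calibration of a CADD
    cutoff on labeled variants, per-residue structural feature extraction
    (AlphaFold pLDDT confidence and Shrake-Rupley relative solvent
    accessibility) from predicted structures, VUS prioritization with
    per-gene summaries, extrapolation of the number of pathogenic variants
    hidden among VUSs, patient-level diagnostic logic for autosomal
    recessive and dominant cases, and a synthetic generator emulating the
    statistical structure of the Deafness Variation Database so the whole
    pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
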