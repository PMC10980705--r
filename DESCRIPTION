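Package: hairpinreg
Title: Beta-Hairpin Registry Analysis of Disordered Peptide Ensembles and
    Amyloid Nucleation Propensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies beta-hairpin content in conformational ensembles of
    intrinsically disordered peptides and relates it to amyloid fibril
    nucleation kinetics. Detects backbone hydrogen bonds, classifies per-frame
    hairpins into even and odd registry classes, computes random-coil and
    beta-content fractions with a hairpin/coil orthogonality rule, and scores
    nucleation propensity with the cross-beta hairpin amyloid trimer (xHAT)
    score S = f_odd * f_even^2. Includes repeat-domain (tau k18) local-hairpin
    and inter-hexapeptide pairing statistics, solvent-accessible surface area
    differentials, Thioflavin-T aggregation curve fitting (sigmoidal half-time),
    rank correlation of structural metrics with aggregation speed, and
    ground-truth synthetic conformer and plate generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
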