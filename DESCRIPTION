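Package: senospec
Title: Label-Free Quantification of Mesenchymal Stromal Cell Senescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying replicative senescence in human
    mesenchymal stromal cell (hMSC) cultures from autofluorescence
    microspectroscopy and flow cytometry, benchmarked against
    senescence-associated beta-galactosidase staining. Implements training
    of a four-fluorophore spectral component library (free and bound NADH,
    FAD, lipopigment) from reference solutions and senescent-cell residuals,
    non-negative least-squares unmixing of per-cell emission spectra,
    forward-scatter and C12FDG flow summaries with debris gating, population
    doubling bookkeeping with early/senescent passage classification, and a
    benchmarking layer of per-donor fold differences, one-tailed Welch tests
    and Spearman correlations against the beta-galactosidase standard. A
    synthetic cohort generator with recorded ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
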