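Package: dualsip
Title: Dual-Isotope Quantitative DNA Stable-Isotope Probing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative DNA stable-isotope probing (qSIP) for paired
    13C + 15N labelling experiments. Takes fraction-resolved OTU read
    counts from CsCl buoyant-density gradients together with per-fraction
    qPCR totals, estimates each taxon's weighted average buoyant density
    in unlabelled and labelled incubations, converts the density shift
    into a molecular weight excess (MWE) relative to the theoretical
    maximum under full 13C + 15N substitution, and calls taxa active at a
    configurable MWE cutoff. Includes OTU filtering rules for
    fraction-resolved amplicon data, per-taxon activity summaries, and a
    forward simulator of paired gradient experiments with known ground
    truth for validating the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
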