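Package: glycoSIRM
Title: Microscale Glycogen Quantification and Isotope Tracing by UHR-FTMS
    and 1D 1H-NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying glycogen content and stable-isotope
    (13C/2H) enrichment in stable isotope resolved metabolomics (SIRM)
    studies at microgram scale. Implements multi-tracer glucose
    isotopologue enumeration with exact masses and natural-abundance
    isotopic fine structure, a calibrated kinetic model of microwave acid
    hydrolysis of glycogen, synthetic direct-infusion ultra-high-resolution
    FTMS and anomeric-region 1H-NMR spectrum generation, peak picking and
    isotopologue assignment with natural-abundance correction and
    spiked-standard absolute quantification, 13C-satellite fractional
    enrichment and DSS-referenced NMR quantification, and the full
    pre/post-hydrolysis glycogen computation chain (net glucose, glucose
    equivalents, hydrolysis-efficiency correction, per-protein
    normalization, isotopologue splits and NMR-visible fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
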