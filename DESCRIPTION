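Package: aqscreen
Title: LC-MS/MS Screening and Annotation of 2-Alkyl-4(1H)-Quinolone Homologous Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for annotating 2-alkyl-4(1H)-quinolone (pseudane-type)
    secondary metabolites in LC-MS/MS feature tables. Provides exact
    monoisotopic mass arithmetic with electron-corrected [M+H]+ adducts,
    brute-force CHNOS molecular-formula enumeration within a ppm tolerance
    with ring-plus-double-bond filtering, readers and writers for feature
    tables (CSV/TSV), MS/MS spectra (MGF) and NIST-style spectral libraries
    (MSP), precursor-filtered cosine spectral-library search,
    diagnostic-fragment analysis across spectrum sets, homologous-series
    detection by CH2 mass spacing with a retention-time trend model,
    retention-time-based isomer resolution, a ground-truthed synthetic
    LC-MS/MS data generator, and an end-to-end annotation pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
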