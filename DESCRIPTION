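Package: stoolddpcr
Title: Absolute Quantification of Faecal Host DNA by Droplet Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for absolute quantification of host DNA in
    stool by droplet digital PCR (ddPCR): droplet threshold calling, Poisson
    copy-number estimation with confidence intervals, no-template-control
    background and dilution adjustment, normalisation to stool mass, spike-in
    recovery estimation, specificity (signal-to-noise) ratios, standard-curve
    validation statistics (linearity, percent yield, percent CV),
    genome-equivalent and cell-count conversions, and in silico PCR product
    enumeration on arbitrary FASTA templates. Includes a synthetic droplet
    data generator emulating Poisson partition loading, two-cluster
    fluorescence amplitudes with rain, spike-in and dilution-series designs,
    and longitudinal stool collection studies, so the full pipeline is
    testable end to end without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
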