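Package: cueflux
Title: Transcriptomic Markers of Fungal Growth, Respiration and
    Carbon-Use Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives gene-expression markers of fungal growth, respiration
    and carbon-use efficiency (CUE) from liquid-culture experiments.
    Converts biomass and closed-loop CO2 measurements into relative growth
    rate, respiration, metabolic quotient and CUE; normalizes RNA-seq
    counts to RPKM and aggregates genes by Enzyme Commission (EC) number;
    screens all enzyme classes for correlation with the measured fluxes;
    fits power-law (log-log) marker regressions; and combines paired
    growth and respiration markers into a transcript-based CUE index.
    Ships a synthetic-study generator with known ground truth so that
    every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
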