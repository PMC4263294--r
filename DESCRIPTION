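Package: oxomap
Title: Genome-Wide Mapping of 8-Oxoguanine from DIP-Chip Log-Ratio Signals
Version: 0.1.0
Authors@R:
    person("oxomap", "maintainers", email = "oxomap@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide oxidative DNA damage
    (8-oxoguanine) profiles measured by DNA immunoprecipitation on tiling
    microarrays. Provides per-probe log2(IP/input) signal assembly,
    sliding-window smoothing of chromosome-scale profiles, non-overlapping
    genomic binning with gene-density association, expression-group
    comparisons of genic damage levels, a chain-file based interval
    remapping engine (liftOver semantics with a minimum mapped-fraction
    criterion), lamina-associated domain association statistics including a
    permutation z-score test, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
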