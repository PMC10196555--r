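Package: btrefuge
Title: Refuge-Based Management of Insect Resistance to Bt Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling and monitoring the evolution of insect
    resistance to transgenic Bt crops under host-plant refuge strategies,
    motivated by Cry1Ac resistance of the cotton bollworm (Helicoverpa
    armigera) in northern China. Provides a deterministic one-locus,
    two-allele simulator of resistance-allele trajectories with
    habitat-weighted genotype fitness (dominance, recessive fitness cost,
    incomplete resistance), an effective-refuge calculator that weights
    non-Bt host crops by their relative pest production, a pooled-amplicon
    allele-frequency pipeline for dual-tagged paired-end reads with the
    1/(2n) rare-sequence filter and bootstrap annual means, the monitoring
    statistics used in resistance surveillance (continuity-corrected Wilson
    intervals, genotype tallies, diagnostic-dose bioassay summaries,
    log-scale regression and correlation, pooled t-tests), and synthetic
    data generators with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
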