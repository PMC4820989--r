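Package: chipperscan
Title: Simulation and Analysis of Dense Restriction-Digest CRISPR Tiling Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing dense CRISPR
    tiling screens built from type III restriction-digest (EcoP15I) sgRNA
    libraries. Includes exhaustive protospacer/PAM enumeration on input DNA
    regions, an in-silico "molecular chipper" digest that converts random
    fragment ends into G+19 targeting domains, a synthetic FACS-bin screen
    generator emitting barcoded amplicon reads, read clipping,
    demultiplexing and mapping back to input regions, floored log2
    enrichment scoring with multi-replicate hit calling, a sliding-window
    cluster statistic that multiplies per-sgRNA upper-tail normal
    probabilities, and library complexity QC (neighbour-distance
    distributions, saturation subsampling, input-capacity extrapolation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
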