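Package: mmeco
Title: Meta-Metabolome Ecology for High-Resolution Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ecological null-model analysis of metabolite assemblages detected by
    ultrahigh-resolution mass spectrometry (FTICR-MS). Builds three relational
    dendrograms over peaks -- from molecular properties (MCD), from putative
    biochemical-transformation networks (TD), and from their combination (TWCD) --
    and applies phylogeny-style alpha- and beta-diversity metrics (Faith-type
    dendrogram diversity, MPD, MNTD, unweighted UniFrac) together with ecological
    null models (NRI, NTI, beta-NTI, Raup-Crick) to infer whether metabolite
    assemblages are structured by stochastic or deterministic assembly processes.
    Includes a synthetic CHONSP formula and assemblage generator for validation
    under controlled assembly regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
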