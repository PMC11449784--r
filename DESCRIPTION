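Package: gmnet
Title: Integrative Gene-Metabolite Network Reconstruction from
    Longitudinal Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating longitudinal transcriptomic and
    targeted-metabolomic measurements into gene-metabolite networks.
    Implements targeted-metabolomics preprocessing (group-wise 80
    percent detection rule, LOD-bounded random imputation, class-mean
    imputation, batch centering within time points), consecutive
    time-point differential tables with Benjamini-Hochberg adjustment,
    reconstruction of an integrative network from a stoichiometric
    reaction model enriched with protein-protein interactions,
    pathway-based subnetwork extraction scored by differential content
    and degree-distribution distance, and pie-glyph SVG rendering of
    per-node fold-change vectors across five consecutive comparisons.
    A synthetic-data module generates toy reaction models, pathway
    maps, interaction tables and two-condition longitudinal omics
    matrices with planted effects for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
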