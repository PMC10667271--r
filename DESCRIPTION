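Package: desiccnet
Title: Desiccation-Tolerance Physiology, Differential Expression and
    Thresholded Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for analysing modified desiccation
    tolerance in resurrection grasses. Implements relative-water-content
    scoring and Evans Blue cell-death indexing of gradual-versus-rapid
    drying experiments; per-tissue, per-dehydration-state differential
    expression against a hydrated reference (Welch tests on log2
    abundances, Benjamini-Hochberg adjustment, the |FC| >= 2 and
    adjusted p < 0.05 enrichment rule); coefficient-of-variation gene
    ranking and thresholded Pearson co-expression networks (|r| > 0.964)
    with per-state up/down node overlays and cross-state network
    comparison; metabolite fold-change, heatmap-ordering and PCA
    analyses; and one-way ANOVA of phytohormone trajectories with
    Tukey-based compact letter displays. A seeded synthetic-data
    generator emulating the two-tissue, six-state, triplicate design
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
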