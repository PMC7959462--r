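Package: ptmburden
Title: Burden and Selection Analysis of PTM-Disrupting Somatic Mutations in the Tumor Matrisome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pan-cancer analysis of somatic mutations that
    disrupt annotated post-translational modification (PTM) sites in
    extracellular-matrix (matrisome) proteins. Provides readers for
    protein-coordinate mutation tables, PTM site catalogs, matrisome gene
    annotations, domain/region intervals and interaction edge lists; calls
    PTM-disrupting mutations by residue-footprint overlap; computes local and
    global PTM-site mutation burdens, random-gene-set controls, per-gene
    dN/dS ratios at PTM and non-PTM positions and their ratio r_dNdS,
    cross-cohort hotspot recurrence, domain-specific mutation ratios,
    functional-region and sequence-motif context, and patient-level
    co-occurrence of PTM-disrupting mutations across protein interaction
    networks. Includes a synthetic cohort generator that emulates the
    statistical structure of the inputs (category-dependent PTM frequencies,
    per-site selection, transition/transversion mixes, injected hotspots)
    so every stage of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
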