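Package: domevol
Title: Domain-Based Gene-Family Profiling and Ancestral Toolkit
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for tracing the evolution of
    domain-defined gene families (such as the ubiquitin, SUMO and Ufm1
    signaling systems) across a species phylogeny.  Reads per-species
    protein domain annotation tables, assigns proteins to families via
    core Pfam domains with motif-based refinements, builds gene-count
    and presence/absence matrices, reconstructs per-branch gains and
    losses by Fitch and Dollo parsimony and by an asymmetric two-state
    Mk likelihood model, reconstructs ancestral accessory-domain
    co-occurrence networks at named tree nodes, performs lineage
    enrichment tests, scaled PCA of toolkit profiles and the
    matched-pairs test of symmetry, screens reciprocal similarity-search
    results for horizontal transfer candidates, and simulates synthetic
    datasets with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
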