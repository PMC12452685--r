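Package: goxprofiler
Title: Evolutionary Profiling of Glyphosate Oxidoreductase Homologs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for evolutionary profiling of bacterial glyphosate
    oxidoreductase (Gox) and related FAD-dependent oxidoreductases from
    annotated protein FASTA files. Provides header-metadata parsing with
    protein-name (ontology) grouping and taxonomy aggregation,
    reference-anchored identity filtering, guide-tree progressive multiple
    sequence alignment, UPGMA phylogenies with monophyletic cluster cutting
    and supergrouping, physicochemical (AMAS-style, 0-11) per-column
    conservation scoring, PROSITE-style consensus motif extraction and
    matching with variable-length wildcards, proline-rich motif detection,
    domain-architecture classification from region annotation tables, and a
    seeded synthetic protein-family simulator with planted motifs for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
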