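Package: aligneval
Title: Evaluation of Biomedical Ontology Alignments with Consensus References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for evaluating ontology matching systems on biomedical
    class hierarchies (e.g. phenotype and disease ontologies). Builds
    consensus ("silver standard") reference alignments by voting across
    system families, computes standard and semantic precision, recall and
    F-measure where correctness is decided by subsumption entailment over
    the merged aligned ontology, detects incoherence via disjointness
    clashes, extracts per-system unique mappings with positive and negative
    contribution statistics from sampled manual assessment, and simulates
    an interactive domain-expert oracle with a configurable error rate.
    Includes readers and writers for the RDF Alignment XML format, a TSV
    mapping dialect, OBO flat files and subsumption edge lists, plus a
    synthetic fixture generator producing toy ontology pairs and simulated
    system alignments with controlled precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
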