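Package: ontokit
Title: Zero-Shot Ontology and Knowledge-Graph Extraction from Scientific
    Text with DAG-Aware Taxonomy Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a five-stage, zero-shot pipeline that turns a corpus
    of plain-text scientific papers into a rooted isA taxonomy and a
    knowledge graph: vocabulary extraction with anti-hallucination
    verification, long-context category generation with self-consistent
    refinement, iterative cycle-guarded taxonomy construction over a
    directed acyclic graph, leaf instantiation, and vocabulary-filtered
    relation-triple extraction. The text-generation engine is pluggable:
    scripted replay and planted-world simulated backends allow the whole
    pipeline to run and be tested offline. A metric suite generalising
    hierarchical precision, recall, F1 and accuracy to DAGs, together with
    lowest-common-ancestor preservation and ancestor error counts, compares
    reconstructed taxonomies against a ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
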