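Package: shortloop
Title: Short Loop Network Motif Profiling and Commonality Detection in
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Profiles short loop network motifs (cyclic interactions of
    three or four proteins) in undirected protein-protein interaction
    networks, detects 'short loop commonality' pairs of non-interacting
    proteins that share the same triangle partner pairs, measures
    functional consensus of loops from ontology annotations, builds
    random-subnetwork null distributions with z-scores, computes mutation
    hotspot statistics (normalized nsSNV frequency, hotspot detection and
    the mutation hotspot ratio density with a uniform-placement null), and
    classifies gene pairs from CRISPR dependency screens as mutually
    exclusive or co-occurring. Includes seedable synthetic-data generators
    with recorded ground truth and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
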