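Package: hitclust
Title: Cluster and Annotate the Hits of a Protein Similarity Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes the hit list of a protein BLAST search by greedy
    two-pass clustering of the hit sequences. Cluster membership is governed
    by a length-difference rule and an identity threshold taken as the larger
    of a user cutoff and the length-dependent twilight-zone (Rost) curve,
    which acts as a non-overridable floor. Clusters are annotated with their
    joint taxonomy, domain architectures, PDB entries and length range, and a
    saved session can be re-clustered instantly at new identity cutoffs
    without repeating the search. Includes a synthetic protein-family
    generator with planted cluster structure for fully offline testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
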