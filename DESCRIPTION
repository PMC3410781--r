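Package: seqnr
Title: Non-Redundant Sequence Annotation Store Keyed by MD5 Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and queries a non-redundant, multi-source annotated
    sequence database in which every distinct residue string is stored
    exactly once under the 32-character hexadecimal MD5 fingerprint of its
    normalized sequence. Source bundles (FASTA plus tab-separated
    annotation and functional-hierarchy tables) are converted to the
    MD5-keyed internal form and merged so that adding a new annotation
    namespace appends metadata only, never sequence data. Provides bulk
    identifier resolution and namespace-to-namespace translation through
    shared sequence identity, mapping of BLAST/BLAT 12-column tabular
    similarity results onto functions, organisms and functional-hierarchy
    categories without recomputing searches, per-source uniqueness
    statistics, reproducible tabular dumps, a synthetic source-bundle
    generator for testing, and a command-line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Biostrings,
    data.table,
    openssl,
    stats,
    yaml,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
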