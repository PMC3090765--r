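Package: mapscaffold
Title: Map-Guided Genome Scaffolding with Pseudo Mate-Pair Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts non-sequence map data (physical, linkage and synteny
    marker positions) into pseudo mate-pair link constraints, extracts
    inter-contig links from paired-end SAM alignments, and combines both
    under a priority scheme in a greedy graph scaffolder. Sequence-based
    links override map-based links on conflict. Includes a Bambus-style
    mates/contig file exporter, assembly summary statistics (total span,
    scaffold N50, percent of contigs scaffolded), and a seeded simulator
    that generates a complete synthetic fixture (genome, contigs, marker
    map, PSL placements, paired-end SAM, truth layout) for end-to-end
    testing without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
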