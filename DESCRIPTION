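Package: wsrep
Title: Tandem Repeats in Weighted (Probabilistic) DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects all tandem repeats in weighted sequences, i.e. strings
    in which each position carries a probability distribution over the
    alphabet (position probability matrices, IUPAC-ambiguous DNA). Given a
    cumulative weight threshold 1/z, the package computes every repetition
    u^e (e >= 2, primitive root u) whose copies are valid factors at the
    threshold, in O(n log n)-class time: positions are filtered and coloured
    black/grey/white, extended factors are generated around branching
    (black) positions, maximal repetitions of each factor are found by a
    partitioning-equivalent runs algorithm, longest-valid-factor arrays cut
    them to the threshold, and overlapping valid squares are composed into
    maximal repetitions. Brute-force oracles, a probability-matrix TSV
    format, IUPAC FASTA ingestion and a synthetic-data generator with
    planted repeats are included.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
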