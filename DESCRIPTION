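Package: lorasm
Title: Progressive Error Correction and Two-Stage Assembly of Noisy Long Reads
Version: 0.1.0
Author: lorasm developers
Maintainer: lorasm developers <lorasm@example.org>
Description: Correction and de novo assembly of noisy long (nanopore-style)
    reads.  Implements adaptive per-template selection of supporting reads
    (global plus individual overlapping-error-rate thresholds), a two-pass
    progressive consensus correction that first fixes low-error-rate
    subsequences and then rescues high-error-rate subsequences with a
    sensitive realigner, coverage-based trimming, string-graph contig
    assembly with transitive reduction and best-overlap pruning, and a
    final contig-bridging stage that re-uses raw reads to join contigs.
    Ships a nanopore-style read simulator with full ground truth so the
    whole pipeline can be exercised and evaluated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
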