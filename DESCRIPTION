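Package: gapfillr
Title: Flank-Anchored Gap Filling for Long-Read Scaffolds
Version: 0.1.0
Authors@R:
    person("gapfillr", "developers", email = "gapfillr@example.org",
           role = c("aut", "cre"))
Description: Fills N-gaps in draft genome scaffolds using only the long
    reads that the scaffolder associated with each scaffold. Both flanks
    of a gap are anchored by strict local alignments against a candidate
    read; a gap is filled only when both anchors are unique, on the same
    strand and in order, each read is consumed at most once, and subreads
    from the same SMRT-cell well (ZMW) are prevented from filling
    disparate gaps. Includes assembly/gap statistics (N50, gap counts),
    a long-read fixture simulator with known ground truth, and a
    command-line interface with fill, stats and simulate subcommands.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    parallel,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
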