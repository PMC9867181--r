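Package: sscoi
Title: Species-Specific COI Primer Design and In-Silico PCR
Version: 0.1.0
Authors@R:
    person("sscoi", "developers", email = "sscoi@example.org", role = c("aut", "cre"))
Description: A toolkit for building species-diagnostic PCR assays from DNA
    barcode (COI) sequence panels. Computes uncorrected p-distance matrices,
    neighbor-joining trees and bootstrap support from taxon-labeled
    alignments; scans alignments for regions conserved within a target taxon
    but divergent from its relatives; enumerates and pairs primer candidates
    under length, GC, melting-temperature and product-size constraints; and
    verifies primer pairs by degenerate-aware in-silico PCR with 3'-clamp
    mismatch rules and virtual-gel band reports. Includes a synthetic panel
    simulator with controlled within- and between-species divergence and
    optional planted primer binding sites, so the whole workflow is testable
    without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
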