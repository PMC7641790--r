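Package: ehrfrag
Title: Display and Task Fragmentation Metrics for Electronic Health Record Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and visualizes two kinds of fragmentation in
    electronic health record (EHR) user interfaces. Display fragmentation is
    measured by the Display Fragmentation Index (DFI), a navigation-complexity
    score computed over a traced pathway through the interface's menu
    hierarchy (data elements reached, level-weighted screen transitions,
    clicks and scroll actions, and accumulated menu length). Task
    fragmentation is measured from time-stamped session event logs via
    average continuous time (ACT) and proportion per instance (PPI). The
    package models annotated navigation trees built from a modified cognitive
    walkthrough, segments session logs into task instances, renders sunburst
    navigation maps and time belt task sequences as deterministic SVG,
    detects pogo-sticking (repeated back-and-forth navigation), generates
    synthetic trees and sessions with controllable fragmentation for testing,
    and assembles comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
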