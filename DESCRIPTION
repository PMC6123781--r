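Package: pathdoe
Title: Design of Experiments and Assembly Planning for Combinatorial
    Pathway Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the Design-Build-Test-Learn (DBTL) engineering of
    microbial production pathways. Defines combinatorial design spaces over
    promoter, copy-number and gene-order factors; reduces them to small
    representative construct libraries with mixed-level orthogonal arrays
    (GF(4) finite-field construction with level collapsing) and Latin-square
    positional assignment, or regular two-level fractional factorials;
    compiles design points into annotated circular plasmid records with
    FASTA and GenBank input/output; plans ligase cycling reaction (LCR)
    assembly by designing junction bridging oligonucleotides to a
    nearest-neighbor melting-temperature target and emitting robotics
    worklists; fits main-effects least-squares models of production titer
    with per-factor F tests and propagates the learned design rules into
    constraints for the next design round. A seeded synthetic-data module
    generates random DNA parts and log-normal titer tables so the full DBTL
    loop runs and is testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
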