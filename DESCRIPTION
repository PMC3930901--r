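Package: ssrforge
Title: Genome-Wide SSR Marker Development Toolkit
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Develops simple sequence repeat (SSR, microsatellite) markers
    from genome assemblies. Detects perfect microsatellite tracts under
    per-motif-class repeat-count thresholds, retains single-copy loci via a
    five-fold top-alignment-score rule, calls SSR length polymorphisms
    between a reference and alternate assemblies by flank anchoring, designs
    locus-specific primer pairs under explicit constraints, and computes
    downstream marker statistics: polymorphism information content (PIC),
    cross-species transferability, Nei (1983) DA genetic distances with
    neighbor-joining trees in Newick format, and a physical map of marker
    positions. Includes a seeded synthetic-data generator (genomes with
    planted SSRs, mutated alternate genotypes, genotype matrices) so the
    entire pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    phangorn,
    jsonlite
Config/testthat/edition: 3
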