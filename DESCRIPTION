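Package: clipbench
Title: Benchmarking Computational Steps for CLIP-Seq Binding-Site Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the computational steps of CLIP-Seq (HITS-CLIP)
    analysis for RNA-binding proteins that bind mRNA: PCR-duplicate collapsing,
    fixed-width peak calling against a global Poisson background with an
    FDR-selected read-count threshold, five peak normalization and ranking
    strategies (raw coverage, transcript-average CLIP, transcript-average input,
    site-level input, and RNAseq/RPKM enrichment), peak-quality metrics (exonic
    fraction and motif occurrence over top-ranked peaks, cross-sample rank
    correlation), and tetramer motif enrichment under GC-matched genomic or
    input-peak background models. Includes a synthetic CLIP/input/RNAseq read
    generator with planted binding sites, transcript abundance variation, PCR
    duplication, fragmentation hotspots, and compositional confounder k-mers, so
    every stage can be tested against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
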