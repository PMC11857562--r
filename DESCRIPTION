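Package: barcodegap
Title: Barcoding-Gap Analysis and Species-Delimitation Scoring for DNA Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the species-level discriminatory power of a DNA
    marker from a multiple-sequence alignment and a reference taxonomy.
    Computes pairwise p-distances and Kimura 2-parameter (K2P) distances
    with pairwise deletion, collapses haplotypes, categorizes pairwise
    distances into intraspecific, within-genus and between-genus classes
    and compares them with rank tests, derives per-sample barcoding gaps
    (nearest non-conspecific minus farthest conspecific distance) with
    per-genus significance tests, classifies sequences to genus by
    diagnostic signature columns, and scores species-delimitation
    partitions and rooted trees against the taxonomy using
    MONO/MERGE/SPLIT/multi-SPLIT verdicts with plain and sample-weighted
    success rates. A K80 sequence-evolution simulator generates taxonomies,
    trees and alignments with nested intraspecific, within-genus and
    between-genus divergence scales so the whole pipeline is testable
    end to end. Bundles a reference dataset of dictyostelid 18S rDNA
    summaries (a 16-isolate pairwise distance table and a 214-sample,
    44-species delimitation summary) used throughout the examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
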