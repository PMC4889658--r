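Package: genarch
Title: Exon-Intron Architecture, Splice-Site Strength, and DNA Strand
    Asymmetry of Polyadenylation Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the exon-intron architecture of
    protein-coding genes: isoform sampling and intron/exon extraction from
    genome FASTA and Ensembl-style GTF annotation, retrainable
    maximum-entropy splice-site strength models (log-odds scoring in bits),
    DNA strand asymmetry of polyadenylation and donor-site-like hexamer
    motifs in trimmed exon and intron interiors, intron-plus-next-exon
    (IpE) unit statistics with a resampling test for nonrandom intron-exon
    size association, sliding-window medians and rank-correlation
    summaries, and a synthetic genome generator with planted, recoverable
    statistical structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
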