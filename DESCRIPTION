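Package: OrfHarmony
Title: Gene-Level Start-Codon Harmonization and NMD Feature Annotation
    for Spliced Transcripts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Annotates open reading frames on spliced transcript models by
    selecting, per gene, the authentic start codon (the start yielding the
    longest protein across all isoforms) and propagating it to every
    isoform, in contrast to the conventional longest-ORF-per-transcript
    annotation. Classifies each stop codon as normal or premature by the
    50-nt downstream exon-junction rule of the EJC model of
    nonsense-mediated decay (NMD), computes 3'/5' UTR lengths and Kozak
    start context (RNNATGGV), compares Reference and Revised annotation
    sets, and scores NMD-target enrichment in differential transcript
    expression data via up/down ratios and Fisher's exact test. Includes a
    deterministic synthetic fixture generator emulating alternative
    splicing events (intron retention, alternative acceptor, exon
    skipping) with ground-truth ORFs and planted differential expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, Annotation, AlternativeSplicing, GenePrediction
RoxygenNote: 7.3.3
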