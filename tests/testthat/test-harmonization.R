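test_that("the two-isoform gene harmonizes to the authentic start", {
    d <- withr::local_tempdir()
    mg <- writeMicroGene(d)
    m <- readTranscriptModels(mg$gtf)
    g <- readGenome(mg$fa)
    seqs <- splicedSequences(m, g)
    expect_identical(as.character(seqs[["t1"]]),
                     "AAAATGGAGGAGGAGTGATTT")
    expect_identical(as.character(seqs[["t2"]]),
                     "AAAATGTGATTTATGGAGGAGTGATTT")

    ref <- annotateReference(m, seqs = seqs, minProteinLen = 1)
    rev <- annotateRevised(m, seqs = seqs, minProteinLen = 1)
    or <- orfTable(ref); ov <- orfTable(rev)
    ## Reference: each isoform keeps its own longest ORF
    expect_identical(or$protein, c("MEEE", "MEE"))
    ## Revised: t1's start (4 aa beats 3 aa) is imposed on t2, whose
    ## harmonized ORF stops immediately (1 aa)
    expect_identical(ov$protein, c("MEEE", "M"))
    expect_identical(ov$start, c(4L, 4L))
    expect_identical(ov$end[2L], 9L)
    expect_identical(unique(ov$status), "HARMONIZED")
    gs <- geneStartTable(rev)
    expect_identical(gs$sourceTranscript, "t1")
    expect_identical(gs$genomicStart, 4L)
})

test_that("gene start selection prefers longest protein then 5'-most", {
    d <- withr::local_tempdir()
    mg <- writeMicroGene(d)
    m <- readTranscriptModels(mg$gtf)
    seqs <- splicedSequences(m, readGenome(mg$fa))
    sel <- selectGeneStart(m, as.list(as.character(seqs)),
                           c("t1", "t2"), minProteinLen = 1)
    expect_identical(sel$sourceTranscript, "t1")
    expect_identical(sel$genomicStart, 4L)

    ## equal-length proteins from different starts: 5'-most genomic wins
    d2 <- withr::local_tempdir()
    fa <- file.path(d2, "g.fa"); gtf <- file.path(d2, "a.gtf")
    ## tA ORF at genomic 1, tB ORF at genomic 13, both 2 aa
    writeLines(c(">chr1", "ATGAAATAACCCATGAAATAACCC"), fa)
    at <- function(tx) sprintf('gene_id "g"; transcript_id "%s";', tx)
    writeLines(c(
        sprintf("chr1\tx\texon\t1\t9\t.\t+\t.\t%s", at("tA")),
        sprintf("chr1\tx\texon\t13\t21\t.\t+\t.\t%s", at("tB"))), gtf)
    m2 <- readTranscriptModels(gtf)
    s2 <- splicedSequences(m2, readGenome(fa))
    sel2 <- selectGeneStart(m2, as.list(as.character(s2)),
                            c("tA", "tB"), minProteinLen = 1)
    expect_identical(sel2$genomicStart, 1L)
    expect_identical(sel2$sourceTranscript, "tA")
})

test_that("isoforms lacking the authentic start fall back, audited", {
    d <- withr::local_tempdir()
    fx <- generateFixture(nGenes = 40, seed = 21, dir = d,
                          eventWeights = c(EXON_SKIP = 1))
    m <- readTranscriptModels(fx$gtfFile)
    g <- readGenome(fx$genomeFile)
    rev <- annotateRevised(m, g)
    o <- orfTable(rev)
    tr <- fx$truth
    skip2 <- tr$transcript_id[tr$revStatus == "FALLBACK_OWN_LONGEST"]
    expect_true(length(skip2) > 0L)
    expect_identical(
        o$status[match(skip2, o$transcript_id)],
        rep("FALLBACK_OWN_LONGEST", length(skip2)))
    ## fallback keeps the isoform's own longest ORF
    expect_identical(o$start[match(skip2, o$transcript_id)],
                     tr$revStart[match(skip2, tr$transcript_id)])
})

test_that("Revised never exceeds Reference protein length; equality iff same start", {
    d <- withr::local_tempdir()
    fx <- generateFixture(nGenes = 60, seed = 31, dir = d)
    m <- readTranscriptModels(fx$gtfFile)
    g <- readGenome(fx$genomeFile)
    seqs <- splicedSequences(m, g)
    ref <- annotateReference(m, seqs = seqs)
    rev <- annotateRevised(m, seqs = seqs)
    or <- orfTable(ref); ov <- orfTable(rev)
    both <- !is.na(or$start) & !is.na(ov$start)
    lr <- nchar(or$protein[both]); lv <- nchar(ov$protein[both])
    expect_true(all(lv <= lr))
    same <- or$start[both] == ov$start[both]
    expect_identical(lv == lr, same)
})

test_that("all harmonized isoforms of a gene share one genomic start", {
    d <- withr::local_tempdir()
    fx <- generateFixture(nGenes = 100, seed = 41, dir = d)
    m <- readTranscriptModels(fx$gtfFile)
    g <- readGenome(fx$genomeFile)
    rev <- annotateRevised(m, g)
    o <- orfTable(rev)
    gs <- geneStartTable(rev)
    harm <- o[o$status == "HARMONIZED", ]
    for (i in seq_len(nrow(harm))) {
        id <- harm$transcript_id[i]
        gpos <- transcriptToGenomic(m, id, harm$start[i])
        want <- gs$genomicStart[gs$gene_id == harm$gene_id[i]]
        expect_identical(gpos, want)
    }
    ## the source transcript is harmonized and keeps its longest ORF
    src <- gs$sourceTranscript[!is.na(gs$sourceTranscript)]
    expect_identical(unique(o$status[match(src, o$transcript_id)]),
                     "HARMONIZED")
})

test_that("re-annotating a written Revised GTF is idempotent", {
    d <- withr::local_tempdir()
    fx <- generateFixture(nGenes = 20, seed = 51, dir = d)
    m <- readTranscriptModels(fx$gtfFile)
    g <- readGenome(fx$genomeFile)
    rev <- annotateRevised(m, g)
    out <- file.path(d, "revised.gtf")
    writeAnnotationGtf(m, rev, out)
    m2 <- readTranscriptModels(out)
    rev2 <- annotateRevised(m2, g)
    expect_identical(orfTable(rev2)$start, orfTable(rev)$start)
    expect_identical(orfTable(rev2)$end, orfTable(rev)$end)
    expect_identical(orfTable(rev2)$protein, orfTable(rev)$protein)
})

test_that("harmonization agrees exactly with brute-force enumeration", {
    d <- withr::local_tempdir()
    fx <- generateFixture(nGenes = 30, seed = 61, dir = d)
    m <- readTranscriptModels(fx$gtfFile)
    g <- readGenome(fx$genomeFile)
    seqs <- splicedSequences(m, g)
    rev <- annotateRevised(m, seqs = seqs)
    o <- orfTable(rev)
    want <- bruteRevised(m, seqs, minLen = 30L)
    for (id in names(want)) {
        i <- which(o$transcript_id == id)
        expect_identical(o$start[i], want[[id]]$start)
        expect_identical(o$end[i], want[[id]]$end)
        expect_identical(o$status[i], want[[id]]$status)
    }
})

test_that("reference ORFs lift from CDS records with validation", {
    d <- withr::local_tempdir()
    fa <- file.path(d, "g.fa"); gtf <- file.path(d, "a.gtf")
    ## spliced transcript reads AAA ATGGAGGAG TGA TTT: CDS (stop
    ## excluded) spans both exons
    writeLines(c(">chr1", "AAAATGGACCCCGGAGTGATTT"), fa)
    at <- function(tx) sprintf('gene_id "g"; transcript_id "%s";', tx)
    writeLines(c(
        sprintf("chr1\tx\texon\t1\t8\t.\t+\t.\t%s", at("t1")),
        sprintf("chr1\tx\texon\t13\t22\t.\t+\t.\t%s", at("t1")),
        sprintf("chr1\tx\tCDS\t4\t8\t.\t+\t0\t%s", at("t1")),
        sprintf("chr1\tx\tCDS\t13\t16\t.\t+\t1\t%s", at("t1")),
        sprintf("chr1\tx\texon\t1\t8\t.\t+\t.\t%s", at("t2"))), gtf)
    m <- readTranscriptModels(gtf)
    g <- readGenome(fa)
    ann <- referenceOrfsFromGtf(m, gtf, g)
    o <- orfTable(ann)
    i <- which(o$transcript_id == "t1")
    expect_identical(o$start[i], 4L)
    expect_identical(o$protein[i], "MEE")
    expect_identical(o$end[i], 15L)
    expect_true(o$hasStop[i])
    ## transcript without CDS is noncoding
    j <- which(o$transcript_id == "t2")
    expect_identical(o$status[j], "NONCODING")

    ## a CDS whose implied stop is not a stop codon is flagged invalid
    writeLines(c(
        sprintf("chr1\tx\texon\t1\t10\t.\t+\t.\t%s", at("t1")),
        sprintf("chr1\tx\tCDS\t4\t6\t.\t+\t0\t%s", at("t1"))), gtf)
    m2 <- readTranscriptModels(gtf)
    expect_warning(ann2 <- referenceOrfsFromGtf(m2, gtf, g), "invalid")
    expect_identical(orfTable(ann2)$status, "INVALID")
})
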