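test_that("GTF coordinates convert to transcript models correctly", {
    d <- withr::local_tempdir()
    gtf <- file.path(d, "a.gtf")
    at <- function(tx) sprintf('gene_id "g1"; transcript_id "%s";', tx)
    ## single exon 101-200 (+): one 100-nt transcript
    writeLines(sprintf("chr1\tx\texon\t101\t200\t.\t+\t.\t%s", at("t1")),
               gtf)
    m <- readTranscriptModels(gtf)
    expect_identical(txIds(m), "t1")
    expect_identical(txData(m)$splicedLength, 100L)
    g <- exonsBy(m)[["t1"]]
    expect_identical(GenomicRanges::start(g), 101L)
    expect_identical(GenomicRanges::end(g), 200L)

    ## two exons: junction after the 50th transcript base, both strands
    for (strand in c("+", "-")) {
        gtf2 <- file.path(d, paste0("b", strand, ".gtf"))
        writeLines(sprintf("chr1\tx\texon\t%d\t%d\t.\t%s\t.\t%s",
                           c(101L, 201L), c(150L, 250L), strand,
                           at("t2")), gtf2)
        m2 <- readTranscriptModels(gtf2)
        expect_identical(exonJunctions(m2)[["t2"]], 50L)
        g2 <- exonsBy(m2)[["t2"]]
        ## 5'->3' exon order flips with strand
        expect_identical(GenomicRanges::start(g2)[1L],
                         if (strand == "+") 101L else 201L)
    }
})

test_that("GTF parse and validation errors are informative", {
    d <- withr::local_tempdir()
    gtf <- file.path(d, "bad.gtf")
    writeLines("chr1\tx\texon\t1\t10\t.\t+\t.\tgene_id \"g\";", gtf)
    expect_error(readTranscriptModels(gtf), "transcript_id")
    ## mixed strands within one transcript
    writeLines(c(
        "chr1\tx\texon\t1\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
        "chr1\tx\texon\t20\t30\t.\t-\t.\tgene_id \"g\"; transcript_id \"t\";"),
        gtf)
    expect_error(readTranscriptModels(gtf), "mixed")
    expect_error(readTranscriptModels(file.path(d, "nofile.gtf")),
                 "not found")
})

test_that("FASTA reading normalizes case, names and rejects duplicates", {
    d <- withr::local_tempdir()
    fa <- file.path(d, "g.fa")
    writeLines(c(">chr1 some description", "acgt", "ACGT"), fa)
    g <- readGenome(fa)
    expect_identical(names(g), "chr1")
    expect_identical(as.character(g[[1L]]), "ACGTACGT")
    writeLines(c(">c", "AA", ">c", "TT"), fa)
    expect_error(readGenome(fa), "duplicate")
})

test_that("spliced sequence extraction splices and reverse-complements", {
    d <- withr::local_tempdir()
    fa <- file.path(d, "g.fa"); gtf <- file.path(d, "a.gtf")
    writeLines(c(">chr1", "ATGCCCTAA"), fa)
    at <- 'gene_id "g"; transcript_id "t";'
    ## exons (1-3) and (7-9) on +: "ATG" + "TAA"
    writeLines(sprintf("chr1\tx\texon\t%d\t%d\t.\t+\t.\t%s",
                       c(1L, 7L), c(3L, 9L), at), gtf)
    m <- readTranscriptModels(gtf)
    g <- readGenome(fa)
    s <- splicedSequences(m, g)
    expect_identical(as.character(s[["t"]]), "ATGTAA")
    expect_identical(exonJunctions(m)[["t"]], 3L)

    ## minus strand single exon over "TTACAT" -> "ATGTAA"
    writeLines(c(">chr1", "TTACAT"), fa)
    writeLines(sprintf("chr1\tx\texon\t1\t6\t.\t-\t.\t%s", at), gtf)
    m2 <- readTranscriptModels(gtf)
    s2 <- splicedSequences(m2, readGenome(fa))
    expect_identical(as.character(s2[["t"]]), "ATGTAA")
    expect_identical(exonJunctions(m2)[["t"]], integer(0))

    ## exon beyond chromosome end
    writeLines(sprintf("chr1\tx\texon\t1\t60\t.\t+\t.\t%s", at), gtf)
    expect_error(splicedSequences(readTranscriptModels(gtf),
                                  readGenome(fa)), "bounds")
})

test_that("minus-strand extraction equals revcomp of plus extraction", {
    set.seed(42)
    d <- withr::local_tempdir()
    for (rep in 1:5) {
        chrom <- randomSeq(300)
        fa <- file.path(d, "g.fa"); gtf <- file.path(d, "a.gtf")
        writeLines(c(">chr1", chrom), fa)
        ## random non-overlapping exon set
        cuts <- sort(sample(10:290, 6))
        st <- cuts[c(1, 3, 5)]; en <- cuts[c(2, 4, 6)] - 1L
        lines <- c(
            sprintf("chr1\tx\texon\t%d\t%d\t.\t+\t.\t%s", st, en,
                    'gene_id "g"; transcript_id "tp";'),
            sprintf("chr1\tx\texon\t%d\t%d\t.\t-\t.\t%s", st, en,
                    'gene_id "g"; transcript_id "tm";'))
        writeLines(lines, gtf)
        m <- readTranscriptModels(gtf)
        s <- splicedSequences(m, readGenome(fa))
        rc <- as.character(Biostrings::reverseComplement(s[["tp"]]))
        expect_identical(as.character(s[["tm"]]), rc)
    }
})

test_that("genomic/transcript coordinate maps invert each other", {
    d <- withr::local_tempdir()
    gtf <- file.path(d, "a.gtf")
    at <- function(tx) sprintf('gene_id "g"; transcript_id "%s";', tx)
    writeLines(c(
        sprintf("chr1\tx\texon\t%d\t%d\t.\t+\t.\t%s", c(101L, 201L),
                c(150L, 250L), at("tp")),
        sprintf("chr1\tx\texon\t%d\t%d\t.\t-\t.\t%s", c(101L, 201L),
                c(150L, 250L), at("tm"))), gtf)
    m <- readTranscriptModels(gtf)
    ## 1-based: genomic 201 is the 51st transcript base on +
    expect_identical(genomicToTranscript(m, "tp", 201L), 51L)
    expect_identical(transcriptToGenomic(m, "tp", 51L), 201L)
    ## intronic position is absent, not an error
    expect_identical(genomicToTranscript(m, "tp", 175L), NA_integer_)
    ## minus strand: genomic 250 is the transcript's first base
    expect_identical(genomicToTranscript(m, "tm", 250L), 1L)
    expect_identical(transcriptToGenomic(m, "tm", 100L), 101L)
    expect_error(transcriptToGenomic(m, "tp", 101L), "out of range")
    ## round trip over every exonic position, both strands
    for (tx in c("tp", "tm")) {
        for (gpos in c(101:150, 201:250)) {
            tp <- genomicToTranscript(m, tx, gpos)
            expect_identical(transcriptToGenomic(m, tx, tp), gpos)
        }
    }
})

test_that("annotation GTF round-trips models and CDS spans", {
    d <- withr::local_tempdir()
    fx <- generateFixture(nGenes = 10, seed = 3, dir = d)
    m <- readTranscriptModels(fx$gtfFile)
    g <- readGenome(fx$genomeFile)
    seqs <- splicedSequences(m, g)
    rev <- annotateRevised(m, seqs = seqs)
    out <- file.path(d, "out.gtf")
    writeAnnotationGtf(m, rev, out)
    m2 <- readTranscriptModels(out)
    expect_identical(txIds(m2), txIds(m))
    expect_identical(exonJunctions(m2), exonJunctions(m))
    ## CDS lines lift back to exactly the ORFs that were written
    lift <- referenceOrfsFromGtf(m2, out, seqs = seqs)
    o1 <- orfTable(rev); o2 <- orfTable(lift)
    coding <- !is.na(o1$start) & o1$hasStop
    expect_identical(o2$start[coding], o1$start[coding])
    expect_identical(o2$end[coding], o1$end[coding])
    expect_identical(o2$protein[coding], o1$protein[coding])
    ## ORF spanning a junction gets frame values from cumulative length
    lines <- readLines(out)
    cdsLines <- grep("\tCDS\t", lines, value = TRUE)
    expect_true(length(cdsLines) > 0L)
    frames <- as.integer(vapply(strsplit(cdsLines, "\t"), `[[`,
                                character(1), 8L))
    expect_true(all(frames %in% 0:2))
})

test_that("feature table CSV writes the documented layout", {
    d <- withr::local_tempdir()
    fx <- generateFixture(nGenes = 5, seed = 5, dir = d)
    m <- readTranscriptModels(fx$gtfFile)
    g <- readGenome(fx$genomeFile)
    rev <- annotateRevised(m, g)
    f <- nmdFeatures(rev, m, g)
    csv <- file.path(d, "feat.csv")
    writeFeatureTable(f, csv)
    hdr <- strsplit(readLines(csv, n = 1L), ",")[[1L]]
    expect_identical(hdr[1L], "\"Transcript_ID\"")
    ## protein translation is the final column
    expect_identical(hdr[length(hdr)], "\"Translation\"")
    back <- readFeatureTable(csv)
    expect_identical(back$stopClass, f$stopClass)
    expect_identical(back$utr3Length, f$utr3Length)
    expect_identical(back$protein, f$protein)
    ## empty collection -> header-only CSV
    writeFeatureTable(f[0, ], csv)
    expect_identical(length(readLines(csv)), 1L)
})
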