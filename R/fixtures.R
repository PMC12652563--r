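## Synthetic multi-isoform fixture generator.
##
## Construction guarantees that make ground truth derivable by
## arithmetic rather than by re-running the annotator:
##  - designed ORF bodies and UTRs are built from T-free alphabets, so
##    outside the planted ATG/stop codons no start or stop codon can
##    occur in any frame;
##  - planted introns embed TAGCTAGCTAG, which terminates translation in
##    all three frames within 11 nt;
##  - the alternative-acceptor tail TAGCTAGCTAGCAG likewise stops all
##    frames and enters the reading frame at phase 0 by construction.

.TFREE <- apply(expand.grid(c("A", "C", "G"), c("A", "C", "G"),
                            c("A", "C", "G")), 1, paste, collapse = "")
.STOPBLOCK <- "TAGCTAGCTAG"
.ALTTAIL <- "TAGCTAGCTAGCAG"   # 14 nt, stop in every frame

.randChars <- function(n)
    if (n <= 0L) "" else
        paste(sample(c("A", "C", "G"), n, replace = TRUE), collapse = "")

.aa <- function(codons)
    paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")

.revcompChar <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## One gene: canonical 3-exon isoform with a designed main ORF, plus at
## most one event isoform. Returns segment sequence (plus orientation),
## exon tables and truth rows, all in local coordinates.
.makeGene <- function(geneId, event, pKozak, fracMinus) {
    minus <- stats::runif(1) < fracMinus
    kozak <- stats::runif(1) < pKozak
    u  <- sample(9:30, 1L)
    c1 <- sample(10:15, 1L)
    c2 <- sample(25:35, 1L)
    c3 <- sample(10:20, 1L)
    m  <- sample(2:4, 1L)          # internal ATG = exon-2 codon m
    i1 <- sample(28:40, 1L)
    i2 <- sample(17:30, 1L)
    v  <- sample(30:80, 1L)

    utr5 <- paste0(.randChars(u - 3L), if (kozak) "GCC" else "CCC")
    body <- sample(.TFREE, c1 + c2 + c3, replace = TRUE)
    body[1L] <- if (kozak) "GCA" else "CCA"
    body[c1 + m - 1L] <- "CCC"     # weak context for the internal ATG
    body[c1 + m] <- "ATG"
    body[c1 + m + 1L] <- "CCA"
    utr3 <- .randChars(v)
    intron1 <- paste0("GT", .STOPBLOCK, .randChars(i1 - 27L), .ALTTAIL)
    intron2 <- paste0("GT", .STOPBLOCK, .randChars(i2 - 15L), "AG")
    stopifnot(nchar(intron1) == i1, nchar(intron2) == i2)

    A <- u + 3L + 3L * c1                       # end of exon 1
    e1seq <- paste0(utr5, "ATG",
                    paste(body[seq_len(c1)], collapse = ""))
    e2seq <- paste(body[(c1 + 1L):(c1 + c2)], collapse = "")
    e3seq <- paste0(paste(body[(c1 + c2 + 1L):(c1 + c2 + c3)],
                          collapse = ""), "TAA", utr3)
    segment <- paste0(e1seq, intron1, e2seq, intron2, e3seq)
    B <- A + i1 + 3L * c2                       # end of exon 2
    segLen <- nchar(segment)

    e1 <- c(1L, A)
    e2 <- c(A + i1 + 1L, B)
    e3 <- c(B + i2 + 1L, segLen)

    canonEnd <- u + 3L * (2L + c1 + c2 + c3)
    canonProt <- paste0("M", .aa(body))
    internalProt <- paste0(
        "M", .aa(body[(c1 + m + 1L):(c1 + c2 + c3)]))
    t1 <- geneId %.% ".1"; t2 <- geneId %.% ".2"

    truth1 <- data.frame(
        transcript_id = t1, gene_id = geneId, event = event,
        strand = if (minus) "-" else "+",
        refStart = u + 1L, refEnd = canonEnd, refClass = "NORMAL",
        refKozak = kozak, refProtein = canonProt,
        revStart = u + 1L, revEnd = canonEnd, revClass = "NORMAL",
        revKozak = kozak, revProtein = canonProt,
        revStatus = "HARMONIZED", revDist = NA_integer_,
        revNDej = 0L, stringsAsFactors = FALSE)

    exons <- list()
    exons[[t1]] <- rbind(e1, e2, e3)
    truth <- truth1

    if (event == "INTRON_RETENTION") {
        exons[[t2]] <- rbind(c(1L, B), e3)
        refStart <- A + i1 + 3L * (m - 1L) + 1L
        truth <- rbind(truth, data.frame(
            transcript_id = t2, gene_id = geneId, event = event,
            strand = if (minus) "-" else "+",
            refStart = refStart, refEnd = canonEnd + i1,
            refClass = "NORMAL", refKozak = FALSE,
            refProtein = internalProt,
            revStart = u + 1L, revEnd = A + 9L, revClass = "PTC_dEJ",
            revKozak = kozak,
            revProtein = paste0("M", .aa(body[seq_len(c1)]), "VS"),
            revStatus = "HARMONIZED",
            revDist = i1 + 3L * c2 - 9L, revNDej = 1L,
            stringsAsFactors = FALSE))
    } else if (event == "ALT_ACCEPTOR") {
        exons[[t2]] <- rbind(e1, c(A + i1 - 13L, B), e3)
        refStart <- A + 14L + 3L * (m - 1L) + 1L
        truth <- rbind(truth, data.frame(
            transcript_id = t2, gene_id = geneId, event = event,
            strand = if (minus) "-" else "+",
            refStart = refStart, refEnd = canonEnd + 14L,
            refClass = "NORMAL", refKozak = FALSE,
            refProtein = internalProt,
            revStart = u + 1L, revEnd = A + 3L, revClass = "PTC_dEJ",
            revKozak = kozak,
            revProtein = paste0("M", .aa(body[seq_len(c1)])),
            revStatus = "HARMONIZED",
            revDist = 11L + 3L * c2, revNDej = 1L,
            stringsAsFactors = FALSE))
    } else if (event == "EXON_SKIP") {
        exons[[t2]] <- rbind(e2, e3)
        st <- 3L * (m - 1L) + 1L
        en <- 3L * (c2 + c3 + 1L)
        truth <- rbind(truth, data.frame(
            transcript_id = t2, gene_id = geneId, event = event,
            strand = if (minus) "-" else "+",
            refStart = st, refEnd = en, refClass = "NORMAL",
            refKozak = FALSE, refProtein = internalProt,
            revStart = st, revEnd = en, revClass = "NORMAL",
            revKozak = FALSE, revProtein = internalProt,
            revStatus = "FALLBACK_OWN_LONGEST",
            revDist = NA_integer_, revNDej = 0L,
            stringsAsFactors = FALSE))
    }

    if (minus) {
        segment <- .revcompChar(segment)
        exons <- lapply(exons, function(m2)
            cbind(segLen - m2[, 2L] + 1L, segLen - m2[, 1L] + 1L))
    }
    list(segment = segment, exons = exons, truth = truth,
         strand = if (minus) "-" else "+")
}

`%.%` <- function(a, b) paste0(a, b)

.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Generate a synthetic genome + annotation fixture with ground truth
#'
#' Emits a single-chromosome genome FASTA and a GTF of multi-isoform
#' genes with controlled alternative-splicing events, together with a
#' ground-truth table derived from the construction itself (not from
#' re-running the annotator). Each gene has a canonical 3-exon isoform
#' with a designed main ORF whose start has a strong Kozak context with
#' probability \code{pKozak}, plus (depending on the event drawn) one
#' event isoform:
#' \itemize{
#' \item \code{INTRON_RETENTION}: the first intron (stop-bearing in all
#'   frames) is retained, so the harmonized (Revised) ORF terminates
#'   early with a junction >= 50 nt downstream (planted PTC_dEJ), while
#'   the per-transcript longest ORF (Reference) restarts at a planted
#'   weak-context internal ATG and looks normal;
#' \item \code{ALT_ACCEPTOR}: an upstream acceptor includes a 14-nt
#'   stop-bearing intron tail, same Revised-vs-Reference contrast;
#' \item \code{EXON_SKIP}: the first exon (carrying the authentic start)
#'   is skipped, exercising the fallback to the isoform's own longest
#'   ORF;
#' \item \code{NONE}: single-isoform gene.
#' }
#' Output is deterministic given \code{seed}.
#'
#' @param nGenes Number of genes.
#' @param eventWeights Named non-negative weights over the four events.
#' @param pKozak Probability that a canonical start gets a strong Kozak
#'   context.
#' @param fracMinus Fraction of genes placed on the minus strand.
#' @param intergenicGap Gap (nt) between gene loci.
#' @param seed Integer seed; the generator restores the caller's RNG
#'   state.
#' @param dir Output directory (created if needed).
#' @return List: \code{genomeFile}, \code{gtfFile}, \code{truthFile},
#'   \code{truth} (data.frame), \code{genome}
#'   (\link[Biostrings]{DNAStringSet}).
#' @examples
#' fx <- generateFixture(nGenes = 2, seed = 7, dir = tempdir())
#' fx$truth[, c("transcript_id", "event", "refClass", "revClass")]
#' @export
generateFixture <- function(nGenes,
                            eventWeights = c(NONE = 1,
                                             INTRON_RETENTION = 1,
                                             ALT_ACCEPTOR = 1,
                                             EXON_SKIP = 1),
                            pKozak = 0.5, fracMinus = 0.3,
                            intergenicGap = 200L, seed = 1L, dir) {
    evs <- c("NONE", "INTRON_RETENTION", "ALT_ACCEPTOR", "EXON_SKIP")
    w <- eventWeights[evs]
    w[is.na(w)] <- 0
    if (any(w < 0) || sum(w) <= 0)
        stop("eventWeights must be non-negative with positive sum")
    if (nGenes < 1L) stop("nGenes must be >= 1")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

    res <- .withSeed(seed, {
        segs <- character(nGenes)
        gtf <- character(0)
        truth <- vector("list", nGenes)
        offset <- 0L
        gap <- strrep("C", intergenicGap)
        for (i in seq_len(nGenes)) {
            gid <- sprintf("g%04d", i)
            ev <- sample(evs, 1L, prob = w)
            g <- .makeGene(gid, ev, pKozak, fracMinus)
            for (tx in names(g$exons)) {
                e <- g$exons[[tx]]
                o <- order(e[, 1L])
                gtf <- c(gtf, sprintf(
                    "chr1\tfixture\texon\t%d\t%d\t.\t%s\t.\t%s",
                    offset + e[o, 1L], offset + e[o, 2L], g$strand,
                    .gtfAttr(gid, tx)))
            }
            segs[i] <- g$segment
            truth[[i]] <- g$truth
            offset <- offset + nchar(g$segment) + intergenicGap
        }
        chrom <- paste0(paste(segs, collapse = gap), gap)
        list(chrom = chrom, gtf = gtf,
             truth = do.call(rbind, truth))
    })

    genome <- Biostrings::DNAStringSet(res$chrom)
    names(genome) <- "chr1"
    genomeFile <- file.path(dir, "genome.fa")
    gtfFile <- file.path(dir, "annotation.gtf")
    truthFile <- file.path(dir, "truth.csv")
    Biostrings::writeXStringSet(genome, genomeFile)
    writeLines(res$gtf, gtfFile)
    utils::write.csv(res$truth, truthFile, row.names = FALSE, na = "")
    list(genomeFile = genomeFile, gtfFile = gtfFile,
         truthFile = truthFile, truth = res$truth, genome = genome)
}

#' Generate a planted differential-expression table over fixture truth
#'
#' Assigns UP/DOWN/NO_CHANGE per transcript by Bernoulli draws whose up
#' probability depends on the transcript's planted (Revised) stop class,
#' then draws corrected p-values and log2 fold changes consistent with
#' those statuses under the default [classifyDe()] thresholds. The
#' planted NMD enrichment factor is
#' \code{(pUpPtc/pDown) / (pUpNormal/pDown) = pUpPtc/pUpNormal},
#' attached as attribute \code{expectedFactor}.
#'
#' @param truth Truth data.frame from [generateFixture()].
#' @param pUpPtc,pUpNormal Up probability for PTC_dEJ / normal-stop
#'   transcripts.
#' @param pDown Down probability (class-independent, emulating
#'   class-blind indirect effects).
#' @param seed Integer seed.
#' @param file Optional CSV path to write.
#' @return data.frame with columns \code{transcript_id}, \code{qval},
#'   \code{log2fc}; attribute \code{expectedFactor}.
#' @export
generateDeTable <- function(truth, pUpPtc = 0.3, pUpNormal = 0.15,
                            pDown = 0.15, seed = 1L, file = NULL) {
    stopifnot(pUpPtc >= 0, pUpNormal >= 0, pDown >= 0,
              pUpPtc + pDown <= 1, pUpNormal + pDown <= 1)
    de <- .withSeed(seed, {
        n <- nrow(truth)
        pUp <- ifelse(truth$revClass == "PTC_dEJ", pUpPtc, pUpNormal)
        u <- stats::runif(n)
        status <- ifelse(u < pUp, "UP",
                         ifelse(u < pUp + pDown, "DOWN", "NO_CHANGE"))
        qval <- ifelse(status == "NO_CHANGE",
                       stats::runif(n, 0.2, 0.9),
                       stats::runif(n, 0.001, 0.049))
        lfc <- ifelse(status == "UP", stats::runif(n, 1.5, 4),
               ifelse(status == "DOWN", -stats::runif(n, 1.5, 4),
                      stats::runif(n, -0.5, 0.5)))
        data.frame(transcript_id = truth$transcript_id,
                   qval = qval, log2fc = lfc, stringsAsFactors = FALSE)
    })
    attr(de, "expectedFactor") <-
        if (pDown > 0 && pUpNormal > 0) pUpPtc / pUpNormal else NA_real_
    if (!is.null(file))
        utils::write.csv(de, file, row.names = FALSE)
    de
}
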