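## ORF rows are accumulated as plain lists and bound once at the end
## (data.frame construction per transcript is a hotspot at scale).
.naOrfRow <- function(id, gene, status = "NONCODING")
    list(transcript_id = id, gene_id = gene, start = NA_integer_,
         end = NA_integer_, hasStop = NA, cdsLength = NA_integer_,
         protein = NA_character_, status = status)

.orfRow <- function(id, gene, orf, status)
    list(transcript_id = id, gene_id = gene,
         start = as.integer(orf$start), end = as.integer(orf$end),
         hasStop = orf$hasStop, cdsLength = as.integer(orf$cdsLength),
         protein = orf$protein, status = status)

.bindOrfRows <- function(rows)
    data.frame(
        transcript_id = vapply(rows, `[[`, character(1), "transcript_id"),
        gene_id = vapply(rows, `[[`, character(1), "gene_id"),
        start = vapply(rows, `[[`, integer(1), "start"),
        end = vapply(rows, `[[`, integer(1), "end"),
        hasStop = vapply(rows, `[[`, logical(1), "hasStop"),
        cdsLength = vapply(rows, `[[`, integer(1), "cdsLength"),
        protein = vapply(rows, `[[`, character(1), "protein"),
        status = vapply(rows, `[[`, character(1), "status"),
        stringsAsFactors = FALSE)

.finishOrfSet <- function(rows, mode, geneStarts = NULL) {
    if (is.list(rows) && !is.data.frame(rows)) rows <- .bindOrfRows(rows)
    rows <- rows[order(rows$gene_id, rows$transcript_id), , drop = FALSE]
    rownames(rows) <- NULL
    if (is.null(geneStarts))
        geneStarts <- S4Vectors::DataFrame(
            gene_id = character(0), chrom = character(0),
            strand = character(0), genomicStart = integer(0),
            sourceTranscript = character(0))
    new("OrfSet", mode = mode, orfs = S4Vectors::DataFrame(rows),
        geneStarts = geneStarts)
}

## Gene grouping: genes whose isoforms sit on several chrom/strand
## combinations (annotation errors) are processed per (gene, chrom,
## strand) with a warning.
.geneGroups <- function(td) {
    key <- paste(td$gene_id, td$chrom, td$strand, sep = "\r")
    multi <- tapply(key, td$gene_id, function(k) length(unique(k)) > 1L)
    if (any(multi))
        warning("gene(s) with isoforms on multiple chromosomes/strands, ",
                "processed per (gene, chrom, strand) group: ",
                paste(names(multi)[multi], collapse = ", "))
    split(rownames(td), key)
}

## Plain-vector index over the exon chains: avoids per-row S4 indexing
## in the per-transcript loops.
.modelIndex <- function(models) {
    td <- models@txData
    nEx <- S4Vectors::elementNROWS(models@exons)
    u <- unlist(models@exons, use.names = FALSE)
    f <- factor(rep(seq_len(nrow(td)), nEx),
                levels = seq_len(nrow(td)))
    st <- split(GenomicRanges::start(u), f)
    en <- split(GenomicRanges::end(u), f)
    names(st) <- names(en) <- rownames(td)
    ## environments give O(1) by-name lookup in the per-transcript loops
    list(st = list2env(st), en = list2env(en),
         strand = list2env(as.list(structure(
             as.character(td$strand), names = rownames(td)))),
         gene = list2env(as.list(structure(
             as.character(td$gene_id), names = rownames(td)))),
         len = list2env(as.list(structure(
             as.integer(td$splicedLength), names = rownames(td)))),
         ids = rownames(td))
}

.t2g <- function(idx, txId, tpos) {
    st <- idx$st[[txId]]; en <- idx$en[[txId]]
    w <- en - st + 1L
    cum <- cumsum(w); cumBefore <- c(0L, cum[-length(cum)])
    if (any(tpos < 1L | tpos > cum[length(cum)]))
        stop("transcript coordinate out of range for '", txId, "'")
    i <- findInterval(tpos - 1L, cum) + 1L
    off <- tpos - cumBefore[i]
    if (idx$strand[[txId]] == "+") st[i] + off - 1L
    else en[i] - off + 1L
}

.g2t <- function(idx, txId, gpos) {
    st <- idx$st[[txId]]; en <- idx$en[[txId]]
    w <- en - st + 1L
    cumBefore <- c(0L, cumsum(w)[-length(w)])
    i <- which(st <= gpos & gpos <= en)
    if (length(i) == 0L) return(NA_integer_)
    i <- i[1L]
    if (idx$strand[[txId]] == "+") cumBefore[i] + (gpos - st[i] + 1L)
    else cumBefore[i] + (en[i] - gpos + 1L)
}

#' Reference annotation: the longest ORF of each transcript
#'
#' Annotates every isoform independently with its own longest ORF — the
#' conventional per-transcript rule used by reference transcriptome
#' annotations.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param genome A named \link[Biostrings]{DNAStringSet}, or \code{NULL}
#'   when \code{seqs} is supplied.
#' @param minProteinLen Minimum protein length (aa) for an ORF call.
#' @param seqs Optional precomputed [splicedSequences()] result.
#' @return An \linkS4class{OrfSet} with \code{mode = "REFERENCE"}.
#' @export
annotateReference <- function(models, genome = NULL, minProteinLen = 30L,
                              seqs = NULL) {
    if (is.null(seqs)) seqs <- splicedSequences(models, genome)
    sChar <- list2env(as.list(structure(as.character(seqs),
                                        names = names(seqs))))
    idx <- .modelIndex(models)
    rows <- lapply(idx$ids, function(id) {
        orf <- longestOrf(sChar[[id]], minProteinLen)
        if (is.null(orf)) .naOrfRow(id, idx$gene[[id]])
        else .orfRow(id, idx$gene[[id]], orf, "OWN_LONGEST")
    })
    .finishOrfSet(rows, "REFERENCE")
}

#' Select the gene-level authentic start codon
#'
#' Computes each isoform's longest ORF, maps every candidate start to
#' genomic coordinates, and picks as the authentic start the candidate
#' whose own-transcript protein is the longest gene-wide. Ties are broken
#' by the 5'-most genomic position in transcription direction, then by
#' lexicographic transcript id.
#'
#' @param models A \linkS4class{TranscriptModels} (the gene's isoforms;
#'   ids in \code{txIdsOfGene}).
#' @param seqs Spliced sequences covering those transcripts.
#' @param txIdsOfGene Character vector of the gene's transcript ids.
#' @param minProteinLen Minimum protein length (aa) for candidates.
#' @param idx Optional precomputed internal exon index (used by
#'   [annotateRevised()] to avoid rebuilding it per gene).
#' @return List with \code{genomicStart} (NA when the gene is
#'   noncoding), \code{sourceTranscript}, \code{chrom}, \code{strand},
#'   and \code{longest}, a named list of each isoform's own longest-ORF
#'   row (NULL where none).
#' @export
selectGeneStart <- function(models, seqs, txIdsOfGene,
                            minProteinLen = 30L, idx = NULL) {
    if (is.null(idx)) idx <- .modelIndex(models)
    td <- models@txData
    longest <- lapply(txIdsOfGene, function(id)
        longestOrf(seqs[[id]], minProteinLen))
    names(longest) <- txIdsOfGene
    have <- !vapply(longest, is.null, logical(1))
    chrom <- td[txIdsOfGene[1L], "chrom"]
    strand <- idx$strand[[txIdsOfGene[1L]]]
    if (!any(have))
        return(list(genomicStart = NA_integer_,
                    sourceTranscript = NA_character_,
                    chrom = chrom, strand = strand, longest = longest))
    ids <- txIdsOfGene[have]
    plen <- vapply(ids, function(id) longest[[id]]$proteinLength,
                   integer(1))
    gpos <- vapply(ids, function(id)
        as.numeric(.t2g(idx, id, longest[[id]]$start)), numeric(1))
    ## 5'-most in transcription direction: smallest genomic position on
    ## +, largest on -.
    dirpos <- if (strand == "+") gpos else -gpos
    o <- order(-plen, dirpos, ids)
    pick <- ids[o[1L]]
    list(genomicStart = as.integer(gpos[pick]), sourceTranscript = pick,
         chrom = chrom, strand = strand, longest = longest)
}

#' Impose the gene's authentic start codon on one isoform
#'
#' If the authentic genomic start maps into the isoform's exons and its
#' spliced sequence reads ATG there, the ORF runs from that ATG to the
#' first in-frame stop (or to the last complete codon when stopless) —
#' status \code{HARMONIZED}. Otherwise the isoform keeps its own longest
#' ORF (\code{FALLBACK_OWN_LONGEST}), or is \code{NONCODING} when it has
#' none. Harmonized ORFs are never re-filtered by length.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param txId The isoform's transcript id.
#' @param seq Its spliced sequence.
#' @param genomicStart Genomic position of the A of the authentic ATG
#'   (NA for a noncoding gene).
#' @param ownLongest The isoform's own longest-ORF row (or NULL).
#' @param idx Optional precomputed internal exon index.
#' @return Named list: ORF fields (\code{start}, \code{end},
#'   \code{hasStop}, \code{cdsLength}, \code{protein}) plus
#'   \code{status}.
#' @export
applyAuthenticStart <- function(models, txId, seq, genomicStart,
                                ownLongest = NULL, idx = NULL) {
    if (is.null(idx)) idx <- .modelIndex(models)
    gene <- idx$gene[[txId]]
    s <- toupper(as.character(seq))
    if (!is.na(genomicStart)) {
        tpos <- .g2t(idx, txId, genomicStart)
        if (!is.na(tpos) && tpos + 2L <= nchar(s) &&
            substr(s, tpos, tpos + 2L) == "ATG") {
            orf <- .orfFromStart(s, tpos)
            return(.orfRow(txId, gene, orf, "HARMONIZED"))
        }
    }
    if (is.null(ownLongest)) .naOrfRow(txId, gene)
    else .orfRow(txId, gene, ownLongest, "FALLBACK_OWN_LONGEST")
}

#' Revised annotation: harmonized authentic starts across isoforms
#'
#' The core re-annotation: per gene, [selectGeneStart()] chooses the
#' start codon yielding the longest protein across all isoforms, then
#' [applyAuthenticStart()] imposes it on every isoform. The Kozak
#' context plays no role in the selection.
#'
#' @inheritParams annotateReference
#' @return An \linkS4class{OrfSet} with \code{mode = "REVISED"} and a
#'   filled gene-start table.
#' @examples
#' fx <- generateFixture(nGenes = 3, seed = 1, dir = tempdir())
#' m <- readTranscriptModels(fx$gtfFile)
#' g <- readGenome(fx$genomeFile)
#' annotateRevised(m, g)
#' @export
annotateRevised <- function(models, genome = NULL, minProteinLen = 30L,
                            seqs = NULL) {
    if (is.null(seqs)) seqs <- splicedSequences(models, genome)
    sChar <- list2env(as.list(structure(as.character(seqs),
                                        names = names(seqs))))
    idx <- .modelIndex(models)
    td <- models@txData
    groups <- .geneGroups(td)
    rows <- vector("list", nrow(td)); ri <- 0L
    gs <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
        ids <- groups[[gi]]
        sel <- selectGeneStart(models, sChar, ids, minProteinLen,
                               idx = idx)
        gs[[gi]] <- data.frame(
            gene_id = td[ids[1L], "gene_id"], chrom = sel$chrom,
            strand = sel$strand, genomicStart = sel$genomicStart,
            sourceTranscript = sel$sourceTranscript,
            stringsAsFactors = FALSE)
        for (id in ids) {
            ri <- ri + 1L
            rows[[ri]] <- applyAuthenticStart(
                models, id, sChar[[id]], sel$genomicStart,
                sel$longest[[id]], idx = idx)
        }
    }
    gs <- do.call(rbind, gs)
    gs <- gs[order(gs$gene_id), , drop = FALSE]
    rownames(gs) <- NULL
    .finishOrfSet(rows, "REVISED", S4Vectors::DataFrame(gs))
}

#' Reference ORFs lifted from the CDS records of a GTF
#'
#' Builds a REFERENCE annotation directly from the CDS lines of a
#' published annotation instead of recomputing longest ORFs. The spliced
#' CDS span is mapped into transcript coordinates; the stop codon may
#' either follow the CDS (the usual GTF convention) or be included in
#' it. Transcripts without CDS records are noncoding; CDS that fall
#' outside exons, are not a multiple of 3, lack an ATG, lack a valid
#' stop codon, or contain an internal stop are flagged \code{INVALID}
#' with a warning.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param path The GTF/GFF file carrying the CDS records.
#' @param genome Genome \link[Biostrings]{DNAStringSet}, or \code{NULL}
#'   when \code{seqs} is given.
#' @param seqs Optional precomputed spliced sequences.
#' @return An \linkS4class{OrfSet} with \code{mode = "REFERENCE"}.
#' @export
referenceOrfsFromGtf <- function(models, path, genome = NULL,
                                 seqs = NULL) {
    if (is.null(seqs)) seqs <- splicedSequences(models, genome)
    fmt <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
        "gff3" else "gtf"
    gr <- rtracklayer::import(path, format = fmt)
    cds <- gr[S4Vectors::mcols(gr)$type == "CDS"]
    at <- .exonAttributes(cds)
    td <- models@txData
    midx <- .modelIndex(models)
    sAll <- list2env(as.list(structure(as.character(seqs),
                                       names = names(seqs))))
    byTx <- split(seq_along(cds), at$transcript_id)
    bad <- character(0)
    rows <- lapply(rownames(td), function(id) {
        gene <- midx$gene[[id]]
        idx <- byTx[[id]]
        if (is.null(idx)) return(.naOrfRow(id, gene))
        g <- cds[idx]
        s <- toupper(sAll[[id]])
        n <- nchar(s)
        ## 5'-most and 3'-most CDS bases in transcript direction
        if (midx$strand[[id]] == "+") {
            g5 <- min(GenomicRanges::start(g))
            g3 <- max(GenomicRanges::end(g))
        } else {
            g5 <- max(GenomicRanges::end(g))
            g3 <- min(GenomicRanges::start(g))
        }
        tA <- .g2t(midx, id, g5)
        tB <- .g2t(midx, id, g3)
        fail <- function() { bad <<- c(bad, id); .naOrfRow(id, gene, "INVALID") }
        if (is.na(tA) || is.na(tB) || tB < tA) return(fail())
        if ((tB - tA + 1L) %% 3L != 0L) return(fail())
        if (substr(s, tA, tA + 2L) != "ATG") return(fail())
        if (tB + 3L <= n &&
            substr(s, tB + 1L, tB + 3L) %in% .STOP_CODONS) {
            end <- tB + 3L            # stop codon follows the CDS
        } else if (substr(s, tB - 2L, tB) %in% .STOP_CODONS) {
            end <- tB                 # stop codon included in the CDS
        } else return(fail())
        prot <- tryCatch(translateCds(substr(s, tA, end)),
                         error = function(e) NULL)
        if (is.null(prot)) return(fail())
        .orfRow(id, gene, list(
            start = tA, end = end, hasStop = TRUE,
            cdsLength = end - tA + 1L, protein = prot), "FROM_GTF")
    })
    if (length(bad) > 0L)
        warning("invalid CDS records for transcript(s): ",
                paste(bad, collapse = ", "))
    .finishOrfSet(rows, "REFERENCE")
}
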