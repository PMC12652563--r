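#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.STOP_CLASSES <- c("NORMAL", "PTC_dEJ", "NO_STOP", "NONCODING")

#' Transcript models over a genome
#'
#' A set of spliced transcript models: for every transcript an ordered exon
#' chain (5' to 3' in transcript orientation) on one chromosome and strand,
#' plus a per-transcript table linking transcripts to genes.
#'
#' @slot exons A \linkS4class{GRangesList}, one element per transcript,
#'   named by transcript id. Exons are stored in transcript (5' to 3')
#'   order: genomic starts strictly increase on \code{+} transcripts and
#'   strictly decrease on \code{-} transcripts.
#' @slot txData A \link[S4Vectors]{DataFrame} with one row per transcript
#'   (rownames = transcript ids) and columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{splicedLength}.
#'
#' @seealso [readTranscriptModels()], [splicedSequences()]
#' @export
setClass("TranscriptModels",
    representation(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptModels", function(object) {
    ex <- object@exons
    td <- object@txData
    if (length(ex) != nrow(td))
        return("exons and txData disagree on the number of transcripts")
    if (!identical(names(ex), rownames(td)))
        return("exons names and txData rownames differ")
    need <- c("gene_id", "chrom", "strand", "splicedLength")
    if (!all(need %in% colnames(td)))
        return(paste("txData lacks columns:",
                     paste(setdiff(need, colnames(td)), collapse = ", ")))
    nEx <- S4Vectors::elementNROWS(ex)
    if (any(nEx == 0L))
        return(sprintf("transcript '%s' has zero exons",
                       names(ex)[nEx == 0L][1L]))
    ## vectorized checks over the unlisted exon chains
    u <- unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(ex), nEx)
    str <- as.character(GenomicRanges::strand(u))
    chr <- as.character(GenomicRanges::seqnames(u))
    firstOf <- cumsum(nEx) - nEx + 1L
    if (!all(str %in% c("+", "-")) ||
        any(str != str[firstOf][grp]))
        return("a transcript has mixed or missing strand")
    if (any(chr != chr[firstOf][grp]))
        return("a transcript spans multiple chromosomes")
    if (!identical(str[firstOf], unname(td$strand)) ||
        !identical(chr[firstOf], unname(td$chrom)))
        return("txData strand/chrom disagree with exon chains")
    st <- GenomicRanges::start(u); en <- GenomicRanges::end(u)
    within <- which(grp[-1] == grp[-length(grp)])  # consecutive same-tx
    if (length(within) > 0L) {
        plus <- str[within] == "+"
        if (any(plus & st[within + 1L] <= en[within]) ||
            any(!plus & en[within + 1L] >= st[within]))
            return("exons out of 5'->3' order or overlapping")
    }
    lens <- as.integer(tapply(en - st + 1L, grp, sum))
    if (!identical(lens, as.integer(td$splicedLength)))
        return("splicedLength does not match exon widths")
    TRUE
})

#' ORF annotation set for a transcriptome
#'
#' One ORF call (or an explicit noncoding call) per transcript, produced
#' either per transcript independently (\code{REFERENCE} mode: the longest
#' ORF of each isoform, or CDS lifted from a GTF) or with the gene-level
#' authentic start codon propagated to all isoforms (\code{REVISED} mode).
#'
#' @slot mode \code{"REFERENCE"} or \code{"REVISED"}.
#' @slot orfs \link[S4Vectors]{DataFrame}, one row per transcript:
#'   \code{transcript_id}, \code{gene_id}, \code{start} (1-based position
#'   of the A of the ATG in transcript coordinates), \code{end} (1-based
#'   position of the last base of the stop codon, or of the last complete
#'   codon when stopless), \code{hasStop}, \code{cdsLength} (nt, stop
#'   included when present), \code{protein} (amino acids, stop excluded)
#'   and \code{status} (\code{OWN_LONGEST}, \code{FROM_GTF},
#'   \code{HARMONIZED}, \code{FALLBACK_OWN_LONGEST}, \code{NONCODING},
#'   \code{INVALID}).
#' @slot geneStarts \link[S4Vectors]{DataFrame} (REVISED mode), one row per
#'   gene: \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{genomicStart} (genomic position of the A of the authentic ATG)
#'   and \code{sourceTranscript} (the isoform whose longest ORF defined
#'   it). Empty in REFERENCE mode.
#'
#' @seealso [annotateReference()], [annotateRevised()], [nmdFeatures()]
#' @export
setClass("OrfSet",
    representation(mode = "character", orfs = "DataFrame",
                   geneStarts = "DataFrame"))

setValidity("OrfSet", function(object) {
    if (!object@mode %in% c("REFERENCE", "REVISED"))
        return("mode must be 'REFERENCE' or 'REVISED'")
    need <- c("transcript_id", "gene_id", "start", "end", "hasStop",
              "cdsLength", "protein", "status")
    if (!all(need %in% colnames(object@orfs)))
        return(paste("orfs lacks columns:",
                     paste(setdiff(need, colnames(object@orfs)),
                           collapse = ", ")))
    if (object@mode == "REFERENCE" && nrow(object@geneStarts) > 0L)
        return("REFERENCE mode carries no gene-start assignments")
    ok <- object@orfs$hasStop & !is.na(object@orfs$start)
    bad <- ok & (object@orfs$end - object@orfs$start + 1L) %% 3L != 0L
    if (any(bad, na.rm = TRUE))
        return("stop-terminated ORF span not a multiple of 3")
    TRUE
})

#' NMD enrichment report
#'
#' Cross-tabulation of differential-expression status (up / no change /
#' down) against stop-codon class (PTC_dEJ / normal), the up/down ratios,
#' and the NMD enrichment factor: the up/down ratio of PTC_dEJ transcripts
#' divided by the up/down ratio of normal-stop transcripts. A factor above
#' one indicates that transcripts bearing the EJC-model NMD trigger are
#' preferentially stabilised (up-regulated) after NMD inhibition.
#'
#' @slot counts 3x2 integer matrix, rows \code{UP}/\code{NO_CHANGE}/
#'   \code{DOWN}, columns \code{PTC_dEJ}/\code{NORMAL}.
#' @slot ratioPtc,ratioNormal up/down ratios per class (\code{Inf} when
#'   the down count is zero).
#' @slot enrichmentFactor \code{ratioPtc / ratioNormal}; \code{NA} when
#'   undefined (see \code{factorDefined}).
#' @slot factorDefined FALSE when any denominator (down counts, up-normal
#'   count) is zero.
#' @slot fisherP two-sided Fisher exact p on the 2x2 (up/down x
#'   PTC_dEJ/normal) table.
#' @slot nDropped number of DE transcripts absent from the feature table
#'   (or without a classifiable stop) and therefore excluded.
#'
#' @seealso [enrichmentReport()], [compareEnrichment()]
#' @export
setClass("EnrichmentReport",
    representation(counts = "matrix", ratioPtc = "numeric",
                   ratioNormal = "numeric", enrichmentFactor = "numeric",
                   factorDefined = "logical", fisherP = "numeric",
                   nDropped = "integer"))
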