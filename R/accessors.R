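#' Accessors for TranscriptModels and OrfSet
#'
#' @param x A \linkS4class{TranscriptModels} or \linkS4class{OrfSet}.
#' @return \code{txIds}: character vector of transcript ids.
#'   \code{geneIds}: character vector mapping each transcript to its gene.
#'   \code{exonsBy}: the underlying \linkS4class{GRangesList} of exon
#'   chains. \code{txData}: the per-transcript DataFrame.
#'   \code{orfTable}: the per-transcript ORF DataFrame.
#'   \code{geneStartTable}: the per-gene authentic-start DataFrame.
#'   \code{annotationMode}: \code{"REFERENCE"} or \code{"REVISED"}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
txIds <- function(x) {
    if (is(x, "TranscriptModels")) rownames(x@txData)
    else as.character(x@orfs$transcript_id)
}

#' @rdname accessors
#' @export
geneIds <- function(x) {
    if (is(x, "TranscriptModels"))
        structure(as.character(x@txData$gene_id), names = rownames(x@txData))
    else structure(as.character(x@orfs$gene_id),
                   names = as.character(x@orfs$transcript_id))
}

#' @rdname accessors
#' @export
exonsBy <- function(x) x@exons

#' @rdname accessors
#' @export
txData <- function(x) x@txData

#' @rdname accessors
#' @export
orfTable <- function(x) x@orfs

#' @rdname accessors
#' @export
geneStartTable <- function(x) x@geneStarts

#' @rdname accessors
#' @export
annotationMode <- function(x) x@mode

setMethod("show", "TranscriptModels", function(object) {
    td <- object@txData
    cat("TranscriptModels with", nrow(td), "transcripts in",
        length(unique(td$gene_id)), "genes\n")
    cat("  chromosomes:",
        paste(utils::head(unique(td$chrom), 5), collapse = ", "),
        if (length(unique(td$chrom)) > 5) "..." else "", "\n")
    cat("  spliced length range:", min(td$splicedLength), "-",
        max(td$splicedLength), "nt\n")
})

setMethod("show", "OrfSet", function(object) {
    o <- object@orfs
    cat("OrfSet (", object@mode, " mode) for ", nrow(o),
        " transcripts\n", sep = "")
    cat("  coding:", sum(!is.na(o$start)), " noncoding:",
        sum(is.na(o$start)), "\n")
    if (object@mode == "REVISED") {
        cat("  status:",
            paste(names(table(o$status)), table(o$status),
                  sep = "=", collapse = " "), "\n")
    }
})

setMethod("show", "EnrichmentReport", function(object) {
    cat("EnrichmentReport\n")
    print(object@counts)
    cat(sprintf("  up/down ratio PTC_dEJ: %.3g  normal: %.3g\n",
                object@ratioPtc, object@ratioNormal))
    if (object@factorDefined)
        cat(sprintf("  NMD enrichment factor: %.3g\n",
                    object@enrichmentFactor))
    else cat("  NMD enrichment factor: undefined (zero denominator)\n")
    cat(sprintf("  Fisher exact p (up/down x PTC/normal): %.3g\n",
                object@fisherP))
    if (object@nDropped > 0L)
        cat("  DE transcripts dropped (no classifiable feature row):",
            object@nDropped, "\n")
})
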