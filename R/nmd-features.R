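#' Classify a stop codon by the downstream exon-junction rule
#'
#' A stop codon is a premature termination codon of the EJC type
#' (\code{PTC_dEJ}) when at least one exon junction lies at least
#' \code{dejThreshold} (default 50) nucleotides downstream of it in the
#' spliced transcript; otherwise it is \code{NORMAL}. A junction at
#' coordinate \code{j} lies between transcript bases \code{j} and
#' \code{j + 1}; \code{stopEnd} is the 1-based position of the last base
#' of the stop codon, so the distance to a downstream junction is
#' \code{j - stopEnd}. A junction exactly at \code{stopEnd} counts as
#' downstream with distance 0 (never PTC_dEJ at the default threshold).
#' Stopless ORFs are \code{NO_STOP}; absent ORFs \code{NONCODING};
#' neither enters NORMAL/PTC_dEJ tallies downstream.
#'
#' @param stopEnd 1-based transcript coordinate of the stop codon's last
#'   base (\code{NA} for a noncoding transcript).
#' @param junctions Integer vector of junction coordinates (see
#'   [exonJunctions()]).
#' @param hasStop Does the ORF end in a stop codon?
#' @param dejThreshold Minimum stop-to-junction distance (nt) for a
#'   PTC_dEJ call.
#' @return List: \code{stopClass}, \code{distStopToLastDej} (distance to
#'   the last downstream junction, \code{NA} when there is none),
#'   \code{nDej} (downstream-junction count).
#' @examples
#' classifyStop(380, c(200, 450))$stopClass  # "PTC_dEJ" (distance 70)
#' classifyStop(401, c(200, 450))$stopClass  # "NORMAL"  (distance 49)
#' @export
classifyStop <- function(stopEnd, junctions, hasStop = TRUE,
                         dejThreshold = 50L) {
    if (is.na(stopEnd))
        return(list(stopClass = "NONCODING",
                    distStopToLastDej = NA_integer_, nDej = NA_integer_))
    if (!isTRUE(hasStop))
        return(list(stopClass = "NO_STOP",
                    distStopToLastDej = NA_integer_, nDej = NA_integer_))
    down <- junctions[junctions >= stopEnd]
    n <- length(down)
    d <- if (n > 0L) max(down) - stopEnd else NA_integer_
    cls <- if (n > 0L && d >= dejThreshold) "PTC_dEJ" else "NORMAL"
    list(stopClass = cls, distStopToLastDej = as.integer(d),
         nDej = as.integer(n))
}

#' UTR lengths implied by an ORF
#'
#' @param start,end 1-based ORF start (A of the ATG) and end (last base
#'   of the stop codon); \code{NA} for noncoding.
#' @param splicedLength Transcript length (nt).
#' @param hasStop Does the ORF end in a stop codon? A stopless ORF has a
#'   3' UTR of 0.
#' @return List with \code{utr5Length} (= start - 1) and
#'   \code{utr3Length} (= splicedLength - end).
#' @export
utrMetrics <- function(start, end, splicedLength, hasStop = TRUE) {
    if (is.na(start))
        return(list(utr5Length = NA_integer_, utr3Length = NA_integer_))
    list(utr5Length = as.integer(start - 1L),
         utr3Length = if (isTRUE(hasStop))
             as.integer(splicedLength - end) else 0L)
}

#' Per-transcript NMD feature records
#'
#' Combines stop-codon classification, UTR metrics, Kozak start-context
#' matching and the protein translation into one record per transcript —
#' the NMD feature table written as CSV by [writeFeatureTable()]. Rows
#' are ordered by gene id then transcript id.
#'
#' @param orfSet An \linkS4class{OrfSet}.
#' @param models The \linkS4class{TranscriptModels} the ORFs refer to.
#' @param genome Genome \link[Biostrings]{DNAStringSet}, or \code{NULL}
#'   when \code{seqs} is given.
#' @param seqs Optional precomputed spliced sequences.
#' @param dejThreshold Minimum stop-to-junction distance (nt) for
#'   PTC_dEJ.
#' @return data.frame with columns \code{transcript_id}, \code{gene_id},
#'   \code{stopClass}, \code{utr5Length}, \code{utr3Length},
#'   \code{distStopToLastDej}, \code{nDej}, \code{kozakMatch},
#'   \code{orfStart}, \code{orfEnd}, \code{protein}.
#' @export
nmdFeatures <- function(orfSet, models, genome = NULL, seqs = NULL,
                        dejThreshold = 50L) {
    if (is.null(seqs)) seqs <- splicedSequences(models, genome)
    sChar <- as.character(seqs)
    jx <- exonJunctions(models)
    o <- orfSet@orfs
    txLen <- as.integer(models@txData$splicedLength)
    ## hoist S4 DataFrame columns and positions out of the loop
    oTx <- as.character(o$transcript_id)
    oStart <- o$start; oEnd <- o$end; oHas <- o$hasStop
    pos <- match(oTx, rownames(models@txData))
    n <- nrow(o)
    stopClass <- character(n); dist <- nDej <- integer(n)
    utr5 <- utr3 <- integer(n); kz <- logical(n)
    for (i in seq_len(n)) {
        k <- pos[i]
        cl <- classifyStop(oEnd[i], jx[[k]], oHas[i], dejThreshold)
        um <- utrMetrics(oStart[i], oEnd[i], txLen[[k]], oHas[i])
        stopClass[i] <- cl$stopClass
        dist[i] <- cl$distStopToLastDej
        nDej[i] <- cl$nDej
        utr5[i] <- um$utr5Length
        utr3[i] <- um$utr3Length
        kz[i] <- if (is.na(oStart[i])) NA
                 else kozakMatch(sChar[[k]], oStart[i])$match
    }
    out <- data.frame(transcript_id = oTx,
                      gene_id = as.character(o$gene_id),
                      stopClass = stopClass,
                      utr5Length = utr5, utr3Length = utr3,
                      distStopToLastDej = dist, nDej = nDej,
                      kozakMatch = kz, orfStart = oStart,
                      orfEnd = oEnd, protein = as.character(o$protein),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_id, out$transcript_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
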