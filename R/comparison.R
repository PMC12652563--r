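.classifiable <- function(features)
    features$transcript_id[features$stopClass %in% c("NORMAL", "PTC_dEJ")]

#' Like-for-like comparison universe of two annotations
#'
#' Transcript ids present in both feature tables with a classifiable
#' stop (\code{NORMAL} or \code{PTC_dEJ}) in both — mirroring the
#' filtering of the published annotation against the re-annotated one so
#' the two can be compared like for like.
#'
#' @param a,b Feature data.frames from [nmdFeatures()].
#' @return Character vector of transcript ids (sorted).
#' @export
intersectUniverse <- function(a, b)
    sort(intersect(.classifiable(a), .classifiable(b)))

#' Stop-class transition table between two annotations
#'
#' Cross-tabulates the stop class of every transcript in the
#' like-for-like universe under annotation \code{a} (rows) and
#' annotation \code{b} (columns) — e.g. Reference vs Revised.
#'
#' @inheritParams intersectUniverse
#' @return List: \code{counts}, a 2x2 matrix with dimnames
#'   \code{NORMAL}/\code{PTC_dEJ}, and \code{universe}, the ids compared.
#' @export
transitionTable <- function(a, b) {
    u <- intersectUniverse(a, b)
    ca <- factor(a$stopClass[match(u, a$transcript_id)],
                 levels = c("NORMAL", "PTC_dEJ"))
    cb <- factor(b$stopClass[match(u, b$transcript_id)],
                 levels = c("NORMAL", "PTC_dEJ"))
    list(counts = table(a = ca, b = cb), universe = u)
}

#' Transcripts whose ORF start changed between two annotations
#'
#' Ids in the like-for-like universe whose ORF start (transcript
#' coordinate) differs between the two feature tables — the set over
#' which Kozak-context rates are compared.
#'
#' @inheritParams intersectUniverse
#' @return Character vector of transcript ids.
#' @export
changedStartSet <- function(a, b) {
    u <- intersectUniverse(a, b)
    sa <- a$orfStart[match(u, a$transcript_id)]
    sb <- b$orfStart[match(u, b$transcript_id)]
    u[sa != sb]
}

#' Classify differential transcript expression calls
#'
#' A transcript is \code{UP} when its corrected p-value is below
#' \code{alpha} and its log2 fold change exceeds \code{lfcThreshold};
#' \code{DOWN} when the p-value is below \code{alpha} and the fold
#' change is below \code{-lfcThreshold}; otherwise \code{NO_CHANGE}.
#' All inequalities are strict.
#'
#' @param de data.frame with columns \code{transcript_id}, \code{qval},
#'   \code{log2fc}.
#' @param alpha Corrected p-value threshold (default 0.05).
#' @param lfcThreshold Absolute log2 fold-change threshold (default 1).
#' @return The input with a \code{status} column added.
#' @examples
#' classifyDe(data.frame(transcript_id = "t", qval = 0.01, log2fc = 2))
#' @export
classifyDe <- function(de, alpha = 0.05, lfcThreshold = 1) {
    need <- c("transcript_id", "qval", "log2fc")
    if (!all(need %in% colnames(de)))
        stop("DE table lacks column(s): ",
             paste(setdiff(need, colnames(de)), collapse = ", "))
    bad <- which(!is.finite(de$qval) | de$qval < 0 | de$qval > 1 |
                 !is.finite(de$log2fc))
    if (length(bad) > 0L)
        stop("malformed DE row(s): ", paste(utils::head(bad, 5),
                                            collapse = ", "))
    de$status <- ifelse(
        de$qval < alpha & de$log2fc > lfcThreshold, "UP",
        ifelse(de$qval < alpha & de$log2fc < -lfcThreshold, "DOWN",
               "NO_CHANGE"))
    de
}

#' Read a differential-expression table from CSV/TSV
#'
#' @param path CSV or TSV file with a header.
#' @param idCol,qvalCol,lfcCol Column names holding the transcript id,
#'   corrected p-value and log2 fold change.
#' @return data.frame with columns \code{transcript_id}, \code{qval},
#'   \code{log2fc}.
#' @export
readDeTable <- function(path, idCol = "transcript_id", qvalCol = "qval",
                        lfcCol = "log2fc") {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    x <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
    for (cl in c(idCol, qvalCol, lfcCol))
        if (!cl %in% colnames(x))
            stop("DE table lacks column '", cl, "'")
    data.frame(transcript_id = as.character(x[[idCol]]),
               qval = as.numeric(x[[qvalCol]]),
               log2fc = as.numeric(x[[lfcCol]]),
               stringsAsFactors = FALSE)
}

#' NMD enrichment analysis of a differential-expression table
#'
#' Cross-tabulates DE status (up / no change / down) against stop class
#' (PTC_dEJ / normal), computes the up/down ratio within each class, the
#' NMD enrichment factor (PTC_dEJ ratio over normal ratio) and a
#' two-sided Fisher exact p on the (up, down) x (PTC_dEJ, normal) table.
#' DE transcripts without a classifiable feature row are dropped and
#' counted in \code{nDropped}. The factor is flagged undefined when any
#' denominator (either down count, or the up-normal count) is zero; an
#' up-PTC count of zero simply gives a factor of 0.
#'
#' @param de data.frame from [classifyDe()] (must carry \code{status}).
#' @param features Feature data.frame from [nmdFeatures()].
#' @return An \linkS4class{EnrichmentReport}.
#' @export
enrichmentReport <- function(de, features) {
    if (!"status" %in% colnames(de))
        stop("'de' must carry a status column; run classifyDe() first")
    cls <- features$stopClass[match(de$transcript_id,
                                    features$transcript_id)]
    keep <- !is.na(cls) & cls %in% c("NORMAL", "PTC_dEJ")
    nDropped <- sum(!keep)
    st <- factor(de$status[keep], levels = c("UP", "NO_CHANGE", "DOWN"))
    cl <- factor(cls[keep], levels = c("PTC_dEJ", "NORMAL"))
    counts <- unclass(table(st, cl))
    names(dimnames(counts)) <- NULL
    upP <- counts["UP", "PTC_dEJ"]; downP <- counts["DOWN", "PTC_dEJ"]
    upN <- counts["UP", "NORMAL"]; downN <- counts["DOWN", "NORMAL"]
    ratioPtc <- if (downP > 0L) upP / downP else Inf
    ratioNormal <- if (downN > 0L) upN / downN else Inf
    defined <- downP > 0L && downN > 0L && upN > 0L
    factor <- if (defined) ratioPtc / ratioNormal else NA_real_
    fp <- if (sum(counts[c("UP", "DOWN"), ]) > 0L)
        stats::fisher.test(matrix(c(upP, downP, upN, downN), 2L))$p.value
    else NA_real_
    new("EnrichmentReport", counts = counts, ratioPtc = ratioPtc,
        ratioNormal = ratioNormal, enrichmentFactor = factor,
        factorDefined = defined, fisherP = fp,
        nDropped = as.integer(nDropped))
}

#' Compare the up/down PTC_dEJ split of two enrichment reports
#'
#' Two-sided Fisher exact test on the 2x2 table of (up, down) PTC_dEJ
#' counts from annotation \code{a} vs annotation \code{b} — the test
#' used to ask whether re-annotation changes the up/down balance of
#' EJC-rule NMD candidates.
#'
#' @param a,b \linkS4class{EnrichmentReport} objects.
#' @return List: \code{p.value}, \code{table} (the 2x2 used),
#'   \code{degenerate} (TRUE when a zero margin forced p = 1).
#' @export
compareEnrichment <- function(a, b) {
    tab <- rbind(a = c(up = a@counts["UP", "PTC_dEJ"],
                       down = a@counts["DOWN", "PTC_dEJ"]),
                 b = c(up = b@counts["UP", "PTC_dEJ"],
                       down = b@counts["DOWN", "PTC_dEJ"]))
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
        return(list(p.value = 1, table = tab, degenerate = TRUE))
    list(p.value = stats::fisher.test(tab)$p.value, table = tab,
         degenerate = FALSE)
}

#' Compare 3' UTR lengths of up-regulated transcripts between annotations
#'
#' For the up-regulated transcripts present in both feature tables,
#' summarises 3' UTR lengths under each annotation and runs a paired
#' two-sided Wilcoxon signed-rank test (the same transcripts are
#' measured under both annotations; set \code{paired = FALSE} for the
#' rank-sum variant).
#'
#' @param de data.frame from [classifyDe()].
#' @param a,b Feature data.frames from [nmdFeatures()].
#' @param paired Use the signed-rank (paired) test.
#' @return List: \code{meanA}, \code{meanB}, \code{medianA},
#'   \code{medianB}, \code{n}, \code{p.value} (NA when n < 2), or
#'   \code{NULL} when n = 0.
#' @export
utr3Comparison <- function(de, a, b, paired = TRUE) {
    up <- de$transcript_id[de$status == "UP"]
    ids <- intersect(up, intersectUniverse(a, b))
    ua <- a$utr3Length[match(ids, a$transcript_id)]
    ub <- b$utr3Length[match(ids, b$transcript_id)]
    keep <- !is.na(ua) & !is.na(ub)
    ua <- ua[keep]; ub <- ub[keep]
    n <- length(ua)
    if (n == 0L) return(NULL)
    p <- if (n >= 2L && (!paired || any(ua != ub)))
        suppressWarnings(stats::wilcox.test(ua, ub, paired = paired,
                                            exact = FALSE)$p.value)
    else if (n >= 2L && paired) 1  # all pairwise differences zero
    else NA_real_
    list(meanA = mean(ua), meanB = mean(ub),
         medianA = stats::median(ua), medianB = stats::median(ub),
         n = n, p.value = p)
}
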