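#' Match the Kozak consensus context around a start codon
#'
#' Tests the 8-nt window around a start codon against the Kozak pattern
#' RNNATGGV (R = A/G, V = A/C/G), aligned so the ATG is literal:
#' positions -3..-1 upstream of the A, then ATG, then +4 and +5. A match
#' requires the base at -3 to be A or G, the base at +4 to be G and the
#' base at +5 to be A, C or G. When fewer than 3 nt precede the ATG or
#' fewer than 2 follow the G, the context is incomplete and the result
#' is no match.
#'
#' @param seq Transcript sequence (character or
#'   \link[Biostrings]{DNAString}).
#' @param start 1-based transcript coordinate of the A of the ATG;
#'   \code{seq[start..start+2]} must read ATG.
#' @return List: \code{hasContext} (full 8-nt window available) and
#'   \code{match}.
#' @examples
#' kozakMatch("GCCATGGC", 4)$match  # TRUE
#' kozakMatch("TCCATGGC", 4)$match  # FALSE (T is not R)
#' @export
kozakMatch <- function(seq, start) {
    s <- toupper(as.character(seq))
    n <- nchar(s)
    if (is.na(start) || start < 1L || start + 2L > n ||
        substr(s, start, start + 2L) != "ATG")
        stop("'start' must point at an ATG within the sequence")
    hasContext <- start - 3L >= 1L && start + 4L <= n
    match <- hasContext &&
        substr(s, start - 3L, start - 3L) %in% c("A", "G") &&
        substr(s, start + 3L, start + 3L) == "G" &&
        substr(s, start + 4L, start + 4L) %in% c("A", "C", "G")
    list(hasContext = hasContext, match = match)
}

#' Kozak match rate over an annotation set
#'
#' Counts Kozak-consensus matches over the coding transcripts of an
#' \linkS4class{OrfSet} (optionally restricted to a subset, e.g. the
#' changed-start set from [changedStartSet()]).
#'
#' @param orfSet An \linkS4class{OrfSet}.
#' @param seqs Spliced sequences (\link[Biostrings]{DNAStringSet}).
#' @param ids Optional transcript ids to restrict to.
#' @return List: \code{matched}, \code{total}, \code{fraction}
#'   (\code{NA} when total is 0).
#' @export
kozakRate <- function(orfSet, seqs, ids = NULL) {
    o <- orfSet@orfs
    keep <- !is.na(o$start)
    if (!is.null(ids)) keep <- keep & o$transcript_id %in% ids
    o <- o[keep, , drop = FALSE]
    sChar <- as.character(seqs)
    pos <- match(o$transcript_id, names(seqs))
    total <- nrow(o)
    matched <- if (total == 0L) 0L else
        sum(vapply(seq_len(total), function(i)
            kozakMatch(sChar[[pos[i]]], o$start[i])$match,
            logical(1)))
    list(matched = as.integer(matched), total = as.integer(total),
         fraction = if (total > 0L) matched / total else NA_real_)
}
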