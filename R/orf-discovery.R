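#' Translate a coding sequence
#'
#' Standard-genetic-code translation of complete codons. A trailing stop
#' codon is dropped; an internal stop codon is an error (valid ORFs never
#' contain one); any codon containing N or another ambiguity letter
#' translates to \code{X}. Trailing bases short of a full codon are
#' ignored.
#'
#' @param cds A DNA string (character or \link[Biostrings]{DNAString}) of
#'   length >= 3.
#' @return Amino-acid string, stop excluded.
#' @examples
#' translateCds("ATGGAGGAGGAGTGA")  # "MEEE"
#' translateCds("ATGNNNTAA")        # "MX"
#' @export
translateCds <- function(cds) {
    s <- toupper(as.character(cds))
    n <- nchar(s)
    if (n < 3L) stop("coding sequence shorter than one codon")
    k <- n %/% 3L
    codons <- substring(s, 3L * seq_len(k) - 2L, 3L * seq_len(k))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    aa[is.na(aa)] <- "X"
    st <- which(aa == "*")
    if (length(st) > 0L) {
        if (any(st < k))
            stop("internal stop codon at codon ", st[st < k][1L],
                 " (nt ", 3L * st[st < k][1L] - 2L, ")")
        aa <- aa[-k]
    }
    paste(aa, collapse = "")
}

## First in-frame stop at or after codon starting at p; returns the ORF
## end (1-based last base) and whether a stop terminates it.
.scanOrfEnd <- function(stopsByFrame, p, n) {
    f <- (p - 1L) %% 3L + 1L
    q <- stopsByFrame[[f]]
    q <- q[q >= p + 3L]
    if (length(q) > 0L)
        list(end = q[1L] + 2L, hasStop = TRUE)
    else
        list(end = p - 1L + 3L * ((n - p + 1L) %/% 3L), hasStop = FALSE)
}

.stopPositionsByFrame <- function(s) {
    n <- nchar(s)
    m <- gregexpr("(?=TAA|TAG|TGA)", s, perl = TRUE)[[1L]]
    q <- if (m[1L] == -1L) integer(0) else as.integer(m)
    q <- q[q + 2L <= n]
    lapply(1:3, function(f) q[(q - 1L) %% 3L == f - 1L])
}

## ORF from a given ATG position (no length filter); s uppercase.
.orfFromStart <- function(s, p, stopsByFrame = NULL) {
    n <- nchar(s)
    if (is.null(stopsByFrame)) stopsByFrame <- .stopPositionsByFrame(s)
    e <- .scanOrfEnd(stopsByFrame, p, n)
    prot <- translateCds(substr(s, p, e$end))
    list(start = p, end = e$end, hasStop = e$hasStop,
         cdsLength = e$end - p + 1L, protein = prot,
         proteinLength = nchar(prot))
}

#' Enumerate candidate ORFs in a spliced transcript sequence
#'
#' One candidate per ATG occurrence on the sense strand, extended to the
#' first in-frame stop codon (TAA/TAG/TGA), or to the last complete codon
#' before the 3' end when no stop occurs (\code{hasStop = FALSE}).
#' Candidates encoding fewer than \code{minProteinLen} amino acids are
#' dropped. Codons containing N are never starts or stops and translate
#' to \code{X}.
#'
#' @param seq A DNA string (character, \link[Biostrings]{DNAString}, or
#'   one element of a DNAStringSet).
#' @param minProteinLen Minimum protein length in amino acids (>= 1).
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive; \code{end} is the last base of the stop codon when
#'   present), \code{hasStop}, \code{cdsLength}, \code{protein},
#'   \code{proteinLength}; zero rows when no candidate survives.
#' @examples
#' findOrfs("CCATGAAATGATAG")  # candidates at 3 ("MK") and 8 ("MI")
#' @export
findOrfs <- function(seq, minProteinLen = 1L) {
    stopifnot(minProteinLen >= 1L)
    s <- toupper(as.character(seq))
    n <- nchar(s)
    empty <- data.frame(start = integer(0), end = integer(0),
                        hasStop = logical(0), cdsLength = integer(0),
                        protein = character(0), proteinLength = integer(0),
                        stringsAsFactors = FALSE)
    if (n < 3L) return(empty)
    m <- gregexpr("(?=ATG)", s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(empty)
    starts <- as.integer(m)
    sbf <- .stopPositionsByFrame(s)
    ends <- integer(length(starts))
    hasStop <- logical(length(starts))
    fr <- (starts - 1L) %% 3L + 1L
    for (f in 1:3) {
        i <- which(fr == f)
        if (length(i) == 0L) next
        q <- sbf[[f]]
        ## first in-frame stop at or after start + 3
        j <- findInterval(starts[i] + 2L, q) + 1L
        hit <- j <= length(q)
        hasStop[i] <- hit
        ends[i[hit]] <- q[j[hit]] + 2L
        p0 <- starts[i[!hit]]
        ends[i[!hit]] <- p0 - 1L + 3L * ((n - p0 + 1L) %/% 3L)
    }
    prot <- vapply(seq_along(starts), function(k)
        translateCds(substr(s, starts[k], ends[k])), character(1))
    out <- data.frame(start = starts, end = ends, hasStop = hasStop,
                      cdsLength = ends - starts + 1L, protein = prot,
                      proteinLength = nchar(prot),
                      stringsAsFactors = FALSE)
    out <- out[out$proteinLength >= minProteinLen, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' The longest ORF of a transcript
#'
#' The candidate from [findOrfs()] maximizing protein length. Ties are
#' broken in favour of stop-terminated candidates, then the 5'-most
#' start.
#'
#' @inheritParams findOrfs
#' @return One-row data.frame as in [findOrfs()], or \code{NULL} when no
#'   candidate survives the length filter.
#' @examples
#' longestOrf("AAAATGTGATTTATGGAGGAGTGATTT")$protein  # "MEE"
#' @export
longestOrf <- function(seq, minProteinLen = 1L) {
    cand <- findOrfs(seq, minProteinLen)
    if (nrow(cand) == 0L) return(NULL)
    o <- order(-cand$proteinLength, !cand$hasStop, cand$start)
    cand[o[1L], , drop = FALSE]
}
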