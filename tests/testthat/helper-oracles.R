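## Independent oracles and tiny fixture builders used across the suite.
## Everything here is deliberately written as naive, loop-based code that
## shares no path with the package implementation.

## --- brute-force ORF scanning ------------------------------------------

bruteTranslate <- function(cds) {
    code <- Biostrings::GENETIC_CODE
    n <- nchar(cds)
    aa <- character(0)
    for (q in seq(1L, n - 2L, by = 3L)) {
        cod <- substr(cds, q, q + 2L)
        a <- code[[cod]]
        if (is.null(a) || is.na(a)) a <- "X"
        aa <- c(aa, a)
    }
    if (length(aa) > 0L && aa[length(aa)] == "*")
        aa <- aa[-length(aa)]
    paste(aa, collapse = "")
}

## every ATG, stepped codon by codon to the first stop / sequence end
bruteOrfs <- function(s, minLen = 1L) {
    s <- toupper(s)
    n <- nchar(s)
    out <- list()
    if (n < 3L) return(out)
    for (p in 1:(n - 2L)) {
        if (substr(s, p, p + 2L) != "ATG") next
        q <- p
        end <- NA_integer_
        has <- FALSE
        while (q + 2L <= n) {
            cod <- substr(s, q, q + 2L)
            if (q > p && cod %in% c("TAA", "TAG", "TGA")) {
                end <- q + 2L; has <- TRUE; break
            }
            q <- q + 3L
        }
        if (!has) end <- p - 1L + 3L * ((n - p + 1L) %/% 3L)
        prot <- bruteTranslate(substr(s, p, end))
        if (nchar(prot) >= minLen)
            out[[length(out) + 1L]] <-
                list(start = p, end = end, hasStop = has, protein = prot)
    }
    out
}

bruteLongestOrf <- function(s, minLen = 1L) {
    cand <- bruteOrfs(s, minLen)
    if (length(cand) == 0L) return(NULL)
    best <- NULL
    for (c in cand) {
        if (is.null(best)) { best <- c; next }
        lb <- nchar(best$protein); lc <- nchar(c$protein)
        if (lc > lb ||
            (lc == lb && c$hasStop && !best$hasStop) ||
            (lc == lb && c$hasStop == best$hasStop &&
             c$start < best$start))
            best <- c
    }
    best
}

## --- brute-force gene-level harmonization ------------------------------

## exon table (from a TranscriptModels) -> vector: transcript coordinate
## index -> genomic position, built by naive enumeration
bruteTxToGenomeMap <- function(models, txId) {
    g <- exonsBy(models)[[txId]]
    st <- GenomicRanges::start(g); en <- GenomicRanges::end(g)
    strand <- as.character(GenomicRanges::strand(g))[1L]
    gmap <- integer(0)
    for (i in seq_along(st)) {
        gmap <- c(gmap, if (strand == "+") st[i]:en[i] else en[i]:st[i])
    }
    gmap
}

## re-derive the Revised annotation per gene by full enumeration
bruteRevised <- function(models, seqs, minLen = 30L) {
    td <- txData(models)
    res <- list()
    for (gene in unique(td$gene_id)) {
        ids <- rownames(td)[td$gene_id == gene]
        strand <- td[ids[1L], "strand"]
        best <- NULL; bestG <- NA_integer_; bestTx <- NA_character_
        for (id in ids) {
            lo <- bruteLongestOrf(as.character(seqs[[id]]), minLen)
            if (is.null(lo)) next
            gpos <- bruteTxToGenomeMap(models, id)[lo$start]
            better <- is.null(best) ||
                nchar(lo$protein) > nchar(best$protein) ||
                (nchar(lo$protein) == nchar(best$protein) &&
                 (if (strand == "+") gpos < bestG else gpos > bestG)) ||
                (nchar(lo$protein) == nchar(best$protein) &&
                 gpos == bestG && id < bestTx)
            if (better) { best <- lo; bestG <- gpos; bestTx <- id }
        }
        for (id in ids) {
            s <- as.character(seqs[[id]])
            gmap <- bruteTxToGenomeMap(models, id)
            tpos <- if (is.na(bestG)) NA_integer_
                    else { w <- which(gmap == bestG)
                           if (length(w)) w[1L] else NA_integer_ }
            if (!is.na(tpos) && tpos + 2L <= nchar(s) &&
                substr(s, tpos, tpos + 2L) == "ATG") {
                ## re-scan from the authentic start, no length filter
                q <- tpos; end <- NA_integer_; has <- FALSE
                while (q + 2L <= nchar(s)) {
                    cod <- substr(s, q, q + 2L)
                    if (q > tpos && cod %in% c("TAA", "TAG", "TGA")) {
                        end <- q + 2L; has <- TRUE; break
                    }
                    q <- q + 3L
                }
                if (!has) end <- tpos - 1L +
                    3L * ((nchar(s) - tpos + 1L) %/% 3L)
                res[[id]] <- list(start = tpos, end = end,
                                  status = "HARMONIZED")
            } else {
                lo <- bruteLongestOrf(s, minLen)
                res[[id]] <- if (is.null(lo))
                    list(start = NA_integer_, end = NA_integer_,
                         status = "NONCODING")
                else list(start = lo$start, end = lo$end,
                          status = "FALLBACK_OWN_LONGEST")
            }
        }
    }
    res
}

## --- Kozak regular-expression oracle -----------------------------------

kozakOracle <- function(s, start) {
    if (start - 3L < 1L || start + 4L > nchar(s)) return(FALSE)
    win <- substr(s, start - 3L, start + 4L)
    grepl("^[AG][ACGTN]{2}ATGG[ACG]$", win)
}

## --- two-sided Fisher p by hypergeometric enumeration -------------------

fisherOracle <- function(a, b, c, d) {
    ## table rbind(c(a, b), c(c, d)); enumerate all tables with the same
    ## margins and sum the probabilities not exceeding the observed one
    m <- a + b; n2 <- c + d; k <- a + c
    lo <- max(0L, k - n2); hi <- min(k, m)
    x <- lo:hi
    dens <- stats::dhyper(x, m, n2, k)
    dobs <- stats::dhyper(a, m, n2, k)
    sum(dens[dens <= dobs * (1 + 1e-7)])
}

## --- tiny handwritten fixtures ------------------------------------------

## the two-isoform gene: t1 and t2 share the first exon (with the
## authentic ATG at genomic position 4), t2 uses a different downstream
## exon whose own longest ORF starts at an internal ATG
writeMicroGene <- function(dir) {
    fa <- file.path(dir, "micro.fa")
    gtf <- file.path(dir, "micro.gtf")
    writeLines(c(">chr1",
        "AAAATGCCCCGAGGAGGAGTGATTTCCCCTGATTTATGGAGGAGTGATTT"), fa)
    at <- function(tx) sprintf('gene_id "g"; transcript_id "%s";', tx)
    writeLines(c(
        sprintf("chr1\tx\texon\t1\t6\t.\t+\t.\t%s", at("t1")),
        sprintf("chr1\tx\texon\t11\t25\t.\t+\t.\t%s", at("t1")),
        sprintf("chr1\tx\texon\t1\t6\t.\t+\t.\t%s", at("t2")),
        sprintf("chr1\tx\texon\t30\t50\t.\t+\t.\t%s", at("t2"))), gtf)
    list(fa = fa, gtf = gtf)
}

## random multi-exon transcript over a random genome; returns models+seqs
randomSeq <- function(n, letters = c("A", "C", "G", "T"))
    paste(sample(letters, n, replace = TRUE), collapse = "")

makeFeatureDf <- function(ids, stopClass, orfStart = NULL,
                          utr3 = NULL) {
    data.frame(transcript_id = ids, gene_id = ids,
               stopClass = stopClass,
               utr5Length = 0L,
               utr3Length = if (is.null(utr3)) 0L else utr3,
               distStopToLastDej = NA_integer_, nDej = 0L,
               kozakMatch = FALSE,
               orfStart = if (is.null(orfStart)) 1L else orfStart,
               orfEnd = 9L, protein = "M", stringsAsFactors = FALSE)
}
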