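#' Read a genome FASTA
#'
#' Reads a (multi-)FASTA into a named \link[Biostrings]{DNAStringSet}.
#' Record names are truncated at the first whitespace and sequences are
#' uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "acgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    x <- Biostrings::readDNAStringSet(path)
    nm <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(nm))
        stop("duplicate FASTA record name: ",
             nm[duplicated(nm)][1L])
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
    names(x) <- nm
    x
}

## Normalize an rtracklayer import of GTF/GFF3 exon records into
## (transcript_id, gene_id) columns.  GTF carries both attributes; GFF3
## from gffread-style conversions may carry Parent/ID instead.
.exonAttributes <- function(gr) {
    mc <- S4Vectors::mcols(gr)
    tx <- if ("transcript_id" %in% colnames(mc)) mc$transcript_id else NULL
    if (is.null(tx) && "Parent" %in% colnames(mc)) {
        p <- mc$Parent
        tx <- if (is(p, "List")) {
            vapply(p, function(v)
                if (length(v)) as.character(v[1L]) else NA_character_,
                character(1))
        } else as.character(p)
        tx <- sub("^transcript:", "", tx)
    }
    gene <- if ("gene_id" %in% colnames(mc)) mc$gene_id else NULL
    list(transcript_id = tx, gene_id = gene)
}

#' Read transcript models from a GTF/GFF annotation
#'
#' Imports exon features (via \code{rtracklayer}) and assembles one exon
#' chain per transcript, ordered 5' to 3' in transcript orientation.
#' Accepts both GTF (\code{key "value";}) and GFF3 (\code{key=value})
#' attribute dialects; in GFF3 input lacking \code{transcript_id} the
#' exon \code{Parent} is used as transcript id and genes are resolved
#' through the parent transcript features.
#'
#' @param path Path to a GTF or GFF3 file with exon features carrying
#'   transcript and gene identifiers.
#' @return A \linkS4class{TranscriptModels} object.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tx\texon\t101\t200\t.\t+\t.",
#'   'gene_id "g1"; transcript_id "g1.1";'), gtf)
#' readTranscriptModels(gtf)
#' @export
readTranscriptModels <- function(path) {
    if (!file.exists(path))
        stop("annotation file not found: ", path)
    fmt <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
        "gff3" else "gtf"
    gr <- rtracklayer::import(path, format = fmt)
    ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
    if (length(ex) == 0L)
        stop("no exon features found in ", path)
    at <- .exonAttributes(ex)
    if (is.null(at$transcript_id) || anyNA(at$transcript_id))
        stop("exon record without a transcript_id attribute in ", path,
             " (first offending record index: ",
             if (is.null(at$transcript_id)) 1L
             else which(is.na(at$transcript_id))[1L], ")")
    gene <- at$gene_id
    if (is.null(gene) || anyNA(gene)) {
        ## GFF3: map exon -> parent transcript -> its Parent gene
        txf <- gr[S4Vectors::mcols(gr)$type %in%
                  c("transcript", "mRNA", "mrna")]
        mp <- .exonAttributes(txf)
        ids <- S4Vectors::mcols(txf)$ID
        if (!is.null(ids) && !is.null(mp$transcript_id)) {
            g2 <- structure(sub("^gene:", "", mp$transcript_id),
                            names = as.character(ids))
            gene <- g2[at$transcript_id]
        }
        if (is.null(gene) || anyNA(gene))
            stop("exon record without a gene_id attribute in ", path)
        gene <- unname(gene)
    }
    S4Vectors::mcols(ex) <- NULL
    ex$transcript_id <- as.character(at$transcript_id)
    ex$gene_id <- as.character(gene)
    .buildModels(ex)
}

## Assemble a TranscriptModels from a GRanges of exons with
## transcript_id/gene_id metadata columns.
.buildModels <- function(ex) {
    txid <- ex$transcript_id
    str <- as.character(GenomicRanges::strand(ex))
    if (!all(str %in% c("+", "-"))) {
        bad <- unique(txid[!str %in% c("+", "-")])
        stop("transcript '", bad[1L], "' has exons with missing strand")
    }
    ## sort genomically within transcript, flip minus chains to 5'->3'
    o <- order(txid, GenomicRanges::start(ex))
    ex <- ex[o]; txid <- txid[o]
    str <- as.character(GenomicRanges::strand(ex))
    chr <- as.character(GenomicRanges::seqnames(ex))
    grp <- match(txid, unique(txid))
    firstOf <- which(!duplicated(grp))
    if (any(str != str[firstOf][grp])) {
        bad <- unique(txid[str != str[firstOf][grp]])
        stop("transcript '", bad[1L], "' has exons on mixed strands")
    }
    if (any(chr != chr[firstOf][grp])) {
        bad <- unique(txid[chr != chr[firstOf][grp]])
        stop("transcript '", bad[1L],
             "' has exons on multiple chromosomes")
    }
    within <- which(grp[-1] == grp[-length(grp)])
    if (length(within) > 0L &&
        any(GenomicRanges::start(ex)[within + 1L] <=
            GenomicRanges::end(ex)[within])) {
        i <- within[GenomicRanges::start(ex)[within + 1L] <=
                    GenomicRanges::end(ex)[within]][1L]
        stop("transcript '", txid[i], "' has overlapping exons")
    }
    gene <- ex$gene_id[firstOf]
    S4Vectors::mcols(ex) <- NULL
    exl <- S4Vectors::split(ex, factor(txid, levels = unique(txid)))
    exl <- S4Vectors::revElements(exl, str[firstOf] == "-")
    len <- as.integer(sum(GenomicRanges::width(exl)))
    td <- S4Vectors::DataFrame(gene_id = gene, chrom = chr[firstOf],
                               strand = str[firstOf],
                               splicedLength = len,
                               row.names = names(exl))
    ## sort transcripts for a deterministic container order
    o2 <- order(td$gene_id, rownames(td))
    new("TranscriptModels", exons = exl[o2], txData = td[o2, ])
}

#' Exon-junction coordinates of each transcript
#'
#' A junction at coordinate \code{j} lies between transcript bases
#' \code{j} and \code{j + 1} (1-based); \code{j} equals the cumulative
#' length of the preceding exons. Single-exon transcripts have no
#' junctions.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @return Named list of integer vectors, one per transcript.
#' @export
exonJunctions <- function(models) {
    lapply(as.list(GenomicRanges::width(models@exons)), function(w) {
        if (length(w) < 2L) integer(0)
        else cumsum(w)[-length(w)]
    })
}

#' Extract spliced transcript sequences
#'
#' Concatenates exon sequences in transcript order; on the minus strand
#' each exon is reverse-complemented so the result reads 5' to 3'.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param genome A named \link[Biostrings]{DNAStringSet} (see
#'   [readGenome()]).
#' @return A named \link[Biostrings]{DNAStringSet}, one sequence per
#'   transcript.
#' @export
splicedSequences <- function(models, genome) {
    td <- models@txData
    if (!all(td$chrom %in% names(genome))) {
        i <- which(!td$chrom %in% names(genome))[1L]
        stop("chromosome '", td$chrom[i], "' of transcript '",
             rownames(td)[i], "' not in genome")
    }
    nEx <- S4Vectors::elementNROWS(models@exons)
    u <- unlist(models@exons, use.names = FALSE)
    txOf <- rep(seq_len(nrow(td)), nEx)
    pieces <- character(length(u))
    for (chr in unique(td$chrom)) {
        idx <- which(td$chrom[txOf] == chr)
        cl <- length(genome[[chr]])
        st <- GenomicRanges::start(u)[idx]
        en <- GenomicRanges::end(u)[idx]
        if (any(st < 1L) || any(en > cl))
            stop("exon out of chromosome bounds for transcript '",
                 rownames(td)[txOf[idx][st < 1L | en > cl]][1L], "'")
        pieces[idx] <- as.character(Biostrings::extractAt(
            genome[[chr]], IRanges::IRanges(st, en)))
    }
    minus <- td$strand[txOf] == "-"
    if (any(minus))
        pieces[minus] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(pieces[minus])))
    ## exons are stored 5'->3', so concatenation in stored order splices
    out <- vapply(split(pieces, factor(txOf, levels = seq_len(nrow(td)))),
                  paste, character(1), collapse = "")
    res <- Biostrings::DNAStringSet(unname(out))
    names(res) <- rownames(td)
    res
}

.txExonFrame <- function(models, txId) {
    g <- models@exons[[txId]]
    if (is.null(g)) stop("unknown transcript: ", txId)
    w <- GenomicRanges::width(g)
    cum <- cumsum(w)
    list(g = g, w = w, cum = cum, cumBefore = c(0L, cum[-length(cum)]),
         strand = as.character(GenomicRanges::strand(g))[1L])
}

#' Map genomic positions into transcript coordinates
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param txId A transcript id present in \code{models}.
#' @param gpos Vector of genomic positions (1-based).
#' @param tpos Vector of transcript coordinates (1-based).
#' @return \code{genomicToTranscript}: integer vector of 1-based
#'   transcript coordinates, \code{NA} where the genomic position is not
#'   exonic in the transcript. \code{transcriptToGenomic}: integer vector
#'   of genomic positions; out-of-range \code{tpos} is an error.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(sprintf("chr1\tx\texon\t%d\t%d\t.\t+\t.\t%s", c(101, 201),
#'   c(150, 250), 'gene_id "g"; transcript_id "t";'), gtf)
#' m <- readTranscriptModels(gtf)
#' genomicToTranscript(m, "t", 201)  # 51
#' transcriptToGenomic(m, "t", 51)   # 201
#' @export
genomicToTranscript <- function(models, txId, gpos) {
    f <- .txExonFrame(models, txId)
    st <- GenomicRanges::start(f$g); en <- GenomicRanges::end(f$g)
    vapply(gpos, function(p) {
        i <- which(st <= p & p <= en)
        if (length(i) == 0L) return(NA_integer_)
        i <- i[1L]
        if (f$strand == "+") f$cumBefore[i] + (p - st[i] + 1L)
        else f$cumBefore[i] + (en[i] - p + 1L)
    }, integer(1))
}

#' @rdname genomicToTranscript
#' @export
transcriptToGenomic <- function(models, txId, tpos) {
    f <- .txExonFrame(models, txId)
    n <- f$cum[length(f$cum)]
    if (any(tpos < 1L | tpos > n))
        stop("transcript coordinate out of range for '", txId, "'")
    st <- GenomicRanges::start(f$g); en <- GenomicRanges::end(f$g)
    i <- findInterval(tpos - 1L, f$cum) + 1L
    off <- tpos - f$cumBefore[i]
    ifelse(f$strand == "+", st[i] + off - 1L, en[i] - off + 1L)
}

## CDS pieces (genomic) for one transcript given a transcript-coordinate
## span [a, b]; returns data.frame(start, end, frame) in 5'->3' order.
.cdsPieces <- function(models, txId, a, b) {
    f <- .txExonFrame(models, txId)
    st <- GenomicRanges::start(f$g); en <- GenomicRanges::end(f$g)
    out <- NULL
    cds_before <- 0L
    for (i in seq_along(st)) {
        lo <- max(a, f$cumBefore[i] + 1L)
        hi <- min(b, f$cum[i])
        if (lo > hi) next
        frame <- (3L - cds_before %% 3L) %% 3L
        if (f$strand == "+") {
            gs <- st[i] + (lo - f$cumBefore[i]) - 1L
            ge <- st[i] + (hi - f$cumBefore[i]) - 1L
        } else {
            gs <- en[i] - (hi - f$cumBefore[i]) + 1L
            ge <- en[i] - (lo - f$cumBefore[i]) + 1L
        }
        out <- rbind(out, data.frame(start = gs, end = ge, frame = frame))
        cds_before <- cds_before + (hi - lo + 1L)
    }
    out
}

.gtfAttr <- function(gene, tx)
    sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)

#' Write an annotation GTF with exon and CDS features
#'
#' Emits exon lines for every transcript and, for transcripts with an
#' ORF, CDS lines covering the ORF minus its stop codon (split across
#' exons, 1-based inclusive, with the frame column filled in). Record
#' order is deterministic: gene id, then transcript id, then transcript
#' 5' to 3' order.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param orfSet An \linkS4class{OrfSet} for the same transcripts, or
#'   \code{NULL} to write exon lines only.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationGtf <- function(models, orfSet = NULL, path) {
    td <- models@txData
    orfs <- if (is.null(orfSet)) NULL else orfSet@orfs
    if (!is.null(orfs) &&
        !all(orfs$transcript_id %in% rownames(td)))
        stop("ORF for unknown transcript: ",
             setdiff(orfs$transcript_id, rownames(td))[1L])
    o <- order(td$gene_id, rownames(td))
    lines <- character(0)
    for (i in o) {
        id <- rownames(td)[i]
        at <- .gtfAttr(td$gene_id[i], id)
        g <- models@exons[[i]]
        lines <- c(lines, sprintf("%s\tOrfHarmony\texon\t%d\t%d\t.\t%s\t.\t%s",
            td$chrom[i], GenomicRanges::start(g), GenomicRanges::end(g),
            td$strand[i], at))
        if (!is.null(orfs)) {
            r <- orfs[orfs$transcript_id == id, , drop = FALSE]
            if (nrow(r) == 1L && !is.na(r$start)) {
                b <- if (isTRUE(r$hasStop)) r$end - 3L else r$end
                if (b >= r$start) {
                    p <- .cdsPieces(models, id, r$start, b)
                    lines <- c(lines, sprintf(
                        "%s\tOrfHarmony\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                        td$chrom[i], p$start, p$end, td$strand[i],
                        p$frame, at))
                }
            }
        }
    }
    writeLines(lines, path)
    invisible(path)
}

.classOut <- c(NORMAL = "Normal", PTC_dEJ = "PTC_dEJ",
               NO_STOP = "No_stop", NONCODING = "Non_coding")

#' Write / read the per-transcript NMD feature table (CSV)
#'
#' One row per transcript with the NMD-relevant features: stop class,
#' UTR lengths, distance from the stop codon to the last downstream exon
#' junction, downstream-junction count, Kozak context match, and the
#' protein sequence in the final \code{Translation} column.
#'
#' @param features A data.frame from [nmdFeatures()].
#' @param path CSV file path.
#' @return \code{writeFeatureTable}: \code{path} invisibly;
#'   \code{readFeatureTable}: the features data.frame.
#' @export
writeFeatureTable <- function(features, path) {
    out <- data.frame(
        Transcript_ID = features$transcript_id,
        Gene_ID = features$gene_id,
        Stop_Class = unname(.classOut[features$stopClass]),
        UTR5_Length = features$utr5Length,
        UTR3_Length = features$utr3Length,
        Dist_Stop_To_Last_dEJ = features$distStopToLastDej,
        N_Downstream_EJ = features$nDej,
        Kozak_Match = features$kozakMatch,
        Translation = features$protein,
        check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    x <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE,
                         colClasses = c(Translation = "character"))
    back <- structure(names(.classOut), names = unname(.classOut))
    data.frame(
        transcript_id = as.character(x$Transcript_ID),
        gene_id = as.character(x$Gene_ID),
        stopClass = unname(back[x$Stop_Class]),
        utr5Length = suppressWarnings(as.integer(x$UTR5_Length)),
        utr3Length = suppressWarnings(as.integer(x$UTR3_Length)),
        distStopToLastDej =
            suppressWarnings(as.integer(x$Dist_Stop_To_Last_dEJ)),
        nDej = suppressWarnings(as.integer(x$N_Downstream_EJ)),
        kozakMatch = as.logical(x$Kozak_Match),
        protein = as.character(x$Translation),
        stringsAsFactors = FALSE)
}
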