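#' Write reads (and state calls) as an annotated BAM
#'
#' Encodes single-molecule footprinting results in a BAM dialect designed
#' for direct inspection in genome viewers such as IGV: every called m6A
#' is a single-base insertion placed immediately before its adenine's
#' Watson-strand base pair (the inserted base is A for plus-strand m6A, T
#' for minus-strand m6A); when chromatin state tracks are supplied,
#' nucleosomal bases are written as mismatch runs (CIGAR \code{X}),
#' accessible bases as match runs (\code{=}) and ambiguous bases as
#' deletions (\code{D}). Without state tracks the aligned span is plain
#' \code{M}. The average read quality is stored in the \code{rq} float
#' tag. The output is coordinate-sorted and indexed.
#'
#' @param reads a \linkS4class{MethylReadSet}.
#' @param path output BAM path (".bam" appended if missing).
#' @param genome named \link[Biostrings]{DNAStringSet}; supplies the
#'   header contig lengths and the record sequences.
#' @param tracks optional \linkS4class{StateTrackSet} parallel to
#'   \code{reads} (same molecules in the same order).
#' @return the BAM path, invisibly.
#' @export
writeAnnotatedBam <- function(reads, path, genome, tracks = NULL) {
    if (!is.null(tracks) &&
        !identical(moleculeId(tracks), moleculeId(reads)))
        stop("tracks must be parallel to reads (same moleculeId order)")
    gr <- granges(reads)
    for (ch in unique(as.character(seqnames(gr)))) .checkChrom(genome, ch)
    sam <- tempfile(fileext = ".sam")
    con <- file(sam, "w")
    on.exit(close(con), add = TRUE)
    writeLines("@HD\tVN:1.6\tSO:unknown", con)
    for (ch in names(genome))
        writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, length(genome[[ch]])),
            con)
    n <- length(reads)
    recs <- character(n)
    for (i in seq_len(n)) {
        ch <- as.character(seqnames(gr))[i]
        st <- start(gr)[i]
        en <- end(gr)[i]
        L <- en - st + 1L
        letters <- strsplit(as.character(
            Biostrings::subseq(genome[[ch]], st, en)), "")[[1]]
        if (is.null(tracks)) {
            opv <- rep("M", L)
        } else {
            lab <- as.character(tracks@labels[[i]])
            opv <- c(A = "=", N = "X", X = "D")[lab]
        }
        o <- reads@m6aPos[[i]] - st + 1L
        ins <- logical(L)
        ins[o] <- TRUE
        tokcount <- ifelse(ins, 2L, 1L)
        basepos <- cumsum(tokcount)
        tokens <- character(sum(tokcount))
        tokens[basepos] <- opv
        tokens[basepos[ins] - 1L] <- "I"
        r <- rle(tokens)
        cig <- paste0(r$lengths, r$values, collapse = "")
        seqv <- character(sum(tokcount))
        seqv[basepos] <- ifelse(opv == "D", NA_character_, letters)
        seqv[basepos[ins] - 1L] <- letters[ins]
        seqstr <- paste(seqv[!is.na(seqv)], collapse = "")
        if (!nzchar(seqstr)) seqstr <- "*"
        recs[i] <- paste(moleculeId(reads)[i], 0L, ch, st, 60L, cig,
            "*", 0L, 0L, seqstr, "*",
            sprintf("rq:f:%g", readQuality(reads)[i]), sep = "\t")
    }
    writeLines(recs, con)
    close(con)
    on.exit()
    if (!grepl("\\.bam$", path)) path <- paste0(path, ".bam")
    dest <- sub("\\.bam$", "", path)
    Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    invisible(path)
}

#' Read the annotated BAM dialect
#'
#' Inverse of \code{\link{writeAnnotatedBam}}: recovers reads (m6A
#' positions and strands from the single-base insertions) and, when the
#' records carry \code{=}/\code{X}/\code{D} runs, the per-base state
#' tracks. Round-trips bit-exactly on coordinates, m6A sets and labels.
#'
#' @param path BAM path.
#' @param genome named \link[Biostrings]{DNAStringSet} used to derive
#'   adenine sets (and validate m6A placement).
#' @return list with elements \code{reads} (a
#'   \linkS4class{MethylReadSet}) and \code{tracks} (a
#'   \linkS4class{StateTrackSet}, or NULL when no record carries state
#'   annotations).
#' @export
readAnnotatedBam <- function(path, genome) {
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos", "cigar", "seq"), tag = "rq")
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    n <- length(b$qname)
    chrom <- as.character(b$rname)
    startv <- b$pos
    endv <- integer(n)
    m6aPos <- vector("list", n)
    m6aStr <- vector("list", n)
    labels <- vector("list", n)
    anyState <- FALSE
    for (i in seq_len(n)) {
        ops <- .parseCigar(b$cigar[i], path)
        refpos <- startv[i]
        qpos <- 1L
        sq <- as.character(b$seq[[i]])
        pos <- integer(0)
        strn <- character(0)
        lab <- character(0)
        hasState <- FALSE
        hasM <- FALSE
        for (j in seq_len(nrow(ops))) {
            len <- ops$len[j]
            op <- ops$op[j]
            if (op == "I") {
                if (len != 1L)
                    stop("annotated-BAM dialect error in ", path,
                        ": insertion of length ", len,
                        " (m6A must be a single-base insertion)")
                base <- substr(sq, qpos, qpos)
                pos <- c(pos, refpos)
                strn <- c(strn, if (base == "T") "-" else "+")
                qpos <- qpos + 1L
            } else if (op %in% c("=", "X", "D", "M")) {
                if (op == "M") hasM <- TRUE else hasState <- TRUE
                lab <- c(lab, rep(c(`=` = "A", X = "N", D = "X",
                    M = "X")[[op]], len))
                refpos <- refpos + len
                if (op != "D") qpos <- qpos + len
            } else {
                stop("annotated-BAM dialect error in ", path,
                    ": unsupported CIGAR op '", op, "'")
            }
        }
        if (hasM && hasState)
            stop("annotated-BAM dialect error in ", path,
                ": record ", b$qname[i], " mixes M with =/X/D runs")
        endv[i] <- refpos - 1L
        m6aPos[[i]] <- pos
        m6aStr[[i]] <- strn
        labels[[i]] <- if (hasState) lab else NULL
        if (hasState) anyState <- TRUE
    }
    reads <- MethylReadSet(b$qname, chrom, startv, endv,
        ifelse(is.na(b$tag$rq), 99, b$tag$rq), m6aPos, m6aStr, genome)
    tracks <- NULL
    if (anyState) {
        has <- !vapply(labels, is.null, logical(1))
        tracks <- StateTrackSet(granges(reads)[has],
            moleculeId(reads)[has], labels[has])
    }
    list(reads = reads, tracks = tracks)
}

.parseCigar <- function(cig, path) {
    if (is.na(cig) || cig == "*")
        stop("annotated-BAM dialect error in ", path, ": missing CIGAR")
    m <- gregexpr("\\d+[A-Z=]", cig)[[1]]
    tok <- regmatches(cig, gregexpr("\\d+[A-Z=]", cig))[[1]]
    if (!length(tok) || sum(nchar(tok)) != nchar(cig))
        stop("annotated-BAM dialect error in ", path,
            ": unparseable CIGAR '", cig, "'")
    data.frame(len = as.integer(sub("[A-Z=]$", "", tok)),
        op = sub("^\\d+", "", tok))
}

#' Construct a StateTrackSet
#'
#' @param ranges GRanges of read spans.
#' @param moleculeId character vector of molecule ids.
#' @param labels list of per-base label vectors (or Rle) over
#'   \code{"A"}/\code{"N"}/\code{"X"}.
#' @param pAdjAccessible,pAdjNucleosomal optional lists of per-base
#'   adjusted p-values (NA where no complete window is centered).
#' @return a \linkS4class{StateTrackSet}.
#' @export
StateTrackSet <- function(ranges, moleculeId, labels,
        pAdjAccessible = NULL, pAdjNucleosomal = NULL) {
    mcols(ranges) <- DataFrame(moleculeId = as.character(moleculeId))
    rl <- RleList(lapply(labels, function(x)
        if (is(x, "Rle")) x else S4Vectors::Rle(x)), compress = FALSE)
    new("StateTrackSet", ranges = ranges, labels = rl,
        pAdjAccessible = pAdjAccessible, pAdjNucleosomal = pAdjNucleosomal)
}

#' @describeIn StateTrackSet-class number of tracks
#' @export
setMethod("length", "StateTrackSet", function(x) length(x@ranges))

#' @describeIn StateTrackSet-class molecule identifiers
#' @export
setMethod("moleculeId", "StateTrackSet",
    function(x) mcols(x@ranges)$moleculeId)

#' @describeIn StateTrackSet-class per-base labels (RleList over
#'   \code{"A"}/\code{"N"}/\code{"X"})
#' @export
setMethod("stateLabels", "StateTrackSet", function(x) x@labels)

#' @describeIn StateTrackSet-class read spans as GRanges
#' @export
setMethod("granges", "StateTrackSet", function(x, ...) x@ranges)

#' @describeIn StateTrackSet-class subset tracks
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "StateTrackSet", function(x, i, j, ..., drop = TRUE) {
    ii <- seq_along(x@labels)[i]
    initialize(x, ranges = x@ranges[ii], labels = x@labels[ii],
        pAdjAccessible = if (is.null(x@pAdjAccessible)) NULL else
            x@pAdjAccessible[ii],
        pAdjNucleosomal = if (is.null(x@pAdjNucleosomal)) NULL else
            x@pAdjNucleosomal[ii])
})

setMethod("show", "StateTrackSet", function(object) {
    n <- length(object)
    cat("StateTrackSet with", n, "tracks\n")
    if (n) {
        tot <- sum(as.numeric(width(object@ranges)))
        cnt <- c(A = 0, N = 0, X = 0)
        for (i in seq_len(n)) {
            r <- object@labels[[i]]
            tv <- tapply(S4Vectors::runLength(r), S4Vectors::runValue(r),
                sum)
            cnt[names(tv)] <- cnt[names(tv)] + tv
        }
        cat(sprintf(
            "  accessible %.1f%%, nucleosomal %.1f%%, ambiguous %.1f%%\n",
            100 * cnt["A"] / tot, 100 * cnt["N"] / tot,
            100 * cnt["X"] / tot))
    }
})

#' Per-molecule state runs as BED
#'
#' Writes maximal runs of one state (default nucleosomal) as BED6
#' intervals named by molecule, one line per run.
#'
#' @param tracks a \linkS4class{StateTrackSet}.
#' @param path output BED path.
#' @param state which label to export: "N", "A" or "X".
#' @return the path, invisibly.
#' @export
writeStateBed <- function(tracks, path, state = "N") {
    rows <- vector("list", length(tracks))
    gr <- granges(tracks)
    for (i in seq_len(length(tracks))) {
        r <- tracks@labels[[i]]
        ends <- cumsum(S4Vectors::runLength(r))
        starts <- ends - S4Vectors::runLength(r) + 1L
        sel <- S4Vectors::runValue(r) == state
        if (!any(sel)) next
        rows[[i]] <- data.frame(
            chrom = as.character(seqnames(gr))[i],
            start = start(gr)[i] + starts[sel] - 2L,  # BED 0-based
            end = start(gr)[i] + ends[sel] - 1L,
            name = moleculeId(tracks)[i], score = 0L, strand = ".")
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(df))
        df <- data.frame(chrom = character(0), start = integer(0),
            end = integer(0), name = character(0), score = integer(0),
            strand = character(0))
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE,
        quote = FALSE)
    invisible(path)
}
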