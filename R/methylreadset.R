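#' Construct a MethylReadSet
#'
#' Builds the read container from per-molecule alignment spans and called
#' m6A positions, deriving adenine counts from the reference genome.
#' Every m6A must sit on an adenine of its strand: a Watson A for
#' plus-strand calls, a Watson T (adenine on the minus strand) for
#' minus-strand calls; violations are reported with the offending
#' position.
#'
#' @param moleculeId character vector of molecule identifiers.
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 1-based closed alignment span.
#' @param readQuality numeric vector, average per-base quality in
#'   [0, 100].
#' @param m6aPos IntegerList (or list) of 1-based Watson coordinates of
#'   called m6A per read.
#' @param m6aStrand CharacterList (or list) of "+"/"-" parallel to
#'   \code{m6aPos}.
#' @param genome a named \link[Biostrings]{DNAStringSet} reference.
#' @return a \linkS4class{MethylReadSet}.
#' @export
MethylReadSet <- function(moleculeId, chrom, start, end, readQuality,
        m6aPos, m6aStrand, genome) {
    n <- length(moleculeId)
    m6aPos <- IRanges::IntegerList(m6aPos)
    if (is(m6aStrand, "CharacterList") || (is.list(m6aStrand) &&
            (n == 0L || is.character(m6aStrand[[1]]) ||
             length(m6aStrand[[1]]) == 0L))) {
        m6aStrandCode <- IRanges::IntegerList(lapply(m6aStrand,
            function(s) ifelse(s == "-", 1L, 0L)))
    } else {
        m6aStrandCode <- IRanges::IntegerList(m6aStrand)
    }
    gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
    nA <- integer(n)
    for (i in seq_len(n)) {
        .checkChrom(genome, chrom[i])
        codes <- .watsonCodes(genome, chrom[i], start[i], end[i])
        nA[i] <- sum(.isAT(codes))
        p <- m6aPos[[i]]
        if (length(p)) {
            if (any(p < start[i] | p > end[i]))
                stop("read ", moleculeId[i],
                    ": m6A position outside alignment span")
            sc <- m6aStrandCode[[i]]
            b <- codes[p - start[i] + 1L]
            want <- ifelse(sc == 0L, .CODE_A, .CODE_T)
            bad <- which(b != want)
            if (length(bad))
                stop("read ", moleculeId[i], ": m6A at ", chrom[i], ":",
                    p[bad[1]],
                    " is not an adenine on the called strand")
        }
    }
    mcols(gr) <- DataFrame(moleculeId = as.character(moleculeId),
        readQuality = as.numeric(readQuality),
        nAdenine = nA, nM6A = lengths(m6aPos))
    new("MethylReadSet", ranges = gr, m6aPos = m6aPos,
        m6aStrand = m6aStrandCode)
}

#' @describeIn MethylReadSet-class number of reads
#' @param x a MethylReadSet
#' @export
setMethod("length", "MethylReadSet", function(x) length(x@ranges))

#' @describeIn MethylReadSet-class molecule identifiers
#' @export
setMethod("moleculeId", "MethylReadSet",
    function(x) mcols(x@ranges)$moleculeId)

#' @describeIn MethylReadSet-class average per-base quality scores
#' @export
setMethod("readQuality", "MethylReadSet",
    function(x) mcols(x@ranges)$readQuality)

#' @describeIn MethylReadSet-class m6A positions (IntegerList, Watson
#'   coordinates)
#' @export
setMethod("m6aPositions", "MethylReadSet", function(x) x@m6aPos)

#' @describeIn MethylReadSet-class average read methylation: called m6A
#'   over adenines on both strands; NA for reads without adenines
#' @export
setMethod("avgMethylation", "MethylReadSet", function(x) {
    nA <- mcols(x@ranges)$nAdenine
    ifelse(nA > 0L, mcols(x@ranges)$nM6A / nA, NA_real_)
})

#' @describeIn MethylReadSet-class alignment spans as GRanges
#' @export
setMethod("granges", "MethylReadSet", function(x, ...) x@ranges)

#' @describeIn MethylReadSet-class subset reads
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "MethylReadSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, ranges = x@ranges[i], m6aPos = x@m6aPos[i],
        m6aStrand = x@m6aStrand[i])
})

setMethod("show", "MethylReadSet", function(object) {
    n <- length(object)
    cat("MethylReadSet with", n, "reads\n")
    if (n) {
        m <- avgMethylation(object)
        cat(sprintf("  span: %d-%d bp; median avg methylation: %.3f\n",
            min(width(object@ranges)), max(width(object@ranges)),
            stats::median(m, na.rm = TRUE)))
    }
})

#' Quality-filter reads
#'
#' Retains reads whose average base quality reaches \code{minQuality}
#' (inclusive; the analysis default is 90) and that cover at least
#' \code{minAdenines} adenines, so that an average methylation is
#' defined. Order-preserving and idempotent.
#'
#' @param reads a \linkS4class{MethylReadSet}.
#' @param minQuality minimum average base quality score (default 90).
#' @param minAdenines minimum adenine count (default 1).
#' @return the filtered \linkS4class{MethylReadSet}.
#' @export
filterReads <- function(reads, minQuality = 90, minAdenines = 1L) {
    keep <- readQuality(reads) >= minQuality &
        mcols(reads@ranges)$nAdenine >= minAdenines
    reads[keep]
}

#' Inter-m6A distance histogram
#'
#' Distances between consecutive called m6A positions within each read
#' (Watson coordinates sorted, both strands pooled by default), counted
#' over all reads and normalised per million nucleotides sequenced.
#' Short distances arise from accessible DNA; on chromatin, a secondary
#' hump near the nucleosome footprint length reflects protection.
#'
#' @param reads a \linkS4class{MethylReadSet}.
#' @param perStrand if TRUE, distances are computed separately within
#'   each strand's m6A set instead of pooling.
#' @return data.frame with columns \code{distance} (bp), \code{count},
#'   and \code{perMillionNt} (count / (total read nucleotides / 1e6)).
#' @export
interM6ADistances <- function(reads, perStrand = FALSE) {
    totalNt <- sum(as.numeric(width(reads@ranges)))
    dists <- integer(0)
    for (i in seq_len(length(reads))) {
        p <- reads@m6aPos[[i]]
        if (perStrand) {
            sc <- reads@m6aStrand[[i]]
            for (s in c(0L, 1L)) {
                ps <- sort(p[sc == s])
                if (length(ps) >= 2L) dists <- c(dists, diff(ps))
            }
        } else {
            if (length(p) >= 2L) dists <- c(dists, diff(sort(p)))
        }
    }
    if (!length(dists))
        return(data.frame(distance = integer(0), count = integer(0),
            perMillionNt = numeric(0)))
    tab <- table(dists)
    data.frame(distance = as.integer(names(tab)),
        count = as.integer(tab),
        perMillionNt = as.integer(tab) / (totalNt / 1e6))
}

#' @importFrom GenomicRanges granges
#' @export
GenomicRanges::granges
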