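#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges IntegerList NumericList CharacterList RleList
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#'   strand
#' @importFrom Biostrings DNAStringSet DNAString
#' @importFrom data.table data.table := .N
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))

#' MethylReadSet: single-molecule m6A footprinting reads
#'
#' Container for per-molecule consensus reads from methyltransferase
#' (M.EcoGII) accessibility footprinting. Each read is one sequenced DNA
#' molecule with its alignment span, average base quality, and the set of
#' called m6A positions (strand-resolved). Adenine counts are derived from
#' the reference at construction time, so the average read methylation
#' (called m6A / adenines, both strands) is always available.
#'
#' Coordinates are 1-based closed (GRanges convention). m6A positions are
#' stored as the Watson-strand coordinate of the methylated base pair; the
#' strand slot records whether the adenine lies on the plus strand (a
#' Watson A) or the minus strand (a Watson T).
#'
#' @slot ranges GRanges, one range per molecule, with metadata columns
#'   \code{moleculeId}, \code{readQuality}, \code{nAdenine}, \code{nM6A}.
#' @slot m6aPos CompressedIntegerList of m6A positions per read (1-based
#'   Watson coordinates).
#' @slot m6aStrand CompressedIntegerList parallel to \code{m6aPos};
#'   0 = plus strand, 1 = minus strand.
#' @exportClass MethylReadSet
setClass("MethylReadSet",
    slots = c(
        ranges = "GRanges",
        m6aPos = "CompressedIntegerList",
        m6aStrand = "CompressedIntegerList"
    )
)

setValidity("MethylReadSet", function(object) {
    gr <- object@ranges
    msg <- character()
    need <- c("moleculeId", "readQuality", "nAdenine", "nM6A")
    miss <- setdiff(need, colnames(mcols(gr)))
    if (length(miss))
        msg <- c(msg, paste("missing mcols:", paste(miss, collapse = ", ")))
    if (length(object@m6aPos) != length(gr) ||
        length(object@m6aStrand) != length(gr))
        msg <- c(msg, "m6aPos/m6aStrand must have one element per read")
    if (!length(msg)) {
        np <- lengths(object@m6aPos)
        if (!all(np == lengths(object@m6aStrand)))
            msg <- c(msg, "m6aPos and m6aStrand elements differ in length")
        bad <- which(np > 0 &
            (min(object@m6aPos) < start(gr) | max(object@m6aPos) > end(gr)))
        if (length(bad))
            msg <- c(msg, paste("m6A positions outside read span for read",
                bad[1]))
        q <- mcols(gr)$readQuality
        if (any(q < 0 | q > 100, na.rm = TRUE))
            msg <- c(msg, "readQuality must lie in [0, 100]")
        if (any(mcols(gr)$nM6A > mcols(gr)$nAdenine))
            msg <- c(msg, "called m6A count exceeds adenine count")
    }
    if (length(msg)) msg else TRUE
})

#' StateTrackSet: per-base chromatin state calls
#'
#' One state track per molecule: a run-length encoded label per base pair
#' over the read span, with labels \code{"A"} (accessible), \code{"N"}
#' (nucleosomal) and \code{"X"} (ambiguous). Optionally carries the
#' per-base adjusted p-values of the two one-tailed window tests.
#'
#' @slot ranges GRanges, one range per molecule, with mcols
#'   \code{moleculeId}.
#' @slot labels RleList of character labels, one Rle per read, each of
#'   length \code{width(ranges)}.
#' @slot pAdjAccessible,pAdjNucleosomal either NULL or a list of numeric
#'   vectors (NA at bases without a complete centered window).
#' @exportClass StateTrackSet
setClass("StateTrackSet",
    slots = c(
        ranges = "GRanges",
        labels = "RleList",
        pAdjAccessible = "ListOrNULL",
        pAdjNucleosomal = "ListOrNULL"
    )
)

setValidity("StateTrackSet", function(object) {
    gr <- object@ranges
    if (length(object@labels) != length(gr))
        return("one label Rle required per read")
    if (length(gr) && !all(lengths(object@labels) == width(gr)))
        return("label length must equal read width")
    ok <- vapply(seq_along(object@labels), function(i)
        all(S4Vectors::runValue(object@labels[[i]]) %in% c("A", "N", "X")),
        logical(1))
    if (!all(ok)) return("labels must be in {A, N, X}")
    TRUE
})

#' CalibrationTable: per-AT-count linear calibration
#'
#' Linear relationship between expected window methylation and average
#' read methylation, one fit per window adenine count N (both strands;
#' N = 3 .. window size). Fitted from a fully-accessible purified-DNA
#' (gDNA) control; the slope's departure from 1 captures the AT-content
#' dependence of m6A detection efficiency.
#'
#' @slot windowSize integer window size in bp (default 25).
#' @slot table data.frame with columns \code{N}, \code{slope},
#'   \code{intercept}, \code{r2}, \code{nPoints}, \code{interpolated}.
#' @slot fitRange numeric(2), closed interval of average read methylation
#'   used in the fit.
#' @exportClass CalibrationTable
setClass("CalibrationTable",
    slots = c(
        windowSize = "integer",
        table = "data.frame",
        fitRange = "numeric"
    )
)

setValidity("CalibrationTable", function(object) {
    w <- object@windowSize
    tb <- object@table
    if (length(w) != 1L || w < 5L)
        return("windowSize must be a single integer >= 5")
    need <- c("N", "slope", "intercept", "r2", "nPoints", "interpolated")
    if (!all(need %in% colnames(tb)))
        return(paste("table needs columns:", paste(need, collapse = ", ")))
    if (!identical(as.integer(tb$N), 3:w))
        return(sprintf("table must have one row per N = 3..%d", w))
    TRUE
})

#' ThresholdPair: adjusted p-value cutoffs for state assignment
#'
#' @slot thresholdAccessible adjusted p-value below which a window center
#'   is called accessible (default 0.853).
#' @slot thresholdNucleosomal adjusted p-value below which a window center
#'   is called nucleosomal (default 0.918).
#' @slot targetFpRate the false-positive rate the thresholds were
#'   calibrated to (NA when using fixed defaults).
#' @exportClass ThresholdPair
setClass("ThresholdPair",
    slots = c(
        thresholdAccessible = "numeric",
        thresholdNucleosomal = "numeric",
        targetFpRate = "numeric"
    )
)

setValidity("ThresholdPair", function(object) {
    ta <- object@thresholdAccessible
    tn <- object@thresholdNucleosomal
    if (length(ta) != 1L || length(tn) != 1L ||
        ta <= 0 || ta > 1 || tn <= 0 || tn > 1)
        return("thresholds must be single values in (0, 1]")
    TRUE
})

#' SimConfig: synthetic-data generator parameters
#'
#' Parameters of the read simulator that emulates the statistical
#' structure of M.EcoGII footprinting data: per-read variation in overall
#' m6A detection (lognormal, median ~11%), AT-content and poly(A)
#' detection bias, ~147-bp nucleosome footprints with short linkers, ~1%
#' residual methylation inside footprints, and promoter NDRs.
#'
#' @slot seed integer RNG seed; generation is fully reproducible.
#' @slot genomeLength,atContent genome size (bp) and mean A+T fraction.
#' @slot atBlockSd,blockLength the genome's compositional heterogeneity:
#'   each block of \code{blockLength} bp draws its local AT content
#'   around the mean with this SD (clipped to [0.05, 0.95]), emulating
#'   the GC-rich coding and AT-rich intergenic regions that populate the
#'   extreme window AT counts the calibration must cover.
#' @slot readLengthMean,readLengthSd read length distribution (bp).
#' @slot readMethDistribution "lognormal" or "fixed".
#' @slot readMethMedian,readMethSdlog lognormal parameters (median on the
#'   natural scale; sdlog on the log scale).
#' @slot readMethFixed fixed per-read m6A fraction (used when
#'   readMethDistribution == "fixed").
#' @slot readMethMax cap on the drawn per-read fraction.
#' @slot nucleosomeFootprint footprint length (bp, default 147).
#' @slot linkerMean,linkerSd linker length distribution (bp); lengths are
#'   drawn as max(5, round(Normal(mean, sd))).
#' @slot ndrLength promoter nucleosome-depleted region length (bp).
#' @slot nucleosomalFraction fraction of nucleosomal windows in the
#'   window-mode in-silico test.
#' @slot nucleosomeMeth m6A detection fraction inside footprints (default
#'   0.01).
#' @slot jitterSd per-molecule SD (bp) of the positional shift applied to
#'   a gene's nucleosome array (cell-to-cell heterogeneity).
#' @slot atBiasModel numeric multiplier on detection probability indexed
#'   by window AT count 0..windowSize (length windowSize + 1).
#' @slot polyABiasModel numeric multiplier indexed by same-strand poly(A)
#'   run length 1..maxRun (runs beyond the end use the last entry).
#' @slot qualityConstant simulated average read quality score.
#' @slot windowSize window size used for the AT-bias lookup.
#' @exportClass SimConfig
setClass("SimConfig",
    slots = c(
        seed = "integer",
        genomeLength = "integer",
        atContent = "numeric",
        atBlockSd = "numeric",
        blockLength = "integer",
        readLengthMean = "numeric",
        readLengthSd = "numeric",
        readMethDistribution = "character",
        readMethMedian = "numeric",
        readMethSdlog = "numeric",
        readMethFixed = "numeric",
        readMethMax = "numeric",
        nucleosomeFootprint = "integer",
        linkerMean = "numeric",
        linkerSd = "numeric",
        ndrLength = "integer",
        nucleosomalFraction = "numeric",
        nucleosomeMeth = "numeric",
        jitterSd = "numeric",
        atBiasModel = "numeric",
        polyABiasModel = "numeric",
        qualityConstant = "numeric",
        windowSize = "integer"
    )
)

setValidity("SimConfig", function(object) {
    fr <- c(object@atContent, object@nucleosomalFraction,
        object@nucleosomeMeth, object@readMethFixed)
    if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
    if (length(object@atBiasModel) != object@windowSize + 1L)
        return("atBiasModel must have one entry per AT count 0..windowSize")
    if (any(object@atBiasModel < 0) || any(object@polyABiasModel < 0))
        return("bias multipliers must be non-negative")
    TRUE
})
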