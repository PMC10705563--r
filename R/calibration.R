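#' Fit the per-AT-count window calibration
#'
#' m6A detection efficiency depends on local AT content, so the expected
#' methylation of a window is not simply the read's average methylation.
#' On a fully-accessible control (purified DNA methylated in vitro,
#' "gDNA"), window methylation is linearly related to average read
#' methylation, with slope and intercept depending on the window's
#' adenine count N (both strands). This fits one ordinary least-squares
#' line per N: reads inside \code{fitRange} (closed interval) are grouped
#' by average methylation rounded to 1\%, the mean window methylation is
#' computed per (N, bin) cell, and the line is fit across cells.
#'
#' N values with fewer than 3 populated bins are flagged unreliable and
#' filled by linear interpolation from neighbouring N.
#'
#' @param controlReads a \linkS4class{MethylReadSet} from a
#'   fully-accessible control.
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param windowSize sliding-window size in bp (default 25).
#' @param fitRange closed interval of average read methylation used in
#'   the fit (default c(0.07, 0.41)).
#' @return a \linkS4class{CalibrationTable}.
#' @export
fitCalibration <- function(controlReads, genome, windowSize = 25L,
        fitRange = c(0.07, 0.41)) {
    W <- as.integer(windowSize)
    m <- avgMethylation(controlReads)
    keep <- !is.na(m) & m >= fitRange[1] & m <= fitRange[2] &
        width(granges(controlReads)) >= W
    reads <- controlReads[keep]
    m <- m[keep]
    if (!length(reads))
        stop("no control reads with average methylation in [",
            fitRange[1], ", ", fitRange[2], "]")
    bin <- as.integer(round(m * 100))
    gr <- granges(reads)
    chroms <- as.character(seqnames(gr))
    chunks <- split(seq_len(length(reads)),
        ceiling(seq_len(length(reads)) / 500))
    agg <- vector("list", length(chunks))
    for (ci in seq_along(chunks)) {
        idx <- chunks[[ci]]
        Ns <- vector("list", length(idx))
        km <- vector("list", length(idx))
        bn <- vector("list", length(idx))
        for (jj in seq_along(idx)) {
            i <- idx[jj]
            codes <- .watsonCodes(genome, chroms[i], start(gr)[i],
                end(gr)[i])
            v <- .windowCounts(.isAT(codes),
                .m6aIndicator(reads, i, start(gr)[i], length(codes)), W)
            sel <- v$n >= 3L
            Ns[[jj]] <- v$n[sel]
            km[[jj]] <- v$k[sel] / v$n[sel]
            bn[[jj]] <- rep(bin[i], sum(sel))
        }
        dt <- data.table::data.table(N = unlist(Ns), wm = unlist(km),
            bin = unlist(bn))
        agg[[ci]] <- dt[, list(s = sum(wm), cnt = .N),
            by = c("N", "bin")]
    }
    cells <- data.table::rbindlist(agg)[, list(s = sum(s),
        cnt = sum(cnt)), by = c("N", "bin")]
    cells[, "wm" := cells$s / cells$cnt]
    tab <- data.frame(N = 3:W, slope = NA_real_, intercept = NA_real_,
        r2 = NA_real_, nPoints = 0L, interpolated = FALSE)
    for (r in seq_len(nrow(tab))) {
        Nv <- tab$N[r]
        cc <- cells[cells$N == Nv, ]
        tab$nPoints[r] <- nrow(cc)
        if (nrow(cc) < 3L) next
        x <- cc$bin / 100
        fit <- stats::lm.fit(cbind(1, x), cc$wm)
        tab$intercept[r] <- fit$coefficients[1]
        tab$slope[r] <- fit$coefficients[2]
        ssr <- sum(fit$residuals^2)
        sst <- sum((cc$wm - mean(cc$wm))^2)
        tab$r2[r] <- if (sst > 0) 1 - ssr / sst else NA_real_
    }
    bad <- is.na(tab$slope)
    if (any(bad)) {
        if (all(bad))
            stop("calibration failed: no N has enough methylation bins")
        ok <- which(!bad)
        for (col in c("slope", "intercept")) {
            tab[[col]][bad] <- stats::approx(tab$N[ok], tab[[col]][ok],
                xout = tab$N[bad], rule = 2)$y
        }
        tab$interpolated[bad] <- TRUE
        message("calibration: interpolated ", sum(bad),
            " data-poor N row(s): ",
            paste(tab$N[bad], collapse = ", "))
    }
    new("CalibrationTable", windowSize = W, table = tab,
        fitRange = as.numeric(fitRange))
}

#' Identity calibration
#'
#' A calibration table with slope 1 and intercept 0 for every N: the
#' expected window methylation equals the average read methylation
#' (no AT-content bias). Useful for simulations and unbiased data.
#'
#' @param windowSize window size in bp.
#' @return a \linkS4class{CalibrationTable}.
#' @export
identityCalibration <- function(windowSize = 25L) {
    W <- as.integer(windowSize)
    new("CalibrationTable", windowSize = W,
        table = data.frame(N = 3:W, slope = 1, intercept = 0, r2 = 1,
            nPoints = 0L, interpolated = FALSE),
        fitRange = c(0, 1))
}

#' Expected window methylation from the calibration
#'
#' Evaluates the per-N line: slope(N) * readMethylation + intercept(N),
#' clamped to (0, 1) by 1e-6 so it can serve as a binomial success
#' probability.
#'
#' @param table a \linkS4class{CalibrationTable}.
#' @param N window adenine count(s), each in 3..windowSize.
#' @param readMethylation average read methylation in [0, 1] (scalar or
#'   vector parallel to N).
#' @return numeric vector of expected window methylation values.
#' @export
expectedWindowMethylation <- function(table, N, readMethylation) {
    W <- table@windowSize
    if (any(N < 3L | N > W))
        stop("N = ", paste(unique(N[N < 3L | N > W]), collapse = ","),
            " outside the calibrated range 3..", W)
    tb <- table@table
    row <- match(N, tb$N)
    .clamp01(tb$slope[row] * readMethylation + tb$intercept[row])
}

#' Poly(A) run-length detection bias profile
#'
#' Groups every genomic adenine by the length of the maximal same-strand
#' poly(A) run containing it (plus-strand runs of A, minus-strand runs of
#' T in Watson coordinates), and reports the mean called-m6A fraction per
#' run length across all control read coverage. Runs of
#' \code{maxRun} or longer are pooled into the top bin.
#'
#' @param controlReads a \linkS4class{MethylReadSet}.
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param maxRun top (pooled) run-length bin, default 8.
#' @return data.frame with columns \code{runLength}, \code{nAdenines}
#'   (adenine observations over all reads) and \code{m6aFraction}.
#' @export
polyABiasProfile <- function(controlReads, genome, maxRun = 8L) {
    maxRun <- as.integer(maxRun)
    runlen <- lapply(genome, .polyARunLengths)
    gr <- granges(controlReads)
    chroms <- as.character(seqnames(gr))
    tot <- num <- numeric(maxRun)
    for (i in seq_len(length(controlReads))) {
        st <- start(gr)[i]
        rl <- runlen[[chroms[i]]][st:end(gr)[i]]
        isA <- rl > 0L
        b <- pmin(rl[isA], maxRun)
        called <- logical(sum(isA))
        p <- controlReads@m6aPos[[i]] - st + 1L
        hit <- logical(length(rl))
        hit[p] <- TRUE
        called <- hit[isA]
        tot <- tot + tabulate(b, maxRun)
        num <- num + tabulate(b[called], maxRun)
    }
    data.frame(runLength = seq_len(maxRun), nAdenines = tot,
        m6aFraction = ifelse(tot > 0, num / tot, NA_real_))
}

# Per-position maximal same-strand A-run length in Watson coordinates:
# >0 at adenines (on either strand), 0 elsewhere.
.polyARunLengths <- function(chromSeq) {
    codes <- as.integer(chromSeq)
    r <- rle(codes)
    isrun <- r$values == .CODE_A | r$values == .CODE_T
    rep(ifelse(isrun, r$lengths, 0L), r$lengths)
}

#' Calibrate state-call thresholds from control false positives
#'
#' Chooses adjusted p-value thresholds so that the caller's
#' false-positive rate stays below \code{targetFpRate}. The nucleosomal
#' threshold is calibrated on the fully-accessible control (any
#' nucleosomal call there is false): the caller is run across a grid of
#' candidate thresholds and the largest one keeping the nucleosomal base
#' fraction below target is returned. A false accessible call needs a
#' truly protected truth set, which the control lacks, so the accessible
#' threshold is calibrated symmetrically on simulated fully-protected
#' reads (methylated at the intra-footprint rate).
#'
#' @param controlReads fully-accessible control
#'   \linkS4class{MethylReadSet}.
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param table a \linkS4class{CalibrationTable} fitted on the control.
#' @param targetFpRate maximum tolerated false-positive base fraction
#'   (default 0.01).
#' @param grid candidate thresholds, ascending.
#' @param protectedReads optional \linkS4class{MethylReadSet} of
#'   simulated fully-protected reads; when NULL the accessible threshold
#'   is left at its default 0.853.
#' @param windowSize window size in bp.
#' @param defaultThresholds fallback \linkS4class{ThresholdPair} whose
#'   accessible threshold anchors the nucleosomal sweep.
#' @return a \linkS4class{ThresholdPair}.
#' @export
calibrateThresholds <- function(controlReads, genome, table,
        targetFpRate = 0.01,
        grid = sort(c(seq(0.05, 0.95, by = 0.05), 0.853, 0.918, 0.99)),
        protectedReads = NULL, windowSize = 25L,
        defaultThresholds = ThresholdPair()) {
    if (!length(controlReads)) stop("empty control read set")
    grid <- sort(grid)
    cacheC <- .adjustedCache(controlReads, genome, table, windowSize)
    fpN <- vapply(grid, function(thr)
        .stateFraction(cacheC, defaultThresholds@thresholdAccessible, thr,
            windowSize, "N"), numeric(1))
    okN <- which(fpN < targetFpRate)
    if (!length(okN))
        stop(sprintf(paste0("no grid threshold restrains the nucleosomal",
            " false-positive rate below %g (minimum achievable: %.4g)"),
            targetFpRate, min(fpN)))
    thrNuc <- grid[max(okN)]
    thrAcc <- defaultThresholds@thresholdAccessible
    if (!is.null(protectedReads)) {
        cacheP <- .adjustedCache(protectedReads, genome, table, windowSize)
        fpA <- vapply(grid, function(thr)
            .stateFraction(cacheP, thr, thrNuc, windowSize, "A"),
            numeric(1))
        okA <- which(fpA < targetFpRate)
        if (!length(okA))
            stop(sprintf(paste0("no grid threshold restrains the ",
                "accessible false-positive rate below %g (minimum ",
                "achievable: %.4g)"), targetFpRate, min(fpA)))
        thrAcc <- grid[max(okA)]
    }
    ThresholdPair(thrAcc, thrNuc, targetFpRate)
}

#' @rdname ThresholdPair-class
#' @param thresholdAccessible,thresholdNucleosomal adjusted p-value
#'   cutoffs (defaults 0.853 and 0.918).
#' @param targetFpRate the false-positive target the pair was calibrated
#'   to (NA for fixed defaults).
#' @export
ThresholdPair <- function(thresholdAccessible = 0.853,
        thresholdNucleosomal = 0.918, targetFpRate = NA_real_) {
    new("ThresholdPair", thresholdAccessible = thresholdAccessible,
        thresholdNucleosomal = thresholdNucleosomal,
        targetFpRate = targetFpRate)
}

setMethod("show", "ThresholdPair", function(object) {
    cat(sprintf(
        "ThresholdPair: accessible < %.3f, nucleosomal < %.3f%s\n",
        object@thresholdAccessible, object@thresholdNucleosomal,
        if (is.na(object@targetFpRate)) "" else
            sprintf(" (target FP rate %g)", object@targetFpRate)))
})

#' Write / read a calibration table as TSV
#'
#' Columns \code{N}, \code{k} (slope), \code{beta} (intercept),
#' \code{r2}, \code{n_points}, \code{interpolated}.
#'
#' @param table a \linkS4class{CalibrationTable}.
#' @param path TSV path.
#' @return the path (write) or a \linkS4class{CalibrationTable} (read).
#' @export
writeCalibrationTable <- function(table, path) {
    tb <- table@table
    df <- data.frame(N = tb$N, k = tb$slope, beta = tb$intercept,
        r2 = tb$r2, n_points = tb$nPoints,
        interpolated = tb$interpolated)
    hdr <- sprintf("# window_size=%d fit_range=%g,%g", table@windowSize,
        table@fitRange[1], table@fitRange[2])
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t",
        quote = FALSE, row.names = FALSE, append = TRUE))
    invisible(path)
}

#' @rdname writeCalibrationTable
#' @export
readCalibrationTable <- function(path) {
    hdr <- readLines(path, n = 1L)
    W <- as.integer(sub(".*window_size=(\\d+).*", "\\1", hdr))
    fr <- as.numeric(strsplit(sub(".*fit_range=([0-9.eE+-]+,[0-9.eE+-]+).*",
        "\\1", hdr), ",")[[1]])
    df <- utils::read.delim(path, comment.char = "#")
    new("CalibrationTable", windowSize = W,
        table = data.frame(N = df$N, slope = df$k, intercept = df$beta,
            r2 = df$r2, nPoints = df$n_points,
            interpolated = as.logical(df$interpolated)),
        fitRange = fr)
}

setMethod("show", "CalibrationTable", function(object) {
    cat(sprintf(paste0("CalibrationTable: %d-bp windows, N = 3..%d, ",
        "fit range [%g, %g]\n"), object@windowSize, object@windowSize,
        object@fitRange[1], object@fitRange[2]))
    r2 <- object@table$r2
    if (any(!is.na(r2)))
        cat(sprintf("  slope range %.3f..%.3f, min R^2 %.4f\n",
            min(object@table$slope), max(object@table$slope),
            min(r2, na.rm = TRUE)))
})
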