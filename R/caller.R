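# Core per-read engine: sliding-window adjusted binomial test, BH
# correction within the read, state assignment at window centers, and
# boundary/ambiguity resolution.

# Rolling window adenine (n) and m6A (k) counts over a read.
# at, m6a: logical vectors over the read span (Watson projection).
.windowCounts <- function(at, m6a, W) {
    L <- length(at)
    nw <- L - W + 1L
    ca <- cumsum(at)
    cm <- cumsum(m6a)
    list(
        n = ca[W:L] - c(0L, ca[seq_len(nw - 1L)]),
        k = cm[W:L] - c(0L, cm[seq_len(nw - 1L)]),
        center = seq_len(nw) + W %/% 2L
    )
}

.m6aIndicator <- function(reads, i, st, L) {
    v <- logical(L)
    v[reads@m6aPos[[i]] - st + 1L] <- TRUE
    v
}

#' Scan a read with the sliding-window binomial test
#'
#' Slides a window of \code{windowSize} bp over one read. For each
#' complete window, counts adenines on both strands (n, from the Watson
#' A+T count) and called m6A (k), predicts the expected window
#' methylation from the calibration and the read's average methylation,
#' and computes the two one-tailed binomial p-values, both including the
#' observed count: pLow = P(X <= k) (evidence for protection) and pHigh
#' = P(X >= k) (evidence for accessibility) under X ~ Binomial(n, pExp).
#' Windows with fewer than 3 adenines are untestable (NA p-values):
#' 3 is the smallest calibrated N.
#'
#' @param read a single-read \linkS4class{MethylReadSet} (or a set; then
#'   \code{which} selects the read).
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param table a \linkS4class{CalibrationTable}.
#' @param windowSize window size in bp (default 25).
#' @param which index of the read to scan.
#' @return data.frame with columns \code{center} (genome position of the
#'   central nucleotide), \code{nAdenines}, \code{kM6A}, \code{pExp},
#'   \code{pLow}, \code{pHigh}, \code{testable}. Zero rows (with an
#'   attribute \code{tooShort = TRUE}) if the read is shorter than the
#'   window.
#' @export
scanWindows <- function(read, genome, table, windowSize = 25L,
        which = 1L) {
    W <- as.integer(windowSize)
    gr <- granges(read)[which]
    st <- start(gr)
    L <- width(gr)
    out0 <- data.frame(center = integer(0), nAdenines = integer(0),
        kM6A = integer(0), pExp = numeric(0), pLow = numeric(0),
        pHigh = numeric(0), testable = logical(0))
    if (L < W) {
        attr(out0, "tooShort") <- TRUE
        return(out0)
    }
    chrom <- as.character(seqnames(gr))
    codes <- .watsonCodes(genome, chrom, st, end(gr))
    v <- .windowCounts(.isAT(codes), .m6aIndicator(read, which, st, L), W)
    m <- avgMethylation(read)[which]
    testable <- v$n >= 3L & !is.na(m)
    pexp <- plow <- phigh <- rep(NA_real_, length(v$n))
    if (any(testable)) {
        pexp[testable] <- expectedWindowMethylation(table, v$n[testable],
            m)
        plow[testable] <- stats::pbinom(v$k[testable], v$n[testable],
            pexp[testable])
        phigh[testable] <- stats::pbinom(v$k[testable] - 1L,
            v$n[testable], pexp[testable], lower.tail = FALSE)
    }
    data.frame(center = st + v$center - 1L, nAdenines = v$n, kM6A = v$k,
        pExp = pexp, pLow = plow, pHigh = phigh, testable = testable)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort ascending, adjusted_i = min over j >= i of
#' p_(j) * m / j, capped at 1, returned in input order. In the caller it
#' is applied within each read, separately to the protection-tail and
#' accessibility-tail p-value families.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NAs allowed and
#'   passed through).
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(pvalues) {
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Assign chromatin states at window centers
#'
#' The central nucleotide of each testable window is labelled accessible
#' ("A") when the adjusted accessibility p-value is below the accessible
#' threshold, nucleosomal ("N") when the adjusted protection p-value is
#' below the nucleosomal threshold, and ambiguous ("X") otherwise. When
#' both pass, the smaller adjusted p-value wins; an exact tie stays
#' ambiguous. Untestable windows and edge bases without a complete
#' centered window are ambiguous.
#'
#' @param stats data.frame from \code{\link{scanWindows}} with added
#'   columns \code{pAdjLow} and \code{pAdjHigh} (BH-adjusted per family
#'   within the read).
#' @param thresholds a \linkS4class{ThresholdPair}.
#' @param readStart,readEnd genome span of the read.
#' @return character label vector of length readEnd - readStart + 1.
#' @export
assignStates <- function(stats, thresholds, readStart, readEnd) {
    if (!all(c("pAdjLow", "pAdjHigh") %in% colnames(stats)))
        stop("stats must carry BH-adjusted columns pAdjLow and pAdjHigh")
    L <- readEnd - readStart + 1L
    lab <- rep("X", L)
    sel <- stats$testable
    if (!any(sel)) return(lab)
    al <- stats$pAdjLow[sel]
    ah <- stats$pAdjHigh[sel]
    acc <- ah < thresholds@thresholdAccessible
    nuc <- al < thresholds@thresholdNucleosomal
    s <- ifelse(acc & !nuc, "A",
        ifelse(nuc & !acc, "N",
            ifelse(acc & nuc,
                ifelse(ah < al, "A", ifelse(al < ah, "N", "X")), "X")))
    lab[stats$center[sel] - readStart + 1L] <- s
    lab
}

#' Resolve state boundaries and reassign short ambiguous runs
#'
#' Window centers near a state transition are systematically ambiguous:
#' as the window slides from accessible DNA into a footprint its
#' methylation passes through the expected value. Four rules, applied in
#' this fixed order, resolve these zones: (1) at each accessible-to-
#' nucleosomal transition, the windowSize/2 nucleotides downstream of the
#' last accessible window center (the second half of that window) become
#' accessible; (2) symmetrically at nucleosomal-to-accessible
#' transitions the downstream extension of the last nucleosomal center
#' becomes nucleosomal; (3) bases claimed by both extensions become
#' nucleosomal; (4) remaining ambiguous runs shorter than
#' \code{maxAmbiguousReassign} adjacent to a nucleosomal run become
#' nucleosomal. Extensions convert ambiguous bases only (called bases
#' are never flipped) and apply only at transitions whose ambiguous gap
#' is shorter than the window, which makes the operation idempotent.
#'
#' @param track a character label vector over \code{"A"/"N"/"X"}, or a
#'   \linkS4class{StateTrackSet} (resolved track-by-track).
#' @param windowSize window size used by the caller; the extension
#'   length is windowSize \%/\% 2.
#' @param maxAmbiguousReassign ambiguous runs strictly shorter than this
#'   and adjacent to a nucleosomal run are reassigned (default 25, one
#'   window: a shorter run cannot independently support an accessible
#'   call).
#' @return same type as the input, with resolved labels.
#' @export
resolveBoundaries <- function(track, windowSize = 25L,
        maxAmbiguousReassign = 25L) {
    if (is(track, "StateTrackSet")) {
        lab <- lapply(seq_len(length(track)), function(i)
            .resolveLabelVector(as.character(track@labels[[i]]),
                windowSize, maxAmbiguousReassign))
        return(StateTrackSet(granges(track), moleculeId(track), lab,
            track@pAdjAccessible, track@pAdjNucleosomal))
    }
    .resolveLabelVector(track, windowSize, maxAmbiguousReassign)
}

.resolveLabelVector <- function(lab, windowSize = 25L, maxAmb = 25L) {
    ext <- as.integer(windowSize) %/% 2L
    L <- length(lab)
    r <- rle(lab)
    v <- r$values
    len <- r$lengths
    nr <- length(v)
    if (nr >= 3L) {
        ends <- cumsum(len)
        extA <- logical(L)
        extN <- logical(L)
        for (j in seq_len(nr - 2L)) {
            if (v[j + 1L] != "X" || len[j + 1L] >= windowSize) next
            if (v[j] == "A" && v[j + 2L] == "N")
                extA[(ends[j] + 1L):min(ends[j] + ext, L)] <- TRUE
            else if (v[j] == "N" && v[j + 2L] == "A")
                extN[(ends[j] + 1L):min(ends[j] + ext, L)] <- TRUE
        }
        isX <- lab == "X"
        lab[isX & extA & !extN] <- "A"
        lab[isX & extN] <- "N"
        r <- rle(lab)
        v <- r$values
        len <- r$lengths
        nr <- length(v)
    }
    if (nr >= 2L) {
        ends <- cumsum(len)
        starts <- ends - len + 1L
        for (j in seq_len(nr)) {
            if (v[j] != "X" || len[j] >= maxAmb) next
            leftN <- j > 1L && v[j - 1L] == "N"
            rightN <- j < nr && v[j + 1L] == "N"
            if (leftN || rightN) lab[starts[j]:ends[j]] <- "N"
        }
    }
    lab
}

# Per-read adjusted p-values at window centers, cached for threshold
# sweeps: list of (centers, adjLow, adjHigh, start, L) per read.
.adjustedCache <- function(reads, genome, table, windowSize = 25L) {
    W <- as.integer(windowSize)
    gr <- granges(reads)
    chroms <- as.character(seqnames(gr))
    m <- avgMethylation(reads)
    tb <- table@table
    slopeByN <- interceptByN <- rep(NA_real_, W)
    slopeByN[tb$N] <- tb$slope
    interceptByN[tb$N] <- tb$intercept
    out <- vector("list", length(reads))
    for (i in seq_len(length(reads))) {
        st <- start(gr)[i]
        L <- width(gr)[i]
        if (L < W || is.na(m[i])) {
            out[[i]] <- list(centers = integer(0), adjLow = numeric(0),
                adjHigh = numeric(0), start = st, L = L,
                reason = if (L < W) "too short" else "no adenines")
            next
        }
        codes <- .watsonCodes(genome, chroms[i], st, end(gr)[i])
        v <- .windowCounts(.isAT(codes), .m6aIndicator(reads, i, st, L),
            W)
        sel <- v$n >= 3L
        n <- v$n[sel]
        pexp <- .clamp01(slopeByN[n] * m[i] + interceptByN[n])
        plow <- stats::pbinom(v$k[sel], n, pexp)
        phigh <- stats::pbinom(v$k[sel] - 1L, n, pexp,
            lower.tail = FALSE)
        out[[i]] <- list(centers = v$center[sel] + st - 1L,
            adjLow = stats::p.adjust(plow, "BH"),
            adjHigh = stats::p.adjust(phigh, "BH"),
            start = st, L = L, reason = NULL)
    }
    out
}

.labelsFromCache <- function(entry, thrAcc, thrNuc, windowSize,
        maxAmb = 25L) {
    lab <- rep("X", entry$L)
    if (length(entry$centers)) {
        acc <- entry$adjHigh < thrAcc
        nuc <- entry$adjLow < thrNuc
        s <- ifelse(acc & !nuc, "A",
            ifelse(nuc & !acc, "N",
                ifelse(acc & nuc, ifelse(entry$adjHigh < entry$adjLow,
                    "A", ifelse(entry$adjLow < entry$adjHigh, "N", "X")),
                    "X")))
        lab[entry$centers - entry$start + 1L] <- s
    }
    .resolveLabelVector(lab, windowSize, maxAmb)
}

# Fraction of base pairs carrying a given final label across cached reads.
.stateFraction <- function(cache, thrAcc, thrNuc, windowSize, state) {
    tot <- hit <- 0
    for (e in cache) {
        lab <- .labelsFromCache(e, thrAcc, thrNuc, windowSize)
        tot <- tot + length(lab)
        hit <- hit + sum(lab == state)
    }
    hit / tot
}

#' Call chromatin states on every read
#'
#' Full per-read pipeline: sliding-window binomial test against the
#' calibrated expectation, BH adjustment within the read (separately for
#' the protection and accessibility families), state assignment at
#' window centers, and boundary resolution. Reads shorter than the
#' window or without adenines pass through fully ambiguous (reason
#' logged via \code{message}).
#'
#' @param reads a \linkS4class{MethylReadSet}.
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param table a \linkS4class{CalibrationTable}.
#' @param thresholds a \linkS4class{ThresholdPair}.
#' @param windowSize window size in bp (default 25).
#' @param maxAmbiguousReassign see \code{\link{resolveBoundaries}}.
#' @param keepPvalues if TRUE, per-base adjusted p-values are retained in
#'   the track set (memory-heavy).
#' @return a \linkS4class{StateTrackSet} parallel to \code{reads}.
#' @export
callReads <- function(reads, genome, table, thresholds = ThresholdPair(),
        windowSize = 25L, maxAmbiguousReassign = 25L,
        keepPvalues = FALSE) {
    cache <- .adjustedCache(reads, genome, table, windowSize)
    skipped <- vapply(cache, function(e) !is.null(e$reason), logical(1))
    if (any(skipped))
        message(sum(skipped), " read(s) passed through fully ambiguous (",
            paste(unique(unlist(lapply(cache, `[[`, "reason"))),
                collapse = "; "), ")")
    lab <- lapply(cache, .labelsFromCache,
        thrAcc = thresholds@thresholdAccessible,
        thrNuc = thresholds@thresholdNucleosomal,
        windowSize = windowSize, maxAmb = maxAmbiguousReassign)
    pa <- pn <- NULL
    if (keepPvalues) {
        pa <- lapply(cache, function(e) {
            v <- rep(NA_real_, e$L)
            v[e$centers - e$start + 1L] <- e$adjHigh
            v
        })
        pn <- lapply(cache, function(e) {
            v <- rep(NA_real_, e$L)
            v[e$centers - e$start + 1L] <- e$adjLow
            v
        })
    }
    StateTrackSet(granges(reads), moleculeId(reads), lab, pa, pn)
}

#' Footprint length histogram
#'
#' Run-length encodes the nucleosomal state across resolved tracks and
#' counts footprint (maximal nucleosomal run) lengths, normalised per
#' million nucleotides sequenced.
#'
#' @param tracks a \linkS4class{StateTrackSet}.
#' @return data.frame with columns \code{length}, \code{count},
#'   \code{perMillionNt}.
#' @export
footprintLengths <- function(tracks) {
    totalNt <- sum(as.numeric(width(granges(tracks))))
    lens <- integer(0)
    for (i in seq_len(length(tracks))) {
        r <- tracks@labels[[i]]
        lens <- c(lens, S4Vectors::runLength(r)[
            S4Vectors::runValue(r) == "N"])
    }
    if (!length(lens))
        return(data.frame(length = integer(0), count = integer(0),
            perMillionNt = numeric(0)))
    tab <- table(lens)
    data.frame(length = as.integer(names(tab)), count = as.integer(tab),
        perMillionNt = as.integer(tab) / (totalNt / 1e6))
}
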