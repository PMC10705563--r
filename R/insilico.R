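#' In-silico window-level validation of the caller
#'
#' Reproduces the model's window-level stress test: for each combination
#' of per-read m6A fraction and nucleosomal fraction, draws independent
#' 25-bp windows at the configured AT content, labels each window
#' nucleosomal with the configured probability, methylates nucleosomal
#' windows at the intra-footprint rate (default 1\%) and accessible
#' windows at the rate solved from the mass balance
#' f = nucFraction * nucleosomeMeth + (1 - nucFraction) * pAcc, then
#' scores every window with the caller's protection statistic
#' P(X <= k | n, pExp) and evaluates classification against truth by
#' ROC/AUC (threshold swept over the statistic) and by a confusion
#' table at the default adjusted-p thresholds (BH across the sample's
#' windows).
#'
#' @param m6aFractions per-read m6A fractions to test (default 0.05,
#'   0.10, 0.15).
#' @param nucFractions nucleosomal fractions to test (default 0.6, 0.7,
#'   0.8).
#' @param nWindows windows per condition (default 100000).
#' @param atContent window AT content (default 0.6).
#' @param nucleosomeMeth intra-footprint methylated fraction (default
#'   0.01).
#' @param windowSize window size in bp.
#' @param table a \linkS4class{CalibrationTable} (identity by default:
#'   the simulated windows carry no AT bias).
#' @param thresholds a \linkS4class{ThresholdPair} for the confusion
#'   table.
#' @param seed RNG seed.
#' @return data.frame with one row per condition: \code{m6aFraction},
#'   \code{nucFraction}, \code{pAccessible}, \code{auc}, and the
#'   confusion counts \code{tp}, \code{fp}, \code{tn}, \code{fn}
#'   (positive class = nucleosomal).
#' @export
insilicoWindowTest <- function(m6aFractions = c(0.05, 0.10, 0.15),
        nucFractions = c(0.6, 0.7, 0.8), nWindows = 100000L,
        atContent = 0.6, nucleosomeMeth = 0.01, windowSize = 25L,
        table = identityCalibration(windowSize),
        thresholds = ThresholdPair(), seed = 1L) {
    set.seed(seed)
    grid <- expand.grid(m6aFraction = m6aFractions,
        nucFraction = nucFractions)
    res <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
        f <- grid$m6aFraction[g]
        q <- grid$nucFraction[g]
        pAcc <- (f - q * nucleosomeMeth) / (1 - q)
        if (pAcc > 1 || pAcc < nucleosomeMeth)
            stop(sprintf(paste0("accessible methylation solves to %.3f",
                " for m6A fraction %.2f at nucleosomal fraction %.2f;",
                " must lie in [%g, 1]"), pAcc, f, q, nucleosomeMeth))
        n <- stats::rbinom(nWindows, windowSize, atContent)
        isNuc <- stats::runif(nWindows) < q
        k <- stats::rbinom(nWindows, n,
            ifelse(isNuc, nucleosomeMeth, pAcc))
        testable <- n >= 3L
        pexp <- expectedWindowMethylation(table,
            pmin(n[testable], windowSize), f)
        plow <- stats::pbinom(k[testable], n[testable], pexp)
        phigh <- stats::pbinom(k[testable] - 1L, n[testable], pexp,
            lower.tail = FALSE)
        truth <- isNuc[testable]
        auc <- as.numeric(pROC::auc(pROC::roc(response = truth,
            predictor = plow, levels = c(FALSE, TRUE), direction = ">",
            quiet = TRUE)))
        adjLow <- stats::p.adjust(plow, "BH")
        adjHigh <- stats::p.adjust(phigh, "BH")
        callNuc <- adjLow < thresholds@thresholdNucleosomal &
            !(adjHigh < thresholds@thresholdAccessible &
              adjHigh < adjLow)
        res[[g]] <- data.frame(m6aFraction = f, nucFraction = q,
            pAccessible = pAcc, auc = auc,
            tp = sum(callNuc & truth), fp = sum(callNuc & !truth),
            tn = sum(!callNuc & !truth), fn = sum(!callNuc & truth))
    }
    do.call(rbind, res)
}
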