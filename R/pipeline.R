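#' Run the full footprinting pipeline
#'
#' End-to-end orchestration: obtain reads (from files or the built-in
#' simulator), quality-filter, fit the AT-content calibration on the
#' fully-accessible control, call per-molecule chromatin states, and
#' compute the population aggregates (TSS phasing profile, footprint
#' lengths, per-gene heterogeneity). All declared outputs are written
#' under \code{outDir} together with a machine-readable manifest of
#' parameters, input checksums and the seed. Results go to files;
#' progress is logged to stderr.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised keys (defaults in parentheses): \code{outDir}
#'   (required), \code{seed} (1), \code{simulate} (TRUE when no read
#'   input is given), \code{genomeFasta}, \code{readsTsv},
#'   \code{controlTsv}, \code{genesBed}, \code{nReads} (500),
#'   \code{nControlReads} (500), \code{readsPerGene} (0: uniform reads),
#'   \code{windowSize} (25), \code{minQuality} (90),
#'   \code{thresholdAccessible} (0.853), \code{thresholdNucleosomal}
#'   (0.918), \code{calibrateThresholds} (FALSE), \code{targetFpRate}
#'   (0.01), \code{fitRange} (c(0.07, 0.41)), \code{flankPhasing}
#'   (400), \code{flankHet} (300), \code{minReads} (6), plus any
#'   \code{\link{SimConfig}} argument prefixed \code{sim.} (e.g.
#'   \code{sim.jitterSd}).
#' @return invisibly, a named list of output file paths and the main
#'   in-memory results.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- function(key, default = NULL)
        if (!is.null(config[[key]])) config[[key]] else default
    outDir <- cfg("outDir")
    if (is.null(outDir)) stop("config must provide outDir")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(cfg("seed", 1L))
    W <- as.integer(cfg("windowSize", 25L))
    if (W < 5L)
        stop("windowSize must be at least 5 (smallest testable window)")
    simArgs <- config[grepl("^sim\\.", names(config))]
    names(simArgs) <- sub("^sim\\.", "", names(simArgs))
    simArgs$seed <- seed
    simArgs$windowSize <- W
    sc <- do.call(SimConfig, simArgs)
    inputs <- character(0)

    if (!is.null(cfg("genomeFasta"))) {
        genome <- Biostrings::readDNAStringSet(cfg("genomeFasta"))
        names(genome) <- sub("\\s.*", "", names(genome))
        genes <- if (!is.null(cfg("genesBed")))
            readGeneBed(cfg("genesBed")) else NULL
        inputs <- c(inputs, cfg("genomeFasta"), cfg("genesBed"))
    } else {
        message("simulating genome (", sc@genomeLength, " bp)")
        g <- simulateGenome(sc)
        genome <- g$genome
        genes <- g$genes
        Biostrings::writeXStringSet(genome,
            file.path(outDir, "genome.fa"))
        writeGeneBed(genes, file.path(outDir, "genes.bed"))
    }

    if (!is.null(cfg("readsTsv"))) {
        reads <- readInterchangeTable(cfg("readsTsv"), genome)
        truth <- NULL
        inputs <- c(inputs, cfg("readsTsv"))
    } else {
        n <- as.integer(cfg("nReads", 500L))
        rpg <- as.integer(cfg("readsPerGene", 0L))
        message("simulating ", if (rpg > 0) "TSS-anchored " else "",
            "nuclei reads")
        sim <- simulateNucleiReads(sc, genome, nReads = n,
            genes = if (rpg > 0) genes else NULL,
            readsPerGene = max(rpg, 1L))
        reads <- sim$reads
        truth <- sim$truth
        writeInterchangeTable(reads, file.path(outDir, "reads.tsv"))
    }

    control <- NULL
    if (!is.null(cfg("controlTsv"))) {
        control <- readInterchangeTable(cfg("controlTsv"), genome)
        inputs <- c(inputs, cfg("controlTsv"))
    } else if (is.null(cfg("readsTsv"))) {
        control <- simulateGdnaReads(sc, genome,
            as.integer(cfg("nControlReads", 500L)))
    }

    minQ <- cfg("minQuality", 90)
    nBefore <- length(reads)
    reads <- filterReads(reads, minQuality = minQ)
    message("quality filter (>= ", minQ, "): retained ", length(reads),
        " of ", nBefore, " reads")

    if (!is.null(control)) {
        message("fitting calibration on ", length(control),
            " control reads")
        table <- fitCalibration(control, genome, windowSize = W,
            fitRange = as.numeric(cfg("fitRange", c(0.07, 0.41))))
    } else {
        message("no control supplied: using identity calibration")
        table <- identityCalibration(W)
    }
    writeCalibrationTable(table, file.path(outDir, "calibration.tsv"))

    if (isTRUE(cfg("calibrateThresholds")) && !is.null(control)) {
        prot <- simulateProtectedReads(sc, genome,
            max(50L, length(control) %/% 10L))
        thresholds <- calibrateThresholds(control, genome, table,
            targetFpRate = cfg("targetFpRate", 0.01),
            protectedReads = prot$reads, windowSize = W)
    } else {
        thresholds <- ThresholdPair(cfg("thresholdAccessible", 0.853),
            cfg("thresholdNucleosomal", 0.918))
    }
    message(sprintf("thresholds: accessible < %.3f, nucleosomal < %.3f",
        thresholds@thresholdAccessible,
        thresholds@thresholdNucleosomal))

    message("calling chromatin states on ", length(reads), " reads")
    tracks <- callReads(reads, genome, table, thresholds, windowSize = W)
    writeAnnotatedBam(reads, file.path(outDir, "calls.bam"), genome,
        tracks)
    writeStateBed(tracks, file.path(outDir, "nucleosomes.bed"),
        state = "N")
    fpl <- footprintLengths(tracks)
    data.table::fwrite(fpl, file.path(outDir, "footprint_lengths.tsv"),
        sep = "\t")

    phas <- het <- NULL
    if (!is.null(genes) && length(genes)) {
        sel <- selectPhasingGenes(genes,
            chromLengths = stats::setNames(lengths(genome),
                names(genome)))
        message(length(sel), " of ", length(genes),
            " genes pass the phasing filter")
        phas <- phasingProfile(tracks, sel,
            flank = cfg("flankPhasing", 400L))
        data.table::fwrite(phas,
            file.path(outDir, "phasing_profile.tsv"), sep = "\t")
        het <- heterogeneityScores(tracks, sel,
            flank = cfg("flankHet", 300L),
            minReads = cfg("minReads", 6L))
        data.table::fwrite(het, file.path(outDir, "heterogeneity.tsv"),
            sep = "\t")
        data.table::fwrite(heterogeneityHistogram(het),
            file.path(outDir, "heterogeneity_hist.tsv"), sep = "\t")
    }

    manifest <- list(
        seed = seed,
        parameters = list(windowSize = W, minQuality = minQ,
            thresholdAccessible = thresholds@thresholdAccessible,
            thresholdNucleosomal = thresholds@thresholdNucleosomal,
            fitRange = as.numeric(cfg("fitRange", c(0.07, 0.41))),
            flankPhasing = cfg("flankPhasing", 400L),
            flankHet = cfg("flankHet", 300L),
            minReads = cfg("minReads", 6L)),
        nReadsIn = nBefore, nReadsCalled = length(reads),
        inputChecksums = as.list(tools::md5sum(
            inputs[!vapply(inputs, is.null, logical(1))])))
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    invisible(list(outDir = outDir, reads = reads, tracks = tracks,
        calibration = table, thresholds = thresholds,
        phasing = phas, heterogeneity = het))
}
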