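# Shared fixtures, all built in code.

suppressPackageStartupMessages({
    library(Biostrings)
    library(GenomicRanges)
    library(S4Vectors)
})

tinyGenome <- function(seq, chrom = "chrT") {
    g <- DNAStringSet(seq)
    names(g) <- chrom
    g
}

# Random genome with reproducible composition.
randomGenome <- function(len, at = 0.5, seed = 1, chrom = "chrT") {
    set.seed(seed)
    tinyGenome(paste(sample(c("A", "T", "C", "G"), len, replace = TRUE,
        prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = ""), chrom)
}

# One-call read constructor: m6a as "pos:strand" tokens (1-based).
mkRead <- function(genome, start, end, m6a = character(0), id = "r1",
        quality = 99, chrom = names(genome)[1]) {
    if (length(m6a)) {
        parts <- strsplit(m6a, ":", fixed = TRUE)
        pos <- as.integer(vapply(parts, `[`, "", 1L))
        strn <- vapply(parts, `[`, "", 2L)
    } else {
        pos <- integer(0)
        strn <- character(0)
    }
    MethylReadSet(id, chrom, start, end, quality, list(pos), list(strn),
        genome)
}

# Expand compact run notation like "A30 X20 N30" to a label vector.
expandLab <- function(runs) {
    tok <- strsplit(runs, " +")[[1]]
    unlist(lapply(tok, function(t)
        rep(substr(t, 1, 1), as.integer(substring(t, 2)))))
}

mkTrack <- function(labels, start = 1L, chrom = "chrT", id = "m1") {
    StateTrackSet(GRanges(chrom,
        IRanges(start, start + length(labels) - 1L)), id, list(labels))
}

# Read whose methylation follows a truth label vector: accessible
# adenines detected with prob pAcc, protected with prob pNuc.
methylateByTruth <- function(genome, start, truth, pAcc, pNuc = 0.01,
        id = "r1") {
    codes <- as.integer(subseq(genome[[1]], start,
        start + length(truth) - 1L))
    at <- codes == 1L | codes == 8L
    p <- ifelse(truth == "N", pNuc, pAcc)
    hit <- which(at & stats::runif(length(truth)) < p)
    mkRead(genome, start, start + length(truth) - 1L,
        sprintf("%d:%s", hit + start - 1L,
            ifelse(codes[hit] == 1L, "+", "-")), id = id)
}
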