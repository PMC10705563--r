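# Shared internal helpers.

# Clamp of the calibration prediction: the binomial test needs a success
# probability strictly inside (0, 1).
.PEXP_EPS <- 1e-6

.clamp01 <- function(x, eps = .PEXP_EPS) pmin(pmax(x, eps), 1 - eps)

# Biostrings integer codes for A and T (single-bit DNA encoding).
.CODE_A <- 1L
.CODE_T <- 8L

# Logical Watson A/T indicator over a genome interval (1-based closed).
# base pairs with A on the plus strand read A; A on the minus strand read T.
.watsonCodes <- function(genome, chrom, from, to) {
    s <- Biostrings::subseq(genome[[chrom]], from, to)
    as.integer(s)
}

.isAT <- function(codes) codes == .CODE_A | codes == .CODE_T

# Retrieve a chromosome or fail with a clear message.
.checkChrom <- function(genome, chrom) {
    if (!chrom %in% names(genome))
        stop("chromosome '", chrom, "' not found in the reference genome")
    invisible(TRUE)
}

# Derive a child RNG seed (< 2^31) from a base seed and a stream label,
# so that independent simulation stages do not share streams.
.childSeed <- function(seed, stream) {
    (as.integer(seed) + 10007L * as.integer(stream)) %% 2147483647L
}
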