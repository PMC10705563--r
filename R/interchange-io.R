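#' Read the tabular read interchange format
#'
#' Tab-separated with header columns \code{molecule_id}, \code{chrom},
#' \code{start}, \code{end}, \code{read_quality}, \code{m6a_positions}.
#' Coordinates on disk are 0-based half-open; m6A positions are
#' comma-separated \code{pos:strand} tokens (0-based Watson coordinate of
#' the methylated base pair, strand of the adenine). Adenine sets are
#' derived from the reference genome.
#'
#' @param path path to the TSV file.
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @return a \linkS4class{MethylReadSet}.
#' @export
readInterchangeTable <- function(path, genome) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
        data.table = FALSE)
    need <- c("molecule_id", "chrom", "start", "end", "read_quality",
        "m6a_positions")
    miss <- setdiff(need, colnames(dt))
    if (length(miss))
        stop("interchange table ", path, " is missing column(s): ",
            paste(miss, collapse = ", "))
    if (!is.character(dt$m6a_positions))
        dt$m6a_positions <- ifelse(is.na(dt$m6a_positions), "",
            as.character(dt$m6a_positions))
    n <- nrow(dt)
    pos <- vector("list", n)
    str <- vector("list", n)
    for (i in seq_len(n)) {
        tok <- dt$m6a_positions[i]
        if (is.na(tok) || !nzchar(tok)) {
            pos[[i]] <- integer(0)
            str[[i]] <- character(0)
            next
        }
        parts <- strsplit(strsplit(tok, ",", fixed = TRUE)[[1]], ":",
            fixed = TRUE)
        ok <- lengths(parts) == 2L
        if (!all(ok))
            stop("malformed m6a_positions token on line ", i + 1L,
                " of ", path)
        p <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
        s <- vapply(parts, `[`, "", 2L)
        if (anyNA(p) || !all(s %in% c("+", "-")))
            stop("malformed m6a_positions token on line ", i + 1L,
                " of ", path)
        pos[[i]] <- p + 1L
        str[[i]] <- s
    }
    MethylReadSet(dt$molecule_id, dt$chrom, dt$start + 1L, dt$end,
        dt$read_quality, pos, str, genome)
}

#' Write the tabular read interchange format
#'
#' Inverse of \code{\link{readInterchangeTable}}; round-trips exactly.
#'
#' @param reads a \linkS4class{MethylReadSet}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeInterchangeTable <- function(reads, path) {
    gr <- granges(reads)
    n <- length(reads)
    tok <- character(n)
    for (i in seq_len(n)) {
        p <- reads@m6aPos[[i]] - 1L
        s <- ifelse(reads@m6aStrand[[i]] == 1L, "-", "+")
        tok[i] <- paste(sprintf("%d:%s", p, s), collapse = ",")
    }
    df <- data.frame(molecule_id = moleculeId(reads),
        chrom = as.character(seqnames(gr)),
        start = start(gr) - 1L, end = end(gr),
        read_quality = readQuality(reads),
        m6a_positions = tok)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    invisible(path)
}
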