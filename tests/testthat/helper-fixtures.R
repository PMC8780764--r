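# In-code fixtures: tiny profiles, annotations and genomes built on the fly.

# EndProfile from sparse named count vectors (names = positions)
makeProfile <- function(L, plus = integer(0), minus = integer(0),
                        orientation = "five_prime_end", id = "chr") {
    cp <- integer(L); cm <- integer(L)
    if (length(plus)) cp[as.integer(names(plus))] <- as.integer(plus)
    if (length(minus)) cm[as.integer(names(minus))] <- as.integer(minus)
    EndProfile(id, L, orientation, "test", cp, cm)
}

sparse <- function(positions, counts) stats::setNames(counts, positions)

makeGenes <- function(starts, ends, strands, ids = NULL, id = "chr") {
    if (is.null(ids)) ids <- sprintf("g%d", seq_along(starts))
    gr <- GenomicRanges::GRanges(
        seqnames = rep(id, length(starts)),
        ranges = IRanges::IRanges(starts, ends),
        strand = strands)
    gr$gene_id <- ids
    gr$kind <- rep("CDS", length(gr))
    gr$product <- rep(NA_character_, length(gr))
    gr
}

emptyGenes <- function() makeGenes(integer(0), integer(0), character(0),
                                   character(0))

# minimal unclassified TSS/TEP rows for assembling by hand
tssRow <- function(position, strand, count = 10L, category = "U",
                   gene_id = NA_character_, utr5 = NA_integer_) {
    data.frame(position = position, strand = strand,
               tap_plus_count = count, tap_minus_count = 0L,
               category = category, gene_id = gene_id,
               utr5_length = utr5, leaderless = NA,
               stringsAsFactors = FALSE)
}

tepRow <- function(position, strand, count = 10L, category = NA_character_,
                   gene_id = NA_character_, utr3 = NA_integer_) {
    data.frame(position = position, strand = strand, count = count,
               category = category, gene_id = gene_id, utr3_length = utr3,
               u_rich = NA, region_start = position, region_end = position,
               stringsAsFactors = FALSE)
}

# candidate table for reconcileReplicates built by hand
candTable <- function(positions, counts, span, strand = "+") {
    data.frame(position = positions, strand = strand, count = counts,
               zscore = Inf, cluster_start = span[1], cluster_end = span[2],
               stringsAsFactors = FALSE)
}

writeTempLines <- function(lines, ext) {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}
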