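# Internal helpers shared across modules.

# fraction of G+C in a DNA string (N ignored in denominator)
.gcFraction <- function(seq) {
    tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
    gc <- sum(tab[names(tab) %in% c("G", "C")])
    acgt <- sum(tab[names(tab) %in% c("A", "C", "G", "T")])
    if (acgt == 0) return(NA_real_)
    gc / acgt
}

# +1 on the forward strand, -1 on the reverse strand
.dirOf <- function(strand) ifelse(strand == "+", 1L, -1L)

# signed distance from a to b along the transcription direction of `strand`:
# positive when b is downstream of a
.dirDist <- function(a, b, strand) (b - a) * .dirOf(strand)

.revcomp <- function(s) {
    chartr("ACGTN", "TGCAN",
           vapply(s, function(x)
               paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
               character(1), USE.NAMES = FALSE))
}

.complement <- function(chars) chartr("ACGTN", "TGCAN", chars)

# population standard deviation (divisor n, not n-1)
.popSd <- function(x) {
    if (length(x) <= 1L) return(0)
    m <- mean(x)
    sqrt(mean((x - m)^2))
}

.IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# list of allowed-base character vectors, one per consensus position
.iupacAllowed <- function(consensus) {
    chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
    unknown <- setdiff(chars, names(.IUPAC_SETS))
    if (length(unknown))
        stop(sprintf("unknown IUPAC code(s): %s",
                     paste(unknown, collapse = ", ")))
    lapply(chars, function(ch) .IUPAC_SETS[[ch]])
}

# number of consensus-incompatible positions in `word` (character scalar)
.iupacMismatches <- function(word, allowed) {
    chars <- strsplit(word, "", fixed = TRUE)[[1]]
    if (length(chars) != length(allowed))
        stop("word length does not match consensus length")
    sum(!mapply(function(ch, ok) ch %in% ok, chars, allowed))
}

# gene geometry vectors from a GRanges annotation
.geneGeometry <- function(genes) {
    stopifnot(is(genes, "GRanges"))
    st <- as.character(GenomicRanges::strand(genes))
    if (any(!st %in% c("+", "-")))
        stop("gene annotation contains unstranded features")
    s <- GenomicRanges::start(genes)
    e <- GenomicRanges::end(genes)
    list(start = s, end = e, strand = st,
         # start-codon (5') and stop-codon (3') positions in transcription order
         start5 = ifelse(st == "+", s, e),
         stop3 = ifelse(st == "+", e, s),
         gene_id = genes$gene_id)
}

.checkStrand <- function(strand) {
    if (!all(strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    strand
}

# strand-aware window of the genome written 5'->3' on the transcript strand,
# covering `len` bases ending at (and including) position `pos`
.upstreamWindow <- function(genome, pos, strand, len, includeAnchor = TRUE) {
    L <- genomeLength(genome)
    if (strand == "+") {
        if (includeAnchor) { lo <- pos - len + 1L; hi <- pos }
        else { lo <- pos - len; hi <- pos - 1L }
        if (lo < 1L || hi > L) return(NA_character_)
        genomeSubseq(genome, lo, hi)
    } else {
        if (includeAnchor) { lo <- pos; hi <- pos + len - 1L }
        else { lo <- pos + 1L; hi <- pos + len }
        if (lo < 1L || hi > L) return(NA_character_)
        .revcomp(genomeSubseq(genome, lo, hi))
    }
}
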