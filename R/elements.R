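## Sequence-level regulatory-element annotation and profile statistics around
## called transcript boundaries: averaged read-density profiles, nucleotide
## enrichment against intergenic background, promoter -10/-35 consensus
## scanning with spacer lengths, UTR-length summaries, U-richness of
## terminator windows, and heptameric direct repeats of the kind bound by
## Streptomyces antibiotic regulatory proteins (SARP).

#' Averaged normalized read density around anchor positions
#'
#' For each anchor `p`, the per-offset density is
#' `d(x, p) = r(p + x) / max(r(p - 300 .. p + 300))`, strand-aware (offsets
#' are mirrored on the minus strand so negative offsets are always upstream).
#' Anchors whose whole window is zero are skipped. The profile is the mean of
#' `d(x, p)` over the retained anchors.
#'
#' @param anchors data.frame with `position` and `strand` columns (for
#'   example a TSS or TEP table).
#' @param profile An [EndProfile-class] (typically RNA-Seq coverage).
#' @param halfWindow Half window in nt (default 300, i.e. 601 offsets).
#' @return data.frame with `offset` and `density` columns; the number of
#'   retained anchors is in attribute `"nPositions"`.
#' @export
readDensity <- function(anchors, profile, halfWindow = 300L) {
    stopifnot(is(profile, "EndProfile"))
    if (nrow(anchors) == 0L) stop("anchor list is empty")
    .checkStrand(anchors$strand)
    L <- genomeLength(profile)
    offsets <- seq(-halfWindow, halfWindow)
    acc <- numeric(length(offsets))
    nUsed <- 0L
    for (i in seq_len(nrow(anchors))) {
        p <- anchors$position[i]; st <- anchors$strand[i]
        counts <- strandCounts(profile, st)
        idx <- p + .dirOf(st) * offsets
        r <- numeric(length(offsets))
        ok <- idx >= 1L & idx <= L
        r[ok] <- counts[idx[ok]]
        m <- max(r)
        if (m == 0) next
        acc <- acc + r / m
        nUsed <- nUsed + 1L
    }
    if (nUsed == 0L) stop("every anchor window is devoid of signal")
    out <- data.frame(offset = offsets, density = acc / nUsed)
    attr(out, "nPositions") <- nUsed
    out
}

# transcript-strand base at signed offset x from anchor (p, strand);
# NA outside the genome
.baseAtOffset <- function(seqChars, p, strand, x, L) {
    idx <- p + .dirOf(strand) * x
    if (idx < 1L || idx > L) return(NA_character_)
    b <- seqChars[idx]
    if (strand == "-") .complement(b) else b
}

# offsets x nucleotide frequency matrix over a set of anchors (T reported
# as U); anchors with any out-of-range offset are dropped
.offsetFrequencies <- function(anchors, genome, offsets) {
    seqChars <- strsplit(genomeSeq(genome), "", fixed = TRUE)[[1]]
    L <- genomeLength(genome)
    nucs <- c("A", "C", "G", "U")
    freq <- matrix(0, nrow = length(offsets), ncol = 4L,
                   dimnames = list(NULL, nucs))
    nUsed <- 0L
    for (i in seq_len(nrow(anchors))) {
        p <- anchors$position[i]; st <- anchors$strand[i]
        lo <- p + .dirOf(st) * min(offsets)
        hi <- p + .dirOf(st) * max(offsets)
        if (min(lo, hi) < 1L || max(lo, hi) > L) next
        bases <- vapply(offsets, function(x)
            .baseAtOffset(seqChars, p, st, x, L), character(1))
        bases[bases == "T"] <- "U"
        for (k in seq_along(offsets)) {
            if (bases[k] %in% nucs)
                freq[k, bases[k]] <- freq[k, bases[k]] + 1
        }
        nUsed <- nUsed + 1L
    }
    if (nUsed == 0L) stop("no anchor with a complete sequence window")
    list(freq = freq / nUsed, n = nUsed)
}

#' Per-offset nucleotide enrichment of anchors over a background set
#'
#' At each offset of the window the frequency of each nucleotide over the
#' anchors is divided by its frequency over the background positions
#' (strand-aware; reverse-complemented on the minus strand; T reported as U).
#'
#' @param anchors data.frame with `position`, `strand` (e.g. a TEP table).
#' @param genome A [Genome-class].
#' @param background data.frame with `position`, `strand`, typically from
#'   [sampleIntergenicBackground()].
#' @param window Integer pair `(from, to)` of offsets; default `c(-41, 20)`,
#'   the 41-nt-upstream to 20-nt-downstream window used for terminator
#'   analysis.
#' @return Long data.frame: `offset`, `nucleotide`, `anchor_freq`,
#'   `background_freq`, `ratio`.
#' @export
nucleotideEnrichment <- function(anchors, genome, background,
                                 window = c(-41L, 20L)) {
    stopifnot(is(genome, "Genome"), nrow(background) > 0L)
    offsets <- seq(window[1], window[2])
    fa <- .offsetFrequencies(anchors, genome, offsets)
    fb <- .offsetFrequencies(background, genome, offsets)
    undefined <- fb$freq == 0 & fa$freq > 0
    if (any(undefined)) {
        bad <- sort(unique(offsets[which(undefined, arr.ind = TRUE)[, 1]]))
        stop(sprintf("background frequency is zero at offset(s) %s",
                     paste(bad, collapse = ", ")))
    }
    ratio <- fa$freq / fb$freq
    ratio[fb$freq == 0] <- NA_real_
    data.frame(
        offset = rep(offsets, times = 4L),
        nucleotide = rep(colnames(fa$freq), each = length(offsets)),
        anchor_freq = as.vector(fa$freq),
        background_freq = as.vector(fb$freq),
        ratio = as.vector(ratio),
        stringsAsFactors = FALSE)
}

#' Sample random intergenic positions
#'
#' Uniform without-replacement sample of positions not covered by any gene
#' body (either strand), each assigned a random strand. Deterministic under
#' `seed`.
#'
#' @param genes Gene `GRanges`.
#' @param genome A [Genome-class].
#' @param n Number of positions.
#' @param seed Integer seed.
#' @return data.frame with `position` and `strand`.
#' @export
sampleIntergenicBackground <- function(genes, genome, n, seed = 1L) {
    stopifnot(is(genome, "Genome"), n >= 1L)
    L <- genomeLength(genome)
    genic <- rep(FALSE, L)
    for (j in seq_along(genes)) {
        s <- GenomicRanges::start(genes)[j]
        e <- GenomicRanges::end(genes)[j]
        genic[s:e] <- TRUE
    }
    pool <- which(!genic)
    if (length(pool) < n)
        stop(sprintf("only %d intergenic positions available, %d requested",
                     length(pool), n))
    set.seed(seed)
    data.frame(position = sample(pool, n),
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
}

# scan a window string for the best match to an IUPAC consensus;
# startIdxs are candidate start indices within the window, tie broken by
# `tie` = "last" (3'-most) or "first" (5'-most)
.scanConsensus <- function(window, allowed, startIdxs, tie, maxIncompat = 2L) {
    width <- length(allowed)
    mism <- vapply(startIdxs, function(i)
        .iupacMismatches(substr(window, i, i + width - 1L), allowed),
        numeric(1))
    best <- min(mism)
    if (best > maxIncompat) return(NULL)
    hits <- startIdxs[mism == best]
    i <- if (tie == "last") hits[length(hits)] else hits[1L]
    list(index = i, mismatches = best,
         seq = substr(window, i, i + width - 1L))
}

#' Annotate promoter -10 and -35 elements around TSSs
#'
#' The 41 transcript-strand nt ending at each TSS (promoter numbering, no
#' position 0: offsets -40 .. -1, +1) are scanned with IUPAC consensi: the
#' -10 element within offsets -20 .. +1 (default consensus `TANNNT`) and the
#' -35 element within -40 .. -25 (default `BTGACN`). The best hexamer match
#' (fewest consensus-incompatible positions) is reported if it has at most 2
#' incompatibilities; ties resolve towards the window's 3' end for the -10
#' and the 5' end for the -35. The spacer is the number of nt strictly
#' between the -35 element's end and the -10 element's start. TSSs too close
#' to the sequence edge are skipped with a warning.
#'
#' @param tss Classified TSS table.
#' @param genome A [Genome-class].
#' @param minus10Consensus,minus35Consensus Length-6 IUPAC strings.
#' @return data.frame: `tss_position`, `strand`, `minus10_offset`,
#'   `minus10_seq`, `minus35_offset`, `minus35_seq`, `spacer_length`.
#'   Offsets are promoter coordinates of the element's 5' base.
#' @export
annotatePromoters <- function(tss, genome, minus10Consensus = "TANNNT",
                              minus35Consensus = "BTGACN") {
    stopifnot(is(genome, "Genome"))
    if (nchar(minus10Consensus) != 6L || nchar(minus35Consensus) != 6L)
        stop("promoter consensi must be 6 nt IUPAC strings")
    a10 <- .iupacAllowed(minus10Consensus)
    a35 <- .iupacAllowed(minus35Consensus)
    regionLen <- 41L       # offsets -40..-1 then +1; index i <=40 -> i - 41
    idxToOffset <- function(i) if (i == 41L) 1L else i - 41L

    n <- nrow(tss)
    m10off <- rep(NA_integer_, n); m10seq <- rep(NA_character_, n)
    m35off <- rep(NA_integer_, n); m35seq <- rep(NA_character_, n)
    spacer <- rep(NA_integer_, n)
    skipped <- 0L
    for (i in seq_len(n)) {
        region <- .upstreamWindow(genome, tss$position[i], tss$strand[i],
                                  regionLen, includeAnchor = TRUE)
        if (is.na(region)) { skipped <- skipped + 1L; next }
        # -10 window: offsets -20..+1 -> indices 21..41, hexamer starts 21..36
        h10 <- .scanConsensus(region, a10, 21:36, tie = "last")
        # -35 window: offsets -40..-25 -> indices 1..16, hexamer starts 1..11
        h35 <- .scanConsensus(region, a35, 1:11, tie = "first")
        if (!is.null(h10)) {
            m10off[i] <- idxToOffset(h10$index)
            m10seq[i] <- h10$seq
        }
        if (!is.null(h35)) {
            m35off[i] <- idxToOffset(h35$index)
            m35seq[i] <- h35$seq
        }
        if (!is.null(h10) && !is.null(h35))
            spacer[i] <- h10$index - (h35$index + 6L)
    }
    if (skipped > 0L)
        warning(sprintf("%d TSS(s) skipped: promoter window outside genome",
                        skipped))
    data.frame(tss_position = tss$position, strand = tss$strand,
               minus10_offset = m10off, minus10_seq = m10seq,
               minus35_offset = m35off, minus35_seq = m35seq,
               spacer_length = spacer, stringsAsFactors = FALSE)
}

#' UTR-length summary statistics
#'
#' Histograms of 5'-UTR lengths (primary TSSs) and 3'-UTR lengths (primary
#' TEPs) in 10-nt bins, plus counts and fractions of leaderless (< 9 nt) and
#' long-leader (> 150 nt) primary TSSs.
#'
#' @param tss Classified TSS table.
#' @param teps Classified TEP table.
#' @return A list: `utr5_hist`, `utr3_hist` (data.frames with `bin_start`,
#'   `bin_label`, `count`), `leaderless`, `long_leader` (each a list with
#'   `count` and `fraction`), `n_primary_tss`, `n_primary_tep`.
#' @export
utrStatistics <- function(tss, teps) {
    utr5 <- tss$utr5_length[tss$category == "P" & !is.na(tss$utr5_length)]
    utr3 <- teps$utr3_length[teps$category == "P" & !is.na(teps$utr3_length)]
    binify <- function(x) {
        if (!length(x))
            return(data.frame(bin_start = integer(0), bin_label = character(0),
                              count = integer(0)))
        b <- floor(x / 10) * 10L
        tb <- table(b)
        starts <- as.integer(names(tb))
        data.frame(bin_start = starts,
                   bin_label = sprintf("%d-%d", starts, starts + 9L),
                   count = as.integer(tb), stringsAsFactors = FALSE)
    }
    nP5 <- length(utr5)
    list(
        utr5_hist = binify(utr5),
        utr3_hist = binify(utr3),
        leaderless = list(count = sum(utr5 < 9),
                          fraction = if (nP5) sum(utr5 < 9) / nP5 else NA_real_),
        long_leader = list(count = sum(utr5 > 150),
                           fraction = if (nP5) sum(utr5 > 150) / nP5 else NA_real_),
        n_primary_tss = nP5,
        n_primary_tep = length(utr3)
    )
}

#' Flag U-rich transcript 3'-end windows
#'
#' A TEP is U-rich when the `windowLen` transcript-strand nt ending at the
#' TEP contain at least `minU` U (genomic T). This is a fixed-threshold
#' approximation of motif membership, not a de-novo motif search; thresholds
#' are configurable.
#'
#' @param teps TEP table.
#' @param genome A [Genome-class].
#' @param windowLen Window length (default 8 nt).
#' @param minU Minimum U count (default 4).
#' @return The TEP table with the `u_rich` flag filled (NA when the window
#'   falls outside the genome).
#' @export
uRichness <- function(teps, genome, windowLen = 8L, minU = 4L) {
    stopifnot(is(genome, "Genome"))
    flag <- rep(NA, nrow(teps))
    for (i in seq_len(nrow(teps))) {
        win <- .upstreamWindow(genome, teps$position[i], teps$strand[i],
                               windowLen, includeAnchor = TRUE)
        if (is.na(win)) next
        flag[i] <- lengths(regmatches(win, gregexpr("T", win))) >= minU
    }
    teps$u_rich <- flag
    teps
}

#' Find heptameric direct repeats upstream of TSSs
#'
#' Scans the `upstreamLen` transcript-strand nt upstream of each TSS for
#' pairs of 7-mers, each within `maxMismatch` of the consensus, separated by
#' exactly 4 or 15 nt — the spacing of SARP-type activator binding sites.
#'
#' @param tss TSS table.
#' @param genome A [Genome-class].
#' @param consensus IUPAC 7-mer consensus.
#' @param maxMismatch Maximum consensus mismatches per heptamer (default 1).
#' @param upstreamLen Upstream window length (default 150 nt).
#' @param spacings Allowed exact gaps between the two heptamers
#'   (default `c(4, 15)`).
#' @return data.frame: `tss_position`, `strand`, `offset1`, `offset2`
#'   (positions of the heptamer 5' bases relative to the TSS, negative),
#'   `heptamer1`, `heptamer2`, `spacing`, `score` (total matches to
#'   consensus, max 14).
#' @export
findHeptamerRepeats <- function(tss, genome, consensus, maxMismatch = 1L,
                                upstreamLen = 150L, spacings = c(4L, 15L)) {
    stopifnot(is(genome, "Genome"))
    if (nchar(consensus) != 7L) stop("consensus must be a 7-mer")
    allowed <- .iupacAllowed(consensus)
    out <- list()
    for (i in seq_len(nrow(tss))) {
        win <- .upstreamWindow(genome, tss$position[i], tss$strand[i],
                               upstreamLen, includeAnchor = FALSE)
        if (is.na(win)) next
        starts <- seq_len(upstreamLen - 6L)
        mism <- vapply(starts, function(s)
            .iupacMismatches(substr(win, s, s + 6L), allowed), numeric(1))
        hits <- starts[mism <= maxMismatch]
        if (length(hits) < 2L) next
        for (h1 in hits) {
            for (gap in spacings) {
                h2 <- h1 + 7L + gap
                if (!(h2 %in% hits)) next
                out[[length(out) + 1L]] <- data.frame(
                    tss_position = tss$position[i], strand = tss$strand[i],
                    offset1 = h1 - upstreamLen - 1L,
                    offset2 = h2 - upstreamLen - 1L,
                    heptamer1 = substr(win, h1, h1 + 6L),
                    heptamer2 = substr(win, h2, h2 + 6L),
                    spacing = gap,
                    score = as.integer(14L - mism[match(h1, starts)] -
                                           mism[match(h2, starts)]),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(tss_position = integer(0), strand = character(0),
                          offset1 = integer(0), offset2 = integer(0),
                          heptamer1 = character(0), heptamer2 = character(0),
                          spacing = integer(0), score = integer(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
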