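## TSS calling from differential RNA-Seq (TAP+/TAP-) 5'-end profiles.
##
## Pipeline per strand: cluster the nonzero TAP(+) 5'-end positions (gap
## < 100 nt), sub-cluster under a positional standard-deviation bound (< 10),
## discard sub-clusters with a summed read count <= 3, take the
## maximum-count position of each surviving sub-cluster, and drop positions whose
## TAP(-) count exceeds their TAP(+) count. Classification against gene start
## codons follows: primary/secondary within [-500, +100] of a start codon,
## internal within a same-strand ORF, antisense over an opposite-strand ORF,
## intergenic otherwise.

# split sorted positions where the gap to the previous position is >= maxGap
.gapPartition <- function(positions, maxGap) {
    if (length(positions) == 0L) return(integer(0))
    c(0L, cumsum(diff(positions) >= maxGap)) + 1L
}

#' Cluster nonzero end positions by genomic distance
#'
#' Consecutive nonzero positions less than `maxGap` nt apart fall in the same
#' cluster; clusters are separated by gaps of at least `maxGap`.
#'
#' @param profile An [EndProfile-class].
#' @param strand `"+"` or `"-"`.
#' @param maxGap Clustering distance in nt (default 100, the 5'-end scale).
#' @return A data.frame with columns `position`, `count`, `cluster` (integer
#'   id), sorted by position; zero rows for an empty strand.
#' @seealso [subclusterBySd()], [clusterThreePrimePositions()]
#' @export
clusterPositions <- function(profile, strand, maxGap = 100L) {
    stopifnot(is(profile, "EndProfile"), maxGap >= 1L)
    strand <- match.arg(strand, c("+", "-"))
    counts <- strandCounts(profile, strand)
    pos <- which(counts > 0L)
    data.frame(position = pos, count = counts[pos],
               cluster = .gapPartition(pos, maxGap))
}

#' Sub-cluster positions under a standard-deviation bound
#'
#' Greedy left-to-right agglomeration: a sub-cluster starts at the leftmost
#' unassigned position and grows rightward while the population standard
#' deviation of the member positions stays below `sdMax`. Deterministic given
#' sorted input.
#'
#' @param positions Sorted integer vector of genomic positions.
#' @param sdMax Standard-deviation bound in nt (default 10).
#' @return Integer vector of sub-cluster ids parallel to `positions`.
#' @examples
#' subclusterBySd(c(100, 101, 102))  # one sub-cluster (sd ~ 0.82)
#' subclusterBySd(c(100, 140))      # two singletons (sd of pair = 20)
#' @export
subclusterBySd <- function(positions, sdMax = 10) {
    stopifnot(sdMax > 0)
    n <- length(positions)
    if (n == 0L) return(integer(0))
    if (is.unsorted(positions)) stop("positions must be sorted")
    ids <- integer(n)
    cur <- 1L
    startIdx <- 1L
    for (i in seq_len(n)) {
        if (i == startIdx) { ids[i] <- cur; next }
        if (.popSd(positions[startIdx:i]) < sdMax) {
            ids[i] <- cur
        } else {
            cur <- cur + 1L
            startIdx <- i
            ids[i] <- cur
        }
    }
    ids
}

#' Call transcription start sites from TAP(+)/TAP(-) profiles
#'
#' See the module description at the top of the file for the pipeline. The
#' read-count filter keeps sub-clusters with a summed count strictly greater
#' than `minClusterReads` ("more than three reads" at the default), applied
#' at the sub-cluster level: the sub-clusters are the final position groups
#' from which one TSS each is selected, so a spurious single-read end inside
#' an otherwise strong cluster does not surface as its own TSS. (This is
#' strictly stronger than filtering whole clusters: if a cluster's sum fails
#' the bound, every sub-cluster's sum does too.)
#' Within a sub-cluster, count ties resolve to the most-5' position (smallest
#' coordinate on `+`, largest on `-`), favouring the longest isoform. The
#' TAP comparison is applied at the selected position with a strict
#' inequality: a position with more TAP(-) than TAP(+) reads is discarded as
#' a processed 5' end.
#'
#' @param tapPlus,tapMinus 5'-end [EndProfile-class]s from TAP-treated and
#'   untreated libraries.
#' @param minClusterReads Cluster-sum threshold (default 3; clusters with sum
#'   <= 3 are dropped).
#' @param maxGap Clustering distance (default 100 nt).
#' @param sdMax Sub-clustering standard-deviation bound (default 10 nt).
#' @return A data.frame in the `tss` schema with `category = "U"` (call
#'   [classifyTSS()] to assign categories).
#' @export
callTSS <- function(tapPlus, tapMinus, minClusterReads = 3L,
                    maxGap = 100L, sdMax = 10) {
    stopifnot(is(tapPlus, "EndProfile"), is(tapMinus, "EndProfile"))
    if (genomeId(tapPlus) != genomeId(tapMinus) ||
        genomeLength(tapPlus) != genomeLength(tapMinus))
        stop("TAP(+) and TAP(-) profiles refer to different genomes")
    if (tapPlus@orientation != "five_prime_end" ||
        tapMinus@orientation != "five_prime_end")
        stop("TSS calling requires five_prime_end profiles")

    out <- list()
    for (st in c("+", "-")) {
        cl <- clusterPositions(tapPlus, st, maxGap)
        if (nrow(cl) == 0L) next
        minusCounts <- strandCounts(tapMinus, st)
        for (cid in unique(cl$cluster)) {
            rows <- cl[cl$cluster == cid, , drop = FALSE]
            sub <- subclusterBySd(rows$position, sdMax)
            for (sid in unique(sub)) {
                r <- rows[sub == sid, , drop = FALSE]
                if (sum(r$count) <= minClusterReads) next
                best <- which(r$count == max(r$count))
                # tie -> most-5' position
                pick <- if (st == "+") best[1L] else best[length(best)]
                p <- r$position[pick]
                tapP <- r$count[pick]
                tapM <- minusCounts[p]
                if (tapM > tapP) next
                out[[length(out) + 1L]] <- data.frame(
                    position = p, strand = st, tap_plus_count = tapP,
                    tap_minus_count = tapM, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out)) {
        res <- data.frame(position = integer(0), strand = character(0),
                          tap_plus_count = integer(0),
                          tap_minus_count = integer(0))
    } else {
        res <- do.call(rbind, out)
    }
    res$category <- rep("U", nrow(res))
    res$gene_id <- rep(NA_character_, nrow(res))
    res$utr5_length <- rep(NA_integer_, nrow(res))
    res$leaderless <- rep(NA, nrow(res))
    res <- res[order(res$strand, res$position), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Classify called TSSs relative to annotated ORFs
#'
#' Precedence per TSS: (1) if it lies within `upWindow` nt upstream to
#' `downWindow` nt downstream of at least one same-strand start codon it is
#' associated with the gene whose start codon is nearest; among the TSSs of
#' one gene the highest TAP(+) count is primary (`P`), the rest secondary
#' (`S`), ties resolving to the nearest start codon. (2) Otherwise a TSS
#' inside a same-strand ORF is internal (`I`); (3) one over an opposite-strand
#' ORF is antisense (`A`); (4) anything else is intergenic (`N`).
#' `utr5_length` is the strand-aware distance from TSS to start codon
#' (negative when the TSS is downstream of the start codon); primary TSSs
#' with `utr5_length < 9` are flagged leaderless.
#'
#' @param tss Output of [callTSS()].
#' @param genes Gene `GRanges` with `gene_id`.
#' @param upWindow,downWindow Association window around start codons
#'   (defaults 500 and 100 nt).
#' @return The `tss` data.frame with `category`, `gene_id`, `utr5_length` and
#'   `leaderless` filled in.
#' @export
classifyTSS <- function(tss, genes, upWindow = 500L, downWindow = 100L) {
    geo <- .geneGeometry(genes)
    n <- nrow(tss)
    category <- rep("N", n)
    gene_id <- rep(NA_character_, n)
    utr5 <- rep(NA_integer_, n)

    for (i in seq_len(n)) {
        p <- tss$position[i]; st <- tss$strand[i]
        same <- which(geo$strand == st)
        if (length(same)) {
            d <- .dirDist(p, geo$start5[same], st)  # + = start codon downstream
            inWin <- d >= -downWindow & d <= upWindow
            if (any(inWin)) {
                cand <- same[inWin]
                j <- cand[which.min(abs(d[inWin]))]
                gene_id[i] <- geo$gene_id[j]
                utr5[i] <- as.integer(.dirDist(p, geo$start5[j], st))
                category[i] <- "S"   # promoted to P below
                next
            }
            if (any(geo$start[same] <= p & geo$end[same] >= p)) {
                category[i] <- "I"
                next
            }
        }
        opp <- which(geo$strand != st)
        if (length(opp) && any(geo$start[opp] <= p & geo$end[opp] >= p))
            category[i] <- "A"
    }

    # per gene: max TAP(+) count -> P (tie -> nearest start codon)
    assoc <- which(category == "S")
    for (g in unique(gene_id[assoc])) {
        rows <- assoc[gene_id[assoc] == g]
        best <- rows[tss$tap_plus_count[rows] == max(tss$tap_plus_count[rows])]
        if (length(best) > 1L) best <- best[which.min(abs(utr5[best]))]
        category[best] <- "P"
    }

    tss$category <- category
    tss$gene_id <- gene_id
    tss$utr5_length <- utr5
    tss$leaderless <- ifelse(category == "P", utr5 < 9L, NA)
    tss
}
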