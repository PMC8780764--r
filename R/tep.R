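## Transcript 3'-end (TEP) calling from Term-Seq profiles.
##
## Candidate 3'-end positions are restricted to intergenic space (a 10-nt
## invasion into the 5' end of the downstream gene is allowed), clustered at
## the 10-nt scale, and scored with a leave-one-out modified z-score: the
## mean and standard deviation are taken over the other positions of the
## cluster, excluding the evaluated one. Positions with fewer than 3 reads or
## a z-score below 3 are discarded, separately per biological replicate, and
## replicate calls are reconciled inside the intersection of overlapping
## cluster spans.

#' Leave-one-out modified z-score of a cluster position
#'
#' With `others` the counts of the cluster excluding the evaluated index:
#' `mu = mean(others)`, `mu2 = mean(others^2)`,
#' `sigma = sqrt(mu2 - mu^2)` and `Z = (count - mu) / sigma`.
#' Edge contracts: a singleton cluster scores `+Inf` (an isolated sharp 3'
#' end is inherently enriched); when `sigma == 0`, the score is `+Inf` if the
#' evaluated count exceeds `mu` and `0` otherwise.
#'
#' @param counts Numeric vector of read counts of the cluster's positions.
#' @param index Index (1-based) of the evaluated position within `counts`.
#' @return A numeric scalar, possibly `Inf`.
#' @examples
#' modifiedZscore(c(1, 2, 3, 10), 4)   # ~9.798
#' modifiedZscore(c(5, 5, 5), 2)       # 0
#' modifiedZscore(c(3, 3, 12), 3)      # Inf
#' @export
modifiedZscore <- function(counts, index) {
    n <- length(counts)
    if (n == 0L) stop("counts must be nonempty")
    if (index < 1L || index > n) stop("index out of range")
    if (n == 1L) return(Inf)
    r <- counts[index]
    others <- counts[-index]
    mu <- mean(others)
    mu2 <- mean(others^2)
    v <- max(mu2 - mu^2, 0)
    if (v < 1e-12) {
        if (r > mu) return(Inf) else return(0)
    }
    (r - mu) / sqrt(v)
}

# per-strand logical mask of positions allowed as 3'-end candidates:
# outside every same-strand gene body, each body shrunk by `invasion` nt at
# its 5' end (the downstream-gene invasion allowance)
.intergenicMask <- function(genes, strand, L, invasion = 10L) {
    geo <- .geneGeometry(genes)
    ok <- rep(TRUE, L)
    same <- which(geo$strand == strand)
    for (j in same) {
        if (geo$strand[j] == "+") {
            lo <- min(geo$start[j] + invasion, L + 1L)
            hi <- geo$end[j]
        } else {
            lo <- geo$start[j]
            hi <- max(geo$end[j] - invasion, 0L)
        }
        if (lo <= hi) ok[lo:hi] <- FALSE
    }
    ok
}

#' Cluster intergenic 3'-end positions
#'
#' Nonzero 3'-end positions are first restricted to the intergenic mask
#' (same-strand gene bodies shrunk by `invasion` nt at their 5' ends), then
#' partitioned so consecutive positions within a cluster are less than
#' `maxGap` nt apart.
#'
#' @param profile A 3'-end [EndProfile-class].
#' @param genes Gene `GRanges`.
#' @param strand `"+"` or `"-"`.
#' @param maxGap Clustering distance (default 10 nt).
#' @param invasion Allowed invasion into the downstream gene (default 10 nt).
#' @return A data.frame with `position`, `count`, `cluster` as in
#'   [clusterPositions()].
#' @export
clusterThreePrimePositions <- function(profile, genes, strand,
                                       maxGap = 10L, invasion = 10L) {
    stopifnot(is(profile, "EndProfile"))
    strand <- match.arg(strand, c("+", "-"))
    counts <- strandCounts(profile, strand)
    mask <- .intergenicMask(genes, strand, genomeLength(profile), invasion)
    pos <- which(counts > 0L & mask)
    data.frame(position = pos, count = counts[pos],
               cluster = .gapPartition(pos, maxGap))
}

#' Call TEP candidates from one Term-Seq replicate
#'
#' Every position of every intergenic cluster is scored with
#' [modifiedZscore()] over the cluster's counts; positions with
#' `count >= minReads` and `Z >= minZ` survive. All survivors are retained —
#' the selection of one representative per cluster happens at replicate
#' reconciliation.
#'
#' @param profile A 3'-end [EndProfile-class].
#' @param genes Gene `GRanges`.
#' @param minReads Read-count threshold (default 3).
#' @param minZ Modified z-score threshold (default 3).
#' @param maxGap,invasion Passed to [clusterThreePrimePositions()].
#' @return A data.frame of candidates: `position`, `strand`, `count`,
#'   `zscore`, `cluster_start`, `cluster_end` (span of the parent cluster).
#'   The spans of all clusters — including those without surviving
#'   candidates — are attached as attribute `"clusterSpans"` for use by
#'   [reconcileReplicates()].
#' @export
callTepsSingleReplicate <- function(profile, genes, minReads = 3L, minZ = 3,
                                    maxGap = 10L, invasion = 10L) {
    out <- list()
    spans <- list()
    for (st in c("+", "-")) {
        cl <- clusterThreePrimePositions(profile, genes, st, maxGap, invasion)
        if (nrow(cl) == 0L) next
        for (cid in unique(cl$cluster)) {
            rows <- cl[cl$cluster == cid, , drop = FALSE]
            z <- vapply(seq_len(nrow(rows)),
                        function(i) modifiedZscore(rows$count, i), numeric(1))
            keep <- rows$count >= minReads & z >= minZ
            spans[[length(spans) + 1L]] <- data.frame(
                strand = st, cluster_start = min(rows$position),
                cluster_end = max(rows$position), stringsAsFactors = FALSE)
            if (!any(keep)) next
            out[[length(out) + 1L]] <- data.frame(
                position = rows$position[keep], strand = st,
                count = rows$count[keep], zscore = z[keep],
                cluster_start = min(rows$position),
                cluster_end = max(rows$position),
                stringsAsFactors = FALSE)
        }
    }
    res <- if (!length(out))
        data.frame(position = integer(0), strand = character(0),
                   count = integer(0), zscore = numeric(0),
                   cluster_start = integer(0), cluster_end = integer(0))
    else do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "clusterSpans") <- if (length(spans)) do.call(rbind, spans)
        else data.frame(strand = character(0), cluster_start = integer(0),
                        cluster_end = integer(0))
    res
}

#' Reconcile TEP candidates from two biological replicates
#'
#' For each pair of overlapping same-strand cluster spans, candidates from
#' both replicates falling inside the span intersection are pooled, and the
#' position with the highest replicate-summed read count is emitted as the
#' TEP (ties resolve to the smaller coordinate). Cluster spans come from the
#' `"clusterSpans"` attribute of the candidate tables when present — i.e. all
#' clusters of each replicate, whether or not any of their positions survived
#' the filters — falling back to the spans carried by the surviving
#' candidates. When the per-replicate profiles are supplied, the summed count
#' at a position is looked up in both tracks; otherwise candidate counts are
#' summed by position.
#'
#' For example, clusters spanning 103-125 in one replicate and 113-142 in the
#' other restrict the selection to positions 113-125, reported in the
#' `region_start`/`region_end` columns.
#'
#' @param cands1,cands2 Candidate tables from [callTepsSingleReplicate()].
#' @param profile1,profile2 Optional [EndProfile-class]s of the two
#'   replicates, used for exact summed counts.
#' @return A data.frame in the `tep` schema with `category = NA` (call
#'   [classifyTEP()] next); `count` is the replicate-summed count.
#' @export
reconcileReplicates <- function(cands1, cands2,
                                profile1 = NULL, profile2 = NULL) {
    spanTable <- function(cands, st) {
        sp <- attr(cands, "clusterSpans")
        if (is.null(sp)) {
            sub <- cands[cands$strand == st, , drop = FALSE]
            unique(sub[c("cluster_start", "cluster_end")])
        } else {
            sp[sp$strand == st, c("cluster_start", "cluster_end"),
               drop = FALSE]
        }
    }
    out <- list()
    for (st in c("+", "-")) {
        a <- cands1[cands1$strand == st, , drop = FALSE]
        b <- cands2[cands2$strand == st, , drop = FALSE]
        if (nrow(a) == 0L && nrow(b) == 0L) next
        spansA <- spanTable(cands1, st)
        spansB <- spanTable(cands2, st)
        if (nrow(spansA) == 0L || nrow(spansB) == 0L) next
        ov <- IRanges::findOverlaps(
            IRanges::IRanges(spansA$cluster_start, spansA$cluster_end),
            IRanges::IRanges(spansB$cluster_start, spansB$cluster_end))
        for (h in seq_along(ov)) {
            ia <- S4Vectors::queryHits(ov)[h]
            ib <- S4Vectors::subjectHits(ov)[h]
            lo <- max(spansA$cluster_start[ia], spansB$cluster_start[ib])
            hi <- min(spansA$cluster_end[ia], spansB$cluster_end[ib])
            pool <- sort(unique(c(
                a$position[a$cluster_start == spansA$cluster_start[ia] &
                           a$cluster_end == spansA$cluster_end[ia]],
                b$position[b$cluster_start == spansB$cluster_start[ib] &
                           b$cluster_end == spansB$cluster_end[ib]])))
            pool <- pool[pool >= lo & pool <= hi]
            if (!length(pool)) next
            if (!is.null(profile1) && !is.null(profile2)) {
                summed <- strandCounts(profile1, st)[pool] +
                    strandCounts(profile2, st)[pool]
            } else {
                cnt <- function(df, p) {
                    v <- df$count[df$position == p]
                    if (length(v)) v[1L] else 0L
                }
                summed <- vapply(pool, function(p)
                    cnt(a, p) + cnt(b, p), numeric(1))
            }
            best <- pool[which.max(summed)]   # tie -> smaller coordinate
            out[[length(out) + 1L]] <- data.frame(
                position = best, strand = st,
                count = as.integer(max(summed)),
                region_start = lo, region_end = hi,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out)) {
        res <- data.frame(position = integer(0), strand = character(0),
                          count = integer(0), region_start = integer(0),
                          region_end = integer(0))
    } else {
        res <- do.call(rbind, out)
        # a span may overlap several partners; keep one record per position
        res <- res[order(res$strand, res$position, -res$count), , drop = FALSE]
        res <- res[!duplicated(res[c("strand", "position")]), , drop = FALSE]
    }
    res$category <- rep(NA_character_, nrow(res))
    res$gene_id <- rep(NA_character_, nrow(res))
    res$utr3_length <- rep(NA_integer_, nrow(res))
    res$u_rich <- rep(NA, nrow(res))
    res <- res[c("position", "strand", "count", "category", "gene_id",
                 "utr3_length", "u_rich", "region_start", "region_end")]
    rownames(res) <- NULL
    res
}

#' Classify TEPs relative to genes and primary TSSs
#'
#' Precedence per TEP: (1) cis-regulatory (`C`) when it lies strand-aware
#' between a gene's primary TSS and that gene's start codon with a TSS-to-TEP
#' distance of at least `minCisDistance` (80 nt by default, the minimum
#' length for a terminator structure to form); only the highest-count C TEP
#' per gene is kept, the others are dropped from the output. (2) Otherwise
#' primary/secondary (`P`/`S`) when less than `downstreamMax` nt downstream
#' of a same-strand stop codon: per gene the highest count is `P`, the rest
#' `S` (tie: nearest stop), with `utr3_length` the stop-to-TEP distance.
#' (3) Otherwise antisense (`A`) over an opposite-strand ORF, (4) else
#' intergenic (`N`).
#'
#' @param teps Output of [reconcileReplicates()].
#' @param tss Classified TSS table ([classifyTSS()]), used for primary TSSs.
#' @param genes Gene `GRanges`.
#' @param downstreamMax P/S window downstream of stop codons (default 500 nt,
#'   strict).
#' @param minCisDistance Minimum primary-TSS-to-TEP distance for a
#'   cis-regulatory call (default 80 nt).
#' @return The TEP data.frame with categories assigned (C-duplicates
#'   removed).
#' @export
classifyTEP <- function(teps, tss, genes, downstreamMax = 500L,
                        minCisDistance = 80L) {
    geo <- .geneGeometry(genes)
    n <- nrow(teps)
    category <- rep("N", n)
    gene_id <- rep(NA_character_, n)
    utr3 <- rep(NA_integer_, n)

    ptss <- tss[tss$category == "P" & !is.na(tss$gene_id), , drop = FALSE]
    ptssPos <- stats::setNames(ptss$position, ptss$gene_id)

    for (i in seq_len(n)) {
        p <- teps$position[i]; st <- teps$strand[i]
        same <- which(geo$strand == st)

        # (1) cis-regulatory: between a gene's primary TSS and its start codon
        cisGene <- NA_character_
        cisBest <- Inf
        for (j in same) {
            g <- geo$gene_id[j]
            if (!g %in% names(ptssPos)) next
            t0 <- ptssPos[[g]]
            dT <- .dirDist(t0, p, st)          # TSS -> TEP, downstream > 0
            dS <- .dirDist(p, geo$start5[j], st)  # TEP -> start codon
            if (dT >= minCisDistance && dS >= 0 && dS < cisBest) {
                cisGene <- g
                cisBest <- dS
            }
        }
        if (!is.na(cisGene)) {
            category[i] <- "C"
            gene_id[i] <- cisGene
            next
        }

        # (2) primary/secondary: downstream of a same-strand stop codon
        if (length(same)) {
            d <- .dirDist(geo$stop3[same], p, st)
            ok <- d >= 0 & d < downstreamMax
            if (any(ok)) {
                cand <- same[ok]
                j <- cand[which.min(d[ok])]
                category[i] <- "S"   # promoted to P below
                gene_id[i] <- geo$gene_id[j]
                utr3[i] <- as.integer(.dirDist(geo$stop3[j], p, st))
                next
            }
        }

        # (3) antisense
        opp <- which(geo$strand != st)
        if (length(opp) && any(geo$start[opp] <= p & geo$end[opp] >= p))
            category[i] <- "A"
    }

    # per gene, keep only the highest-count cis-regulatory TEP
    drop <- logical(n)
    cis <- which(category == "C")
    for (g in unique(gene_id[cis])) {
        rows <- cis[gene_id[cis] == g]
        if (length(rows) > 1L) {
            best <- rows[which.max(teps$count[rows])]
            drop[setdiff(rows, best)] <- TRUE
        }
    }

    # per gene: max count -> P (tie -> nearest stop codon)
    ps <- which(category == "S")
    for (g in unique(gene_id[ps])) {
        rows <- ps[gene_id[ps] == g]
        best <- rows[teps$count[rows] == max(teps$count[rows])]
        if (length(best) > 1L) best <- best[which.min(utr3[best])]
        category[best] <- "P"
    }

    teps$category <- category
    teps$gene_id <- gene_id
    teps$utr3_length <- utr3
    teps <- teps[!drop, , drop = FALSE]
    rownames(teps) <- NULL
    teps
}
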