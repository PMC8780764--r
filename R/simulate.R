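## Synthetic transcript-architecture generator.
##
## Plants a transcription-unit layout (genes, TSSs, TEPs) on an i.i.d. GC-rich
## genome and simulates the five end-count tracks the boundary callers
## consume: TAP(+)/TAP(-) 5'-end profiles, two Term-Seq 3'-end replicates and
## strand-specific RNA-Seq coverage. Ground truth is returned for
## parameter-recovery testing.

# TSS 5'-end jitter: most reads start exactly at the initiation site
.TSS_JITTER_OFFSETS <- -1:1
.TSS_JITTER_PROBS <- c(0.15, 0.70, 0.15)
# TEP 3'-end jitter: modal position with shoulders, so clusters are peaked
.TEP_JITTER_OFFSETS <- -2:2
.TEP_JITTER_PROBS <- c(0.05, 0.15, 0.60, 0.15, 0.05)

#' Generate an i.i.d. genome with a target GC content
#'
#' Nucleotides are drawn independently with `P(G) = P(C) = gcFraction / 2`
#' and `P(A) = P(T) = (1 - gcFraction) / 2`. Deterministic under
#' `params@seed`.
#'
#' @param params A [SimParams-class].
#' @return A [Genome-class] named `"sim_genome"`.
#' @export
simulateGenome <- function(params) {
    stopifnot(is(params, "SimParams"))
    set.seed(params@seed)
    gc <- params@gcFraction
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seq <- paste(sample(names(p), params@genomeLength, replace = TRUE,
                        prob = p), collapse = "")
    Genome("sim_genome", seq)
}

# draw one 5'-UTR length: leaderless point mass near 0, else log-normal with
# mode ~35 nt (mode = exp(meanlog - sdlog^2))
.drawUtr5 <- function(pLeaderless = 0.2) {
    if (runif(1) < pLeaderless) {
        sample(0:5, 1L)
    } else {
        min(450L, max(9L, round(rlnorm(1, meanlog = log(35) + 0.36,
                                       sdlog = 0.6))))
    }
}

# 3'-UTR length: log-normal with mode ~60 nt
.drawUtr3 <- function() {
    min(450L, max(10L, round(rlnorm(1, meanlog = log(60) + 0.25,
                                    sdlog = 0.5))))
}

#' Plant a transcription-unit architecture on a genome
#'
#' Lays out non-overlapping transcription units along the genome, each with
#' one TSS and one TEP: `operonFraction` of TUs span 2-4 genes with intergenic
#' gaps drawn uniformly from 1-400 nt (inside the 500-nt operon rule), the
#' rest are single-gene. 5'-UTRs are leaderless (0-5 nt) with probability 0.2,
#' otherwise log-normal with mode ~35 nt; 3'-UTRs are log-normal with mode
#' ~60 nt. About half of the TEPs are flagged U-rich; for those, the 8
#' transcript-strand nt ending at the TEP are rewritten to contain >= 6 U(T)
#' and a 12-nt inverted repeat (hairpin stem) is planted upstream, so
#' sequence-level terminator signals exist for the element annotator.
#'
#' @param params A [SimParams-class].
#' @param genome Genome from [simulateGenome()].
#' @return A list with elements `genes` (a `GRanges` with `gene_id`), `truth`
#'   (list of data.frames `tss`, `tep`, `tu`) and `genome` (the input genome
#'   with U-rich terminator sequences written in).
#' @export
plantArchitecture <- function(params, genome) {
    stopifnot(is(params, "SimParams"), is(genome, "Genome"))
    set.seed(params@seed + 1L)
    L <- genomeLength(genome)
    margin <- 500L
    nGenes <- params@nGenes

    geneStart <- integer(0); geneEnd <- integer(0); geneStrand <- character(0)
    tssPos <- integer(0); tssStrand <- character(0)
    tssUtr5 <- integer(0); tssLeaderless <- logical(0)
    tepPos <- integer(0); tepStrand <- character(0)
    tepUtr3 <- integer(0); tepURich <- logical(0)
    tuTss <- integer(0); tuTep <- integer(0); tuStrand <- character(0)
    tuGenes <- character(0)

    cursor <- margin + 1L
    placed <- 0L
    while (placed < nGenes) {
        remaining <- nGenes - placed
        k <- if (remaining >= 2L && runif(1) < params@operonFraction)
                 min(sample(2:4, 1L), remaining) else 1L
        lens <- as.integer(round(pmin(pmax(
            rnorm(k, params@meanGeneLen, params@meanGeneLen / 4.5), 300),
            1600)))
        gaps <- if (k > 1L) sample(1:400, k - 1L, replace = TRUE) else integer(0)
        utr5 <- .drawUtr5()
        utr3 <- .drawUtr3()
        strand <- sample(c("+", "-"), 1L)
        span <- utr5 + sum(lens) + sum(gaps) + utr3
        if (cursor + span > L - margin) break

        ids <- sprintf("g%03d", placed + seq_len(k))
        if (strand == "+") {
            tss <- cursor
            s <- tss + utr5
            starts <- integer(k); ends <- integer(k)
            for (i in seq_len(k)) {
                starts[i] <- s
                ends[i] <- s + lens[i] - 1L
                s <- ends[i] + (if (i < k) gaps[i] else 0L) + 1L
            }
            tep <- ends[k] + utr3
            order5to3 <- seq_len(k)
        } else {
            tep <- cursor
            # transcript runs right-to-left; 5'-most gene is rightmost
            b <- cursor + span - 1L
            tss <- b
            e <- tss - utr5
            starts <- integer(k); ends <- integer(k)
            for (i in seq_len(k)) {        # i indexes transcription order
                ends[i] <- e
                starts[i] <- e - lens[i] + 1L
                e <- starts[i] - (if (i < k) gaps[i] else 0L) - 1L
            }
            order5to3 <- seq_len(k)
        }

        geneStart <- c(geneStart, starts)
        geneEnd <- c(geneEnd, ends)
        geneStrand <- c(geneStrand, rep(strand, k))
        tssPos <- c(tssPos, tss); tssStrand <- c(tssStrand, strand)
        tssUtr5 <- c(tssUtr5, utr5); tssLeaderless <- c(tssLeaderless, utr5 < 9)
        uFlag <- runif(1) < 0.5
        tepPos <- c(tepPos, tep); tepStrand <- c(tepStrand, strand)
        tepUtr3 <- c(tepUtr3, utr3); tepURich <- c(tepURich, uFlag)
        tuTss <- c(tuTss, tss); tuTep <- c(tuTep, tep)
        tuStrand <- c(tuStrand, strand)
        tuGenes <- c(tuGenes, paste(ids[order5to3], collapse = ","))
        placed <- placed + k
        cursor <- cursor + span + sample(600:1000, 1L)
    }
    if (placed < nGenes)
        stop(sprintf(
            "genome of %d nt too short for %d genes (placed %d); increase genomeLength",
            L, nGenes, placed))

    ord <- order(geneStart)
    genes <- GenomicRanges::GRanges(
        seqnames = genomeId(genome),
        ranges = IRanges::IRanges(geneStart[ord], geneEnd[ord]),
        strand = geneStrand[ord])
    genes$gene_id <- sprintf("g%03d", seq_len(placed))[ord]
    genes$kind <- "CDS"
    genes$product <- NA_character_

    # rewrite terminator sequence for U-rich TEPs (transcript-strand window of
    # 8 nt ending at the TEP gets >= 6 U, hairpin stem planted upstream)
    seqChars <- strsplit(genomeSeq(genome), "", fixed = TRUE)[[1]]
    for (i in which(tepURich)) {
        p <- tepPos[i]; st <- tepStrand[i]
        uWin <- rep("T", 8L)
        nonU <- sample(8L, 2L)
        uWin[nonU] <- sample(c("G", "C"), 2L, replace = TRUE)
        stem <- sample(c("G", "C", "G", "C", "A", "T"), 12L, replace = TRUE)
        loop <- sample(c("A", "C", "G", "T"), 5L, replace = TRUE)
        hairpin <- c(stem, loop, rev(chartr("ACGT", "TGCA", stem)))
        if (st == "+") {
            if (p - 7L >= 1L) seqChars[(p - 7L):p] <- uWin
            lo <- p - 8L - length(hairpin) + 1L
            if (lo >= 1L) seqChars[lo:(p - 8L)] <- hairpin
        } else {
            if (p + 7L <= L)
                seqChars[p:(p + 7L)] <- rev(chartr("ACGT", "TGCA", uWin))
            hi <- p + 8L + length(hairpin) - 1L
            if (hi <= L)
                seqChars[(p + 8L):hi] <- rev(chartr("ACGT", "TGCA", hairpin))
        }
    }
    genomeOut <- Genome(genomeId(genome), paste(seqChars, collapse = ""))

    truth <- list(
        tss = data.frame(position = tssPos, strand = tssStrand,
                         category = "P", utr5_length = tssUtr5,
                         leaderless = tssLeaderless,
                         stringsAsFactors = FALSE),
        tep = data.frame(position = tepPos, strand = tepStrand,
                         category = "P", utr3_length = tepUtr3,
                         u_rich = tepURich, stringsAsFactors = FALSE),
        tu = data.frame(tu_id = sprintf("truthTU%03d", seq_along(tuTss)),
                        tss_position = tuTss, tep_position = tuTep,
                        strand = tuStrand, gene_ids = tuGenes,
                        n_genes = lengths(strsplit(tuGenes, ",")),
                        category = ifelse(lengths(strsplit(tuGenes, ",")) > 1L,
                                          "poly_cistronic", "mono_cistronic"),
                        stringsAsFactors = FALSE)
    )
    list(genes = genes, truth = truth, genome = genomeOut)
}

# scatter n reads around position p with the given jitter distribution
.addSpikes <- function(vec, p, n, offsets, probs) {
    if (n <= 0L) return(vec)
    counts <- as.vector(stats::rmultinom(1L, n, probs))
    idx <- p + offsets
    ok <- idx >= 1L & idx <= length(vec)
    vec[idx[ok]] <- vec[idx[ok]] + counts[ok]
    vec
}

# uniform background end reads at `rate` per kb on one strand
.addNoise <- function(vec, rate) {
    n <- rpois(1L, rate * length(vec) / 1000)
    if (n > 0L) {
        pos <- sample.int(length(vec), n, replace = TRUE)
        tb <- tabulate(pos, nbins = length(vec))
        vec <- vec + tb
    }
    vec
}

#' Simulate sequencing end profiles from a planted architecture
#'
#' Produces five strand-specific tracks: `tap_plus` and `tap_minus` (5'-end
#' counts; each planted TSS contributes Poisson(`tssSignalMean`) reads with
#' +/-1 nt jitter to TAP(+) and Poisson(`tapMinusLeak` x `tssSignalMean`) to
#' TAP(-)), `termseq_rep1`/`termseq_rep2` (3'-end counts; each planted TEP
#' contributes Poisson(`tepSignalMean`) reads per replicate with independent
#' +/-2 nt jitter) and `rnaseq` (coverage: per-base Poisson(`coverageDepth`)
#' inside each TSS-TEP span). All end tracks also receive uniform background
#' reads at `noiseEndRate` per kb per strand. Deterministic under
#' `params@seed`.
#'
#' @param truth Truth list from [plantArchitecture()].
#' @param genes Gene `GRanges` (unused by the signal model, kept for the
#'   module interface).
#' @param genome The (possibly rewritten) [Genome-class].
#' @param params A [SimParams-class].
#' @return Named list of five [EndProfile-class] objects.
#' @export
simulateProfiles <- function(truth, genes, genome, params) {
    stopifnot(is(params, "SimParams"), is(genome, "Genome"))
    set.seed(params@seed + 2L)
    L <- genomeLength(genome)
    id <- genomeId(genome)

    tracks <- list(
        tap_plus = list(`+` = integer(L), `-` = integer(L)),
        tap_minus = list(`+` = integer(L), `-` = integer(L)),
        termseq_rep1 = list(`+` = integer(L), `-` = integer(L)),
        termseq_rep2 = list(`+` = integer(L), `-` = integer(L))
    )

    for (i in seq_len(nrow(truth$tss))) {
        p <- truth$tss$position[i]; st <- truth$tss$strand[i]
        n <- rpois(1L, params@tssSignalMean)
        tracks$tap_plus[[st]] <- .addSpikes(tracks$tap_plus[[st]], p, n,
                                            .TSS_JITTER_OFFSETS,
                                            .TSS_JITTER_PROBS)
        m <- rpois(1L, params@tapMinusLeak * params@tssSignalMean)
        tracks$tap_minus[[st]] <- .addSpikes(tracks$tap_minus[[st]], p, m,
                                             .TSS_JITTER_OFFSETS,
                                             .TSS_JITTER_PROBS)
    }
    for (i in seq_len(nrow(truth$tep))) {
        p <- truth$tep$position[i]; st <- truth$tep$strand[i]
        for (rep in c("termseq_rep1", "termseq_rep2")) {
            n <- rpois(1L, params@tepSignalMean)
            tracks[[rep]][[st]] <- .addSpikes(tracks[[rep]][[st]], p, n,
                                              .TEP_JITTER_OFFSETS,
                                              .TEP_JITTER_PROBS)
        }
    }
    for (nm in names(tracks)) {
        for (st in c("+", "-"))
            tracks[[nm]][[st]] <- .addNoise(tracks[[nm]][[st]],
                                            params@noiseEndRate)
    }

    cov <- list(`+` = integer(L), `-` = integer(L))
    for (st in c("+", "-")) {
        occ <- numeric(L)
        rows <- which(truth$tu$strand == st)
        for (i in rows) {
            lo <- min(truth$tu$tss_position[i], truth$tu$tep_position[i])
            hi <- max(truth$tu$tss_position[i], truth$tu$tep_position[i])
            occ[lo:hi] <- occ[lo:hi] + 1
        }
        cov[[st]] <- rpois(L, params@coverageDepth * occ)
    }

    list(
        tap_plus = EndProfile(id, L, "five_prime_end", "tap_plus",
                              tracks$tap_plus$`+`, tracks$tap_plus$`-`),
        tap_minus = EndProfile(id, L, "five_prime_end", "tap_minus",
                               tracks$tap_minus$`+`, tracks$tap_minus$`-`),
        termseq_rep1 = EndProfile(id, L, "three_prime_end", "termseq_rep1",
                                  tracks$termseq_rep1$`+`,
                                  tracks$termseq_rep1$`-`),
        termseq_rep2 = EndProfile(id, L, "three_prime_end", "termseq_rep2",
                                  tracks$termseq_rep2$`+`,
                                  tracks$termseq_rep2$`-`),
        rnaseq = EndProfile(id, L, "coverage", "rnaseq",
                            cov$`+`, cov$`-`)
    )
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulateGenome()], [plantArchitecture()] and
#' [simulateProfiles()].
#'
#' @param params A [SimParams-class] (default [simParams()]).
#' @return A list with `genome`, `genes`, `truth`, `profiles` and `params`.
#' @examples
#' sim <- simulateDataset(simParams(genomeLength = 20000, nGenes = 8, seed = 3))
#' nrow(sim$truth$tss)
#' @export
simulateDataset <- function(params = simParams()) {
    genome0 <- simulateGenome(params)
    arch <- plantArchitecture(params, genome0)
    profiles <- simulateProfiles(arch$truth, arch$genes, arch$genome, params)
    list(genome = arch$genome, genes = arch$genes, truth = arch$truth,
         profiles = profiles, params = params)
}

#' Write a simulated dataset to disk
#'
#' Writes FASTA, GFF3, a bedGraph pair per profile and the truth tables as
#' TSV, mirroring the on-disk interface of the callers.
#'
#' @param sim Result of [simulateDataset()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, `outdir`.
#' @export
writeSimulatedDataset <- function(sim, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeGenome(sim$genome, file.path(outdir, "genome.fa"))
    writeAnnotation(sim$genes, file.path(outdir, "genes.gff3"))
    for (nm in names(sim$profiles))
        writeEndProfile(sim$profiles[[nm]], file.path(outdir, nm))
    for (nm in names(sim$truth))
        write.table(sim$truth[[nm]],
                    file.path(outdir, sprintf("truth_%s.tsv", nm)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(outdir)
}
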