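#' Run the full transcript-boundary pipeline
#'
#' Convenience wrapper chaining the callers on a set of end profiles: TSS
#' calling and classification, TEP calling per replicate, replicate
#' reconciliation, TEP classification with U-richness flags, TU assembly and
#' TU clustering.
#'
#' @param profiles Named list with elements `tap_plus`, `tap_minus`,
#'   `termseq_rep1`, `termseq_rep2` (and optionally `rnaseq`), as produced by
#'   [simulateProfiles()] or [readEndProfile()].
#' @param genes Gene `GRanges`.
#' @param genome A [Genome-class].
#' @param variants TU enumeration mode, see [assembleTUs()].
#' @return A list with `tss`, `tep`, `tus` and `clusters` tables.
#' @examples
#' sim <- simulateDataset(simParams(genomeLength = 30000, nGenes = 12, seed = 2))
#' res <- runBoundaryPipeline(sim$profiles, sim$genes, sim$genome)
#' table(res$tss$category)
#' @export
runBoundaryPipeline <- function(profiles, genes, genome, variants = "all") {
    tss <- callTSS(profiles$tap_plus, profiles$tap_minus)
    tss <- classifyTSS(tss, genes)
    c1 <- callTepsSingleReplicate(profiles$termseq_rep1, genes)
    c2 <- callTepsSingleReplicate(profiles$termseq_rep2, genes)
    tep <- reconcileReplicates(c1, c2, profiles$termseq_rep1,
                               profiles$termseq_rep2)
    tep <- classifyTEP(tep, tss, genes)
    tep <- uRichness(tep, genome)
    tus <- assembleTUs(tss, tep, genes, variants = variants)
    clusters <- clusterTUs(tus)
    list(tss = tss, tep = tep, tus = tus, clusters = clusters)
}
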