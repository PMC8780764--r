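# Share simulated datasets between test files so each default-parameter seed
# is generated once per test run.
.simCache <- new.env(parent = emptyenv())

cachedSim <- function(seed) {
    key <- as.character(seed)
    if (is.null(.simCache[[key]]))
        .simCache[[key]] <- simulateDataset(simParams(seed = seed))
    .simCache[[key]]
}

.resultCache <- new.env(parent = emptyenv())

cachedPipeline <- function(seed) {
    key <- as.character(seed)
    if (is.null(.resultCache[[key]])) {
        sim <- cachedSim(seed)
        .resultCache[[key]] <- runBoundaryPipeline(sim$profiles, sim$genes,
                                                   sim$genome)
    }
    .resultCache[[key]]
}

# recall of `truth` positions by `called` within a strand-aware tolerance
matchRate <- function(called, truth, tol) {
    if (nrow(truth) == 0L) return(NA_real_)
    mean(vapply(seq_len(nrow(truth)), function(i)
        any(abs(called$position - truth$position[i]) <= tol &
                called$strand == truth$strand[i]), logical(1)))
}
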