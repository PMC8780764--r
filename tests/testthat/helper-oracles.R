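# Independent brute-force oracles.

# Direct transcription of the three modified z-score equations, with the
# leave-one-out mean written as (1 / (N - 1)) * (-r(x) + sum over cluster).
oracleModifiedZ <- function(counts, index) {
    N <- length(counts)
    r <- counts[index]
    mu <- (1 / (N - 1)) * (-r + sum(counts))
    mu2 <- (1 / (N - 1)) * (-r^2 + sum(counts^2))
    sigma <- sqrt(mu2 - mu^2)
    list(mu = mu, sigma = sigma, z = (r - mu) / sigma)
}

# O(n^2) transitive closure of "connected iff distance < maxGap";
# returns component labels parallel to positions
oraclePartition <- function(positions, maxGap) {
    n <- length(positions)
    comp <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) {
            for (j in seq_len(n)) {
                if (abs(positions[i] - positions[j]) < maxGap &&
                    comp[i] != comp[j]) {
                    m <- min(comp[i], comp[j])
                    comp[comp == comp[i] | comp == comp[j]] <- m
                    changed <- TRUE
                }
            }
        }
        if (!changed) break
    }
    comp
}

# canonical partition: list of sorted member vectors, ordered by minimum
canonicalPartition <- function(positions, labels) {
    parts <- split(positions, labels)
    parts <- lapply(parts, sort)
    unname(parts[order(vapply(parts, min, numeric(1)))])
}
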