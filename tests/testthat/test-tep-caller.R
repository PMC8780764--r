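# TEP calling: modified z-score, intergenic clustering, per-replicate
# filters, replicate reconciliation, classification.

test_that("modifiedZscore matches hand-computed values and edge contracts", {
    # others = {1,2,3}: mu = 2, mu2 = 14/3, sigma = sqrt(2/3)
    expect_equal(modifiedZscore(c(1, 2, 3, 10), 4), 8 / sqrt(2 / 3),
                 tolerance = 1e-12)
    expect_equal(modifiedZscore(c(1, 2, 3, 10), 4), 9.79795897,
                 tolerance = 1e-8)
    # uniform cluster: sigma = 0, r = mu -> 0
    expect_equal(modifiedZscore(c(5, 5, 5), 2), 0)
    # identical others, r > mu -> +Inf
    expect_equal(modifiedZscore(c(3, 3, 12), 3), Inf)
    # identical others, r < mu -> 0
    expect_equal(modifiedZscore(c(3, 3, 1), 3), 0)
    # singleton cluster -> +Inf
    expect_equal(modifiedZscore(7, 1), Inf)
    expect_error(modifiedZscore(c(1, 2), 3), "out of range")
    expect_error(modifiedZscore(numeric(0), 1), "nonempty")
})

test_that("modifiedZscore equals the printed-equation oracle on random clusters", {
    set.seed(202)
    for (rep in 1:200) {
        counts <- sample(0:100, sample(2:30, 1), replace = TRUE)
        idx <- sample(length(counts), 1)
        o <- oracleModifiedZ(counts, idx)
        z <- modifiedZscore(counts, idx)
        if (is.finite(o$sigma) && o$sigma > 1e-9) {
            expect_lt(abs(z - o$z), 1e-9)
        } else {
            # sigma = 0 branch: contract gives +Inf above the mean, else 0
            expect_equal(z, if (counts[idx] > o$mu) Inf else 0)
        }
    }
})

test_that("3'-end clustering is restricted to the intergenic mask", {
    genes <- makeGenes(1030, 1500, "+", "gA")
    prof <- makeProfile(3000,
                        plus = sparse(c(1000, 1005, 1020, 1037, 1200),
                                      c(4, 6, 5, 3, 9)),
                        orientation = "three_prime_end")
    cl <- clusterThreePrimePositions(prof, genes, "+")
    # 1200 lies mid-ORF -> excluded; 1037 is 8 nt into the gene's 5' end,
    # within the 10-nt invasion allowance -> retained
    expect_setequal(cl$position, c(1000, 1005, 1020, 1037))
    # gaps: 5 joins, 15 splits, 17 splits
    expect_equal(canonicalPartition(cl$position, cl$cluster),
                 list(c(1000, 1005), 1020, 1037))

    # minus-strand gene: its 5' end is the right edge
    genesM <- makeGenes(500, 900, "-", "gB")
    profM <- makeProfile(3000, minus = sparse(c(700, 893, 950), c(5, 5, 5)),
                         orientation = "three_prime_end")
    clM <- clusterThreePrimePositions(profM, genesM, "-")
    expect_setequal(clM$position, c(893, 950))   # 700 mid-ORF excluded
})

test_that("clusterThreePrimePositions agrees with the brute-force oracle", {
    set.seed(303)
    for (rep in 1:40) {
        n <- sample(1:50, 1)
        pos <- sort(sample(1:1500, n))
        prof <- makeProfile(1500, plus = sparse(pos, rep(2, n)),
                            orientation = "three_prime_end")
        cl <- clusterThreePrimePositions(prof, emptyGenes(), "+", maxGap = 10)
        expect_equal(canonicalPartition(cl$position, cl$cluster),
                     canonicalPartition(pos, oraclePartition(pos, 10)))
    }
})

test_that("single-replicate filters drop low counts and low z-scores", {
    # cluster [1,1,20]: the 20 survives (z = +Inf), the 1s fail count
    prof <- makeProfile(1000, plus = sparse(c(100, 102, 104), c(1, 1, 20)),
                        orientation = "three_prime_end")
    cands <- callTepsSingleReplicate(prof, emptyGenes())
    expect_equal(cands$position, 104L)
    expect_equal(cands$zscore, Inf)
    expect_equal(cands$cluster_start, 100L)
    expect_equal(cands$cluster_end, 104L)

    # uniform cluster [3,3,3]: all fail the z filter
    prof2 <- makeProfile(1000, plus = sparse(c(200, 201, 202), c(3, 3, 3)),
                         orientation = "three_prime_end")
    expect_equal(nrow(callTepsSingleReplicate(prof2, emptyGenes())), 0L)

    # isolated position with 5 reads: singleton cluster survives by contract
    prof3 <- makeProfile(1000, plus = sparse(500, 5),
                         orientation = "three_prime_end")
    expect_equal(callTepsSingleReplicate(prof3, emptyGenes())$position, 500L)

    # all cluster spans are reported, including ones without survivors
    spans <- attr(callTepsSingleReplicate(prof2, emptyGenes()),
                  "clusterSpans")
    expect_equal(spans$cluster_start, 200L)
    expect_equal(spans$cluster_end, 202L)
})

test_that("reconcileReplicates restricts selection to the span intersection", {
    # worked example: spans 103-125 and 113-142 -> selection inside 113-125
    c1 <- candTable(c(105, 118), c(20, 7), span = c(103, 125))
    c2 <- candTable(c(121, 140), c(12, 6), span = c(113, 142))
    res <- reconcileReplicates(c1, c2)
    expect_equal(nrow(res), 1L)
    expect_equal(res$region_start, 113L)
    expect_equal(res$region_end, 125L)
    # 105 (highest count overall) is outside the intersection; 140 too;
    # among {118: 7, 121: 12} the argmax wins
    expect_equal(res$position, 121L)
    expect_equal(res$count, 12L)

    # non-overlapping spans yield nothing
    c3 <- candTable(105, 9, span = c(100, 110))
    c4 <- candTable(205, 9, span = c(200, 210))
    expect_equal(nrow(reconcileReplicates(c3, c4)), 0L)

    # replicate-summed counts via profiles: 118 has 7 + 6, 121 has 12 + 0
    p1 <- makeProfile(300, plus = sparse(c(105, 118), c(20, 7)),
                      orientation = "three_prime_end")
    p2 <- makeProfile(300, plus = sparse(c(121, 140, 118), c(12, 6, 6)),
                      orientation = "three_prime_end")
    res2 <- reconcileReplicates(c1, c2, p1, p2)
    expect_equal(res2$position, 118L)
    expect_equal(res2$count, 13L)
})

test_that("classifyTEP applies C > P/S > A > N precedence", {
    genes <- makeGenes(1000, 2000, "+", "g1")
    tss <- tssRow(900, "+", 50, category = "P", gene_id = "g1", utr5 = 100L)

    # cis-regulatory needs >= 80 nt from the primary TSS
    res <- classifyTEP(rbind(tepRow(985, "+", 10), tepRow(960, "+", 10)),
                       tss, genes)
    expect_equal(res$category[res$position == 985], "C")
    expect_equal(res$gene_id[res$position == 985], "g1")
    # 60 nt from the TSS: not cis-regulatory, and upstream of the stop -> N
    expect_equal(res$category[res$position == 960], "N")

    # P/S downstream of the stop codon with utr3 lengths
    res2 <- classifyTEP(rbind(tepRow(2100, "+", 30), tepRow(2350, "+", 5)),
                        tss, genes)
    expect_equal(res2$category[res2$position == 2100], "P")
    expect_equal(res2$utr3_length[res2$position == 2100], 100L)
    expect_equal(res2$category[res2$position == 2350], "S")
    expect_equal(res2$utr3_length[res2$position == 2350], 350L)

    # beyond the 500-nt window -> intergenic
    res3 <- classifyTEP(tepRow(2600, "+", 5), tss, genes)
    expect_equal(res3$category, "N")

    # opposite strand over the ORF -> antisense
    res4 <- classifyTEP(tepRow(1500, "-", 5), tss, genes)
    expect_equal(res4$category, "A")

    # multiple cis-regulatory TEPs: only the highest count is kept
    res5 <- classifyTEP(rbind(tepRow(985, "+", 10), tepRow(990, "+", 25)),
                        tss, genes)
    expect_equal(nrow(res5), 1L)
    expect_equal(res5$position, 990L)
})

test_that("minus-strand TEP classification mirrors the geometry", {
    genes <- makeGenes(1000, 2000, "-", "gm")   # stop codon at 1000
    tss <- tssRow(2100, "-", 50, category = "P", gene_id = "gm", utr5 = 100L)
    res <- classifyTEP(rbind(tepRow(900, "-", 20), tepRow(2015, "-", 10)),
                       tss, genes)
    expect_equal(res$category[res$position == 900], "P")
    expect_equal(res$utr3_length[res$position == 900], 100L)
    expect_equal(res$category[res$position == 2015], "C")  # 85 nt from TSS
})

test_that("emitted TEPs partition into categories with per-gene uniqueness", {
    res <- cachedPipeline(1)$tep
    expect_true(all(res$category %in% c("P", "S", "C", "A", "N")))
    p <- res[res$category == "P", ]
    expect_false(any(duplicated(p$gene_id)))
    cis <- res[res$category == "C", ]
    expect_false(any(duplicated(cis$gene_id)))
    # every emitted TEP lies inside its replicate-intersection region
    expect_true(all(res$position >= res$region_start &
                        res$position <= res$region_end))
    expect_true(all(res$count >= 3L))
})
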