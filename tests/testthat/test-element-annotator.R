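# Element annotation: read-density profiles, nucleotide enrichment,
# intergenic background, promoter elements, UTR statistics, U-richness,
# heptameric repeats.

anchorDf <- function(position, strand = "+")
    data.frame(position = position,
               strand = rep(strand, length.out = length(position)),
               stringsAsFactors = FALSE)

test_that("readDensity normalizes per anchor and averages across anchors", {
    # constant coverage in the window -> density 1 everywhere
    prof <- makeProfile(2000, plus = sparse(1:2000, rep(5, 2000)),
                        orientation = "coverage")
    d <- readDensity(anchorDf(1000), prof)
    expect_true(all(d$density == 1))
    expect_equal(attr(d, "nPositions"), 1L)

    # single spike at the anchor -> density 1 at offset 0, 0 elsewhere
    prof2 <- makeProfile(2000, plus = sparse(1000, 10),
                         orientation = "coverage")
    d2 <- readDensity(anchorDf(1000), prof2)
    expect_equal(d2$density[d2$offset == 0], 1)
    expect_equal(sum(d2$density), 1)

    # two anchors: profile is the mean of the per-anchor profiles
    prof3 <- makeProfile(3000, plus = sparse(c(1000, 2005), c(10, 8)),
                         orientation = "coverage")
    d3 <- readDensity(anchorDf(c(1000, 2000)), prof3)
    expect_equal(d3$density[d3$offset == 0], 0.5)
    expect_equal(d3$density[d3$offset == 5], 0.5)
    expect_equal(sum(d3$density), 1)

    # minus-strand offsets are mirrored: genomic p-5 is offset +5
    prof4 <- makeProfile(2000, minus = sparse(c(1000, 995), c(4, 8)),
                         orientation = "coverage")
    d4 <- readDensity(anchorDf(1000, "-"), prof4)
    expect_equal(d4$density[d4$offset == 5], 1)
    expect_equal(d4$density[d4$offset == 0], 0.5)

    # anchors with empty windows are skipped; all-empty errors
    expect_error(readDensity(anchorDf(integer(0)), prof), "empty")
    profZero <- makeProfile(2000, orientation = "coverage")
    expect_error(readDensity(anchorDf(1000), profZero), "devoid of signal")
    expect_equal(attr(readDensity(anchorDf(c(300, 1000)), prof2),
                      "nPositions"), 1L)
})

test_that("density is bounded in [0, 1]", {
    sim <- cachedSim(1)
    d <- readDensity(sim$truth$tss, sim$profiles$rnaseq)
    expect_true(all(d$density >= 0 & d$density <= 1))
})

test_that("nucleotideEnrichment divides anchor by background frequencies", {
    # genome with a controlled single position: all anchors on T
    genome <- Genome("g", paste0(strrep("A", 24), "T",
                                 "A", "C", "G", "T", strrep("A", 21)))
    anchors <- anchorDf(25)             # base T
    background <- anchorDf(26:29)       # A, C, G, T -> 25% each
    enr <- nucleotideEnrichment(anchors, genome, background,
                                window = c(0L, 0L))
    expect_equal(enr$ratio[enr$nucleotide == "U"], 4)
    expect_equal(enr$anchor_freq[enr$nucleotide == "U"], 1)

    # anchors identical to background -> ratio 1 wherever defined
    enr2 <- nucleotideEnrichment(background, genome, background,
                                 window = c(-2L, 2L))
    defined <- enr2$anchor_freq > 0
    expect_true(all(enr2$ratio[defined] == 1))

    # minus-strand anchor over genomic A is counted as U
    enr3 <- nucleotideEnrichment(anchorDf(30, "-"), genome, background,
                                 window = c(0L, 0L))
    expect_equal(enr3$anchor_freq[enr3$nucleotide == "U"], 1)

    # zero background frequency with nonzero anchor frequency errors
    bgA <- anchorDf(c(10, 11))          # all A
    expect_error(nucleotideEnrichment(anchors, genome, bgA,
                                      window = c(0L, 0L)),
                 "offset")
})

test_that("intergenic background sampling avoids gene bodies, fixed by seed", {
    genome <- Genome("g", strrep("ACGT", 500))    # 2000 nt
    genes <- makeGenes(1, 1000, "+", "g1", id = "g")
    bg <- sampleIntergenicBackground(genes, genome, 500, seed = 3)
    expect_true(all(bg$position > 1000))
    expect_equal(nrow(bg), 500L)
    bg2 <- sampleIntergenicBackground(genes, genome, 500, seed = 3)
    expect_identical(bg, bg2)
    expect_false(any(duplicated(bg$position)))

    # fully genic genome -> capacity error
    genesAll <- makeGenes(1, 2000, "+", "g1", id = "g")
    expect_error(sampleIntergenicBackground(genesAll, genome, 10),
                 "intergenic positions")
})

test_that("promoter elements are found in their windows with the spacer", {
    # region of 41 nt ending at the TSS: CCC TTGACA C*19 TATAAT CCCCCCC
    region <- paste0("CCC", "TTGACA", strrep("C", 19), "TATAAT",
                     strrep("C", 7))
    expect_equal(nchar(region), 41L)
    genome <- Genome("g", paste0(strrep("A", 100), region, strrep("A", 100)))
    tss <- tssRow(141, "+", 10, category = "P")
    ann <- annotatePromoters(tss, genome)
    expect_equal(ann$minus35_seq, "TTGACA")
    expect_equal(ann$minus35_offset, -37L)
    expect_equal(ann$minus10_seq, "TATAAT")
    expect_equal(ann$minus10_offset, -12L)
    expect_equal(ann$spacer_length, 19L)

    # same promoter on the minus strand
    genomeM <- Genome("g", paste0(strrep("T", 100),
                                  tuarchitect:::.revcomp(region),
                                  strrep("T", 100)))
    annM <- annotatePromoters(tssRow(101, "-", 10), genomeM)
    expect_equal(annM$minus10_seq, "TATAAT")
    expect_equal(annM$spacer_length, 19L)

    # an exact TANNNT instance: TAGGGT has 0 incompatibilities
    region2 <- paste0(strrep("C", 25), "TAGGGT", strrep("C", 10))
    genome2 <- Genome("g", paste0(strrep("A", 50), region2, strrep("A", 20)))
    ann2 <- annotatePromoters(tssRow(91, "+", 10), genome2)
    expect_equal(ann2$minus10_seq, "TAGGGT")

    # all-C windows: > 2 incompatibilities -> element absent
    genome3 <- Genome("g", strrep("C", 200))
    ann3 <- annotatePromoters(tssRow(100, "+", 10), genome3)
    expect_true(is.na(ann3$minus10_seq))
    expect_true(is.na(ann3$minus35_seq))
    expect_true(is.na(ann3$spacer_length))

    # too close to the edge -> skipped with a warning
    expect_warning(ann4 <- annotatePromoters(tssRow(10, "+", 10), genome3),
                   "skipped")
    expect_true(is.na(ann4$minus10_seq))
})

test_that("promoter annotation is invariant under coordinate shifts", {
    region <- paste0("CCC", "TTGACA", strrep("C", 19), "TATAAT",
                     strrep("C", 7))
    for (pad in c(50, 137)) {
        genome <- Genome("g", paste0(strrep("A", pad), region,
                                     strrep("A", 60)))
        ann <- annotatePromoters(tssRow(pad + 41L, "+", 10), genome)
        expect_equal(ann$minus10_offset, -12L)
        expect_equal(ann$minus35_offset, -37L)
        expect_equal(ann$spacer_length, 19L)
    }
})

test_that("UTR statistics bin lengths and count leaderless/long leaders", {
    tss <- rbind(
        tssRow(1, "+", 9, category = "P", gene_id = "a", utr5 = 35L),
        tssRow(2, "+", 9, category = "P", gene_id = "b", utr5 = 8L),
        tssRow(3, "+", 9, category = "P", gene_id = "c", utr5 = 151L),
        tssRow(4, "+", 9, category = "S", gene_id = "a", utr5 = 400L))
    teps <- rbind(
        tepRow(10, "+", 9, category = "P", gene_id = "a", utr3 = 64L),
        tepRow(11, "+", 9, category = "S", gene_id = "a", utr3 = 300L))
    st <- utrStatistics(tss, teps)
    expect_equal(st$n_primary_tss, 3L)
    expect_equal(st$utr5_hist$count[st$utr5_hist$bin_label == "30-39"], 1L)
    expect_equal(st$leaderless$count, 1L)       # 8 < 9
    expect_equal(st$leaderless$fraction, 1 / 3)
    expect_equal(st$long_leader$count, 1L)      # 151 > 150
    # secondary records do not enter the histograms
    expect_equal(sum(st$utr5_hist$count), 3L)
    expect_equal(st$utr3_hist$bin_label, "60-69")
})

test_that("U-richness flags terminator windows by U content", {
    # + strand: last 8 nt before/at the TEP are TTCTTTGT (6 U) and GCGCGCGC
    genome <- Genome("g", paste0(strrep("A", 92), "TTCTTTGT",
                                 strrep("A", 20), "GCGCGCGC",
                                 strrep("A", 20)))
    teps <- rbind(tepRow(100, "+"), tepRow(128, "+"))
    res <- uRichness(teps, genome)
    expect_equal(res$u_rich, c(TRUE, FALSE))

    # - strand: genomic AAAAAAAA reads as UUUUUUUU on the transcript
    resM <- uRichness(tepRow(110, "-"), genome)
    expect_true(resM$u_rich)

    # planted U-rich TEPs in the simulator are recovered at the defaults
    sim <- cachedSim(3)
    tr <- sim$truth$tep
    res2 <- uRichness(tr, sim$genome)
    expect_gte(mean(res2$u_rich[tr$u_rich]), 0.9)
})

test_that("heptameric repeats need consensus matches at 4 or 15 nt spacing", {
    hep <- "TGAGCGA"
    filler <- function(n) strrep("C", n)
    # window of 150 nt ending just before the TSS, repeat with 4-nt spacing
    win4 <- paste0(filler(60), hep, filler(4), hep, filler(150 - 60 - 18))
    expect_equal(nchar(win4), 150L)
    genome <- Genome("g", paste0(filler(30), win4, filler(30)))
    tss <- tssRow(30 + 150 + 1, "+", 10)
    sites <- findHeptamerRepeats(tss, genome, hep)
    expect_equal(nrow(sites), 1L)
    expect_equal(sites$spacing, 4L)
    expect_equal(sites$heptamer1, hep)
    expect_equal(sites$score, 14L)
    # offsets locate the heptamers inside the upstream window
    expect_equal(sites$offset1, 61L - 151L)
    expect_equal(sites$offset2, 72L - 151L)

    # same pair at 10-nt spacing: not reported
    win10 <- paste0(filler(60), hep, filler(10), hep, filler(150 - 60 - 24))
    genome10 <- Genome("g", paste0(filler(30), win10, filler(30)))
    expect_equal(nrow(findHeptamerRepeats(tss, genome10, hep)), 0L)

    # one heptamer with 2 mismatches under maxMismatch = 1: not reported
    hepMM <- "TGACCGT"   # 2 mismatches to TGAGCGA
    winMM <- paste0(filler(60), hep, filler(4), hepMM,
                    filler(150 - 60 - 18))
    genomeMM <- Genome("g", paste0(filler(30), winMM, filler(30)))
    expect_equal(nrow(findHeptamerRepeats(tss, genomeMM, hep)), 0L)
    # ... but reported at maxMismatch = 2 with a reduced score
    sitesMM <- findHeptamerRepeats(tss, genomeMM, hep, maxMismatch = 2)
    expect_equal(nrow(sitesMM), 1L)
    expect_equal(sitesMM$score, 12L)

    # 15-nt spacing on the minus strand
    win15 <- paste0(filler(40), hep, filler(15), hep, filler(150 - 40 - 29))
    genomeM <- Genome("g", paste0(filler(30),
                                  tuarchitect:::.revcomp(win15),
                                  filler(30)))
    sitesM <- findHeptamerRepeats(tssRow(30, "-", 10), genomeM, hep)
    expect_equal(sitesM$spacing, 15L)
})
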