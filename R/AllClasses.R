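#' @import methods
#' @importFrom stats rpois rlnorm rnorm runif sd
#' @importFrom utils read.delim write.table
NULL

## ---------------------------------------------------------------------------
## Genome
## ---------------------------------------------------------------------------

#' Genome: a single reference sequence
#'
#' Holds one chromosome/contig as an upper-case DNA string over the alphabet
#' \{A, C, G, T, N\}. Bacterial transcript-boundary analysis in this package is
#' single-replicon, so a `Genome` carries exactly one sequence.
#'
#' @slot id Character scalar, sequence identifier.
#' @slot sequence Character scalar, upper-case DNA sequence.
#'
#' @seealso [readGenome()], [simulateGenome()]
#' @export
setClass("Genome", representation(id = "character", sequence = "character"))

setValidity("Genome", function(object) {
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        return("'id' must be a single non-empty string")
    if (length(object@sequence) != 1L || is.na(object@sequence))
        return("'sequence' must be a single string")
    if (nchar(object@sequence) < 1L)
        return("sequence must be non-empty")
    bad <- regexpr("[^ACGTN]", object@sequence)
    if (bad > 0L)
        return(sprintf("invalid character '%s' at position %d (alphabet is ACGTN)",
                       substr(object@sequence, bad, bad), bad))
    TRUE
})

#' Construct a Genome
#'
#' Lower-case input is normalized to upper case; any character outside
#' \{A,C,G,T,N\} raises an error naming the offending position.
#'
#' @param id Sequence identifier.
#' @param sequence DNA sequence (character scalar).
#' @return A [Genome-class] object.
#' @examples
#' g <- Genome("g", "acgtn")
#' genomeSeq(g)   # "ACGTN"
#' @export
Genome <- function(id, sequence) {
    sequence <- toupper(as.character(sequence))
    new("Genome", id = as.character(id), sequence = sequence)
}

#' @describeIn Genome-class sequence identifier
#' @param x A `Genome`.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname Genome-class
#' @export
setMethod("genomeId", "Genome", function(x) x@id)

#' @describeIn Genome-class the DNA sequence as a character scalar
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname Genome-class
#' @export
setMethod("genomeSeq", "Genome", function(x) x@sequence)

#' @describeIn Genome-class sequence length in nucleotides
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname Genome-class
#' @export
setMethod("genomeLength", "Genome", function(x) nchar(x@sequence))

setMethod("show", "Genome", function(object) {
    n <- nchar(object@sequence)
    gc <- .gcFraction(object@sequence)
    cat(sprintf("Genome '%s': %d nt, GC %.1f%%\n", object@id, n, 100 * gc))
})

#' Extract a sub-sequence from a Genome
#'
#' @param genome A [Genome-class].
#' @param start,end 1-based inclusive coordinates.
#' @return Character scalar (forward strand).
#' @export
genomeSubseq <- function(genome, start, end) {
    stopifnot(is(genome, "Genome"))
    L <- genomeLength(genome)
    if (start < 1L || end > L || start > end)
        stop(sprintf("subsequence [%d, %d] outside genome of length %d",
                     start, end, L))
    substr(genome@sequence, start, end)
}

## ---------------------------------------------------------------------------
## EndProfile
## ---------------------------------------------------------------------------

.PROFILE_ORIENTATIONS <- c("five_prime_end", "three_prime_end", "coverage")

#' EndProfile: strand-specific per-base read counts
#'
#' A dense, strand-specific per-base count track for one sequencing library.
#' Depending on `orientation` the counts are transcript 5' ends (dRNA-Seq),
#' transcript 3' ends (Term-Seq) or plain read coverage (RNA-Seq). Positions
#' are 1-based; absent signal is count 0.
#'
#' @slot genomeId Character, identifier of the genome the track belongs to.
#' @slot genomeLength Integer, genome length (nt).
#' @slot orientation One of `"five_prime_end"`, `"three_prime_end"`,
#'   `"coverage"`.
#' @slot libraryTag Character label, e.g. `"tap_plus"`, `"termseq_rep1"`.
#' @slot countsPlus,countsMinus Integer vectors of length `genomeLength`,
#'   non-negative.
#'
#' @seealso [readEndProfile()], [simulateProfiles()], [strandCounts()]
#' @export
setClass("EndProfile", representation(
    genomeId = "character",
    genomeLength = "integer",
    orientation = "character",
    libraryTag = "character",
    countsPlus = "integer",
    countsMinus = "integer"
))

setValidity("EndProfile", function(object) {
    if (!object@orientation %in% .PROFILE_ORIENTATIONS)
        return(sprintf("orientation must be one of %s",
                       paste(.PROFILE_ORIENTATIONS, collapse = ", ")))
    L <- object@genomeLength
    if (length(L) != 1L || is.na(L) || L < 1L)
        return("genomeLength must be a positive integer")
    if (length(object@countsPlus) != L || length(object@countsMinus) != L)
        return("count vectors must have length genomeLength")
    if (anyNA(object@countsPlus) || anyNA(object@countsMinus))
        return("counts must not contain NA")
    if (any(object@countsPlus < 0L) || any(object@countsMinus < 0L))
        return("counts must be non-negative")
    TRUE
})

#' Construct an EndProfile
#'
#' @param genomeId Genome identifier.
#' @param genomeLength Genome length (nt).
#' @param orientation `"five_prime_end"`, `"three_prime_end"` or `"coverage"`.
#' @param libraryTag Free-text library label.
#' @param countsPlus,countsMinus Integer per-base counts (default all zero).
#' @return An [EndProfile-class] object.
#' @export
EndProfile <- function(genomeId, genomeLength,
                       orientation = c("five_prime_end", "three_prime_end",
                                       "coverage"),
                       libraryTag = "track",
                       countsPlus = NULL, countsMinus = NULL) {
    orientation <- match.arg(orientation)
    genomeLength <- as.integer(genomeLength)
    if (is.null(countsPlus)) countsPlus <- integer(genomeLength)
    if (is.null(countsMinus)) countsMinus <- integer(genomeLength)
    new("EndProfile", genomeId = as.character(genomeId),
        genomeLength = genomeLength, orientation = orientation,
        libraryTag = as.character(libraryTag),
        countsPlus = as.integer(countsPlus),
        countsMinus = as.integer(countsMinus))
}

#' Per-base counts of one strand
#'
#' @param x An [EndProfile-class].
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of length `genomeLength(x)`.
#' @export
setGeneric("strandCounts", function(x, strand) standardGeneric("strandCounts"))

#' @rdname strandCounts
#' @export
setMethod("strandCounts", "EndProfile", function(x, strand) {
    strand <- match.arg(strand, c("+", "-"))
    if (strand == "+") x@countsPlus else x@countsMinus
})

#' @describeIn EndProfile-class library label
#' @param x An `EndProfile`.
#' @export
setGeneric("libraryTag", function(x) standardGeneric("libraryTag"))

#' @rdname EndProfile-class
#' @export
setMethod("libraryTag", "EndProfile", function(x) x@libraryTag)

#' @rdname Genome-class
#' @export
setMethod("genomeId", "EndProfile", function(x) x@genomeId)

#' @rdname Genome-class
#' @export
setMethod("genomeLength", "EndProfile", function(x) x@genomeLength)

setMethod("show", "EndProfile", function(object) {
    cat(sprintf("EndProfile '%s' (%s) on '%s' [%d nt]\n",
                object@libraryTag, object@orientation, object@genomeId,
                object@genomeLength))
    cat(sprintf("  + strand: %d positions, %d reads\n",
                sum(object@countsPlus > 0L), sum(object@countsPlus)))
    cat(sprintf("  - strand: %d positions, %d reads\n",
                sum(object@countsMinus > 0L), sum(object@countsMinus)))
})

## ---------------------------------------------------------------------------
## SimParams
## ---------------------------------------------------------------------------

#' SimParams: synthetic-dataset parameters
#'
#' Parameters of the synthetic transcript-architecture generator. Defaults
#' emulate the study conditions the analysis assumes: a GC-rich (70%)
#' single-replicon genome, sharp TAP(+)-enriched 5'-end pileups at planted
#' TSSs, reproducible Term-Seq 3'-end pileups at planted TEPs, plateau RNA-Seq
#' coverage over each transcription unit and sparse spurious end reads.
#'
#' @slot genomeLength Genome length in nt.
#' @slot gcFraction Genomic G+C fraction in `[0, 1]`.
#' @slot nGenes Number of ORFs to plant.
#' @slot meanGeneLen Mean ORF length (nt).
#' @slot operonFraction Fraction of transcription units spanning >= 2 genes.
#' @slot tssSignalMean Mean TAP(+) read count per planted TSS (Poisson).
#' @slot tapMinusLeak Fraction of the TAP(+) signal leaking into TAP(-).
#' @slot tepSignalMean Mean Term-Seq read count per planted TEP per replicate.
#' @slot noiseEndRate Spurious end reads per kb per strand per library.
#' @slot coverageDepth Mean per-base RNA-Seq coverage within transcripts.
#' @slot seed Integer seed fixing all randomness.
#'
#' @seealso [simParams()], [simulateDataset()]
#' @export
setClass("SimParams", representation(
    genomeLength = "integer", gcFraction = "numeric", nGenes = "integer",
    meanGeneLen = "numeric", operonFraction = "numeric",
    tssSignalMean = "numeric", tapMinusLeak = "numeric",
    tepSignalMean = "numeric", noiseEndRate = "numeric",
    coverageDepth = "numeric", seed = "integer"
))

setValidity("SimParams", function(object) {
    chkFrac <- function(v, nm) {
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            sprintf("%s must be in [0, 1]", nm) else NULL
    }
    msgs <- c(
        if (object@genomeLength < 1000L) "genomeLength must be >= 1000",
        chkFrac(object@gcFraction, "gcFraction"),
        chkFrac(object@operonFraction, "operonFraction"),
        chkFrac(object@tapMinusLeak, "tapMinusLeak"),
        if (object@nGenes < 1L) "nGenes must be >= 1",
        if (object@meanGeneLen < 100) "meanGeneLen must be >= 100",
        if (object@tssSignalMean <= 0) "tssSignalMean must be > 0",
        if (object@tepSignalMean <= 0) "tepSignalMean must be > 0",
        if (object@noiseEndRate < 0) "noiseEndRate must be >= 0",
        if (object@coverageDepth < 0) "coverageDepth must be >= 0"
    )
    if (length(msgs)) msgs else TRUE
})

#' Construct simulation parameters
#'
#' @param genomeLength Genome length in nt (default 100000).
#' @param gcFraction G+C fraction (default 0.70, a GC-rich actinobacterial
#'   genome).
#' @param nGenes Number of ORFs (default 60).
#' @param meanGeneLen Mean ORF length in nt (default 900).
#' @param operonFraction Fraction of multi-gene transcription units
#'   (default 0.4).
#' @param tssSignalMean Mean TAP(+) reads per planted TSS (default 50).
#' @param tapMinusLeak TAP(-) leak fraction (default 0.1).
#' @param tepSignalMean Mean Term-Seq reads per planted TEP per replicate
#'   (default 40).
#' @param noiseEndRate Spurious end reads per kb per strand (default 1.0).
#' @param coverageDepth Mean within-transcript coverage (default 30).
#' @param seed Integer seed (default 1).
#' @return A [SimParams-class] object.
#' @examples
#' simParams(seed = 7)
#' @export
simParams <- function(genomeLength = 100000L, gcFraction = 0.70,
                      nGenes = 60L, meanGeneLen = 900,
                      operonFraction = 0.4, tssSignalMean = 50,
                      tapMinusLeak = 0.1, tepSignalMean = 40,
                      noiseEndRate = 1.0, coverageDepth = 30, seed = 1L) {
    new("SimParams", genomeLength = as.integer(genomeLength),
        gcFraction = gcFraction, nGenes = as.integer(nGenes),
        meanGeneLen = meanGeneLen, operonFraction = operonFraction,
        tssSignalMean = tssSignalMean, tapMinusLeak = tapMinusLeak,
        tepSignalMean = tepSignalMean, noiseEndRate = noiseEndRate,
        coverageDepth = coverageDepth, seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams:\n")
    cat(sprintf("  genome %d nt, GC %.2f, %d genes (mean %.0f nt), operons %.0f%%\n",
                object@genomeLength, object@gcFraction, object@nGenes,
                object@meanGeneLen, 100 * object@operonFraction))
    cat(sprintf("  TSS signal %.0f (leak %.2f), TEP signal %.0f, noise %.2f/kb, coverage %.0f, seed %d\n",
                object@tssSignalMean, object@tapMinusLeak,
                object@tepSignalMean, object@noiseEndRate,
                object@coverageDepth, object@seed))
})
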