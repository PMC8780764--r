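## Readers and writers for the external formats of the pipeline:
## FASTA (genome), GFF3 (annotation), bedGraph pairs (strand-specific
## per-base end counts), TSV + BED6 (result tables).
## Internal coordinates are 1-based inclusive throughout; conversion to the
## 0-based half-open BED/bedGraph conventions happens only at this boundary.

#' Read a genome from a FASTA file
#'
#' Only the first record is used (single-replicon organisms); additional
#' records trigger a warning unless `id` selects one explicitly. Lower-case
#' bases are normalized to upper case; characters outside \{A,C,G,T,N\} raise
#' an error naming the offending position.
#'
#' @param path Path to a FASTA file.
#' @param id Optional record id to select when the file holds several.
#' @return A [Genome-class] object.
#' @export
readGenome <- function(path, id = NULL) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    seqs <- Biostrings::readBStringSet(path)
    if (length(seqs) == 0L)
        stop(sprintf("no FASTA records in %s", path))
    nms <- sub("\\s.*$", "", names(seqs))
    if (!is.null(id)) {
        k <- match(id, nms)
        if (is.na(k)) stop(sprintf("no FASTA record named '%s'", id))
    } else {
        k <- 1L
        if (length(seqs) > 1L)
            warning(sprintf("%d FASTA records; using the first ('%s')",
                            length(seqs), nms[1L]))
    }
    Genome(nms[k], as.character(seqs[[k]]))
}

#' Write a Genome to FASTA
#'
#' @param genome A [Genome-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGenome <- function(genome, path) {
    stopifnot(is(genome, "Genome"))
    x <- Biostrings::DNAStringSet(genomeSeq(genome))
    names(x) <- genomeId(genome)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' One record per CDS feature; `gene` features are used only when the file has
#' no CDS. Records are returned sorted by start coordinate. Coordinates must
#' lie within the genome and every kept feature must be stranded.
#'
#' @param path Path to a GFF3 file.
#' @param genome A [Genome-class] used for bounds checking.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id`, `kind`
#'   and `product`.
#' @export
readAnnotation <- function(path, genome) {
    stopifnot(is(genome, "Genome"))
    gr <- rtracklayer::import(path, format = "gff3")
    kind <- as.character(gr$type)
    keep <- kind == "CDS"
    if (!any(keep)) keep <- kind == "gene"
    if (!any(keep)) stop(sprintf("no CDS or gene features in %s", path))
    gr <- gr[keep]
    st <- as.character(GenomicRanges::strand(gr))
    if (any(st == "*"))
        stop("annotation contains features without strand")
    L <- genomeLength(genome)
    if (any(GenomicRanges::start(gr) < 1L) || any(GenomicRanges::end(gr) > L))
        stop(sprintf("annotation coordinates outside genome [1, %d]", L))
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$locus_tag
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids)) ids <- rep(NA_character_, length(gr))
    ids[is.na(ids)] <- sprintf("gene_%04d", which(is.na(ids)))
    if (anyDuplicated(ids)) stop("duplicated gene identifiers in annotation")
    prod <- gr$product
    if (is.null(prod)) prod <- rep(NA_character_, length(gr))
    out <- GenomicRanges::GRanges(
        seqnames = genomeId(genome),
        ranges = IRanges::IRanges(GenomicRanges::start(gr),
                                  GenomicRanges::end(gr)),
        strand = st)
    out$gene_id <- as.character(ids)
    out$kind <- as.character(gr$type)
    out$product <- as.character(prod)
    out[order(GenomicRanges::start(out))]
}

#' Write a gene annotation to GFF3
#'
#' @param genes A `GRanges` as returned by [readAnnotation()] or
#'   [plantArchitecture()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeAnnotation <- function(genes, path) {
    gr <- genes
    gr$type <- if (!is.null(genes$kind)) genes$kind else
        rep("CDS", length(gr))
    gr$ID <- genes$gene_id
    gr$source <- rep("tuarchitect", length(gr))
    gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

# expand one bedGraph file into a per-base integer vector of length L
.bedGraphToCounts <- function(path, L) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(track|browser|#)", lines)]
    v <- numeric(L)
    if (length(lines) == 0L) return(as.integer(v))
    gr <- rtracklayer::import(path, format = "bedGraph")
    sc <- gr$score
    if (any(sc < 0)) stop("negative bedGraph value")
    s <- GenomicRanges::start(gr)   # already converted to 1-based by import
    e <- GenomicRanges::end(gr)
    if (any(s < 1L) || any(e > L))
        stop(sprintf("bedGraph interval outside genome [1, %d]", L))
    for (k in seq_along(gr)) v[s[k]:e[k]] <- v[s[k]:e[k]] + sc[k]
    as.integer(round(v))
}

#' Read a strand-specific end profile from a pair of bedGraph files
#'
#' bedGraph intervals are the standard 0-based half-open dialect; an interval
#' `[s, e)` with value `v` contributes `v` to 1-based positions `s+1 .. e`.
#' Overlapping intervals are summed. An empty file yields an all-zero strand.
#'
#' @param plusPath,minusPath bedGraph files for the two strands.
#' @param genome A [Genome-class] for length/bounds.
#' @param orientation `"five_prime_end"`, `"three_prime_end"` or `"coverage"`.
#' @param libraryTag Library label stored in the profile.
#' @return An [EndProfile-class].
#' @export
readEndProfile <- function(plusPath, minusPath, genome,
                           orientation = c("five_prime_end",
                                           "three_prime_end", "coverage"),
                           libraryTag = "track") {
    stopifnot(is(genome, "Genome"))
    orientation <- match.arg(orientation)
    L <- genomeLength(genome)
    EndProfile(genomeId(genome), L, orientation, libraryTag,
               countsPlus = .bedGraphToCounts(plusPath, L),
               countsMinus = .bedGraphToCounts(minusPath, L))
}

# write one strand of counts as run-length-compressed bedGraph
.countsToBedGraph <- function(counts, genomeId, path) {
    r <- rle(counts)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    if (any(keep)) {
        gr <- GenomicRanges::GRanges(
            seqnames = genomeId,
            ranges = IRanges::IRanges(starts[keep], ends[keep]))
        gr$score <- r$values[keep]
        rtracklayer::export(gr, path, format = "bedGraph")
    } else {
        writeLines(character(0), path)
    }
    invisible(path)
}

#' Write an EndProfile as a pair of bedGraph files
#'
#' @param profile An [EndProfile-class].
#' @param prefix Output prefix; files `<prefix>_plus.bedgraph` and
#'   `<prefix>_minus.bedgraph` are written.
#' @return Invisibly, the two paths.
#' @export
writeEndProfile <- function(profile, prefix) {
    stopifnot(is(profile, "EndProfile"))
    paths <- paste0(prefix, c("_plus.bedgraph", "_minus.bedgraph"))
    .countsToBedGraph(strandCounts(profile, "+"), genomeId(profile), paths[1])
    .countsToBedGraph(strandCounts(profile, "-"), genomeId(profile), paths[2])
    invisible(paths)
}

## ---------------------------------------------------------------------------
## Feature tables (TSV + BED6 companions)
## ---------------------------------------------------------------------------

.FT_SCHEMAS <- list(
    tss = c(position = "integer", strand = "character",
            tap_plus_count = "integer", tap_minus_count = "integer",
            category = "character", gene_id = "character",
            utr5_length = "integer", leaderless = "logical"),
    tep = c(position = "integer", strand = "character", count = "integer",
            category = "character", gene_id = "character",
            utr3_length = "integer", u_rich = "logical",
            region_start = "integer", region_end = "integer"),
    tu = c(tu_id = "character", tss_position = "integer",
           tep_position = "integer", strand = "character",
           gene_ids = "character", n_genes = "integer",
           category = "character"),
    tu_cluster = c(cluster_id = "character", tu_ids = "character",
                   gene_ids = "character", n_tus = "integer",
                   n_genes = "integer")
)

.FT_SORT_KEY <- list(tss = "position", tep = "position",
                     tu = "tss_position", tu_cluster = "cluster_id")

.coerceSchema <- function(df, schema) {
    spec <- .FT_SCHEMAS[[schema]]
    missing <- setdiff(names(spec), names(df))
    if (length(missing))
        stop(sprintf("table lacks column(s) %s required by schema '%s'",
                     paste(missing, collapse = ", "), schema))
    df <- df[names(spec)]
    for (j in seq_along(spec)) {
        df[[j]] <- switch(spec[[j]],
                          integer = as.integer(df[[j]]),
                          character = as.character(df[[j]]),
                          logical = as.logical(df[[j]]))
    }
    df
}

#' Write a result table as TSV (plus BED6 companion for site tables)
#'
#' Rows are sorted by `(strand, coordinate)`. For the `tss` and `tep` schemas
#' a BED6 companion (`<path minus .tsv>.bed`, 0-based half-open) is written as
#' well.
#'
#' @param table A data.frame following one of the package's result schemas.
#' @param path Output TSV path.
#' @param schema One of `"tss"`, `"tep"`, `"tu"`, `"tu_cluster"`.
#' @param genomeId Chromosome name used in the BED companion.
#' @return Invisibly, `path`.
#' @seealso [readFeatureTable()]
#' @export
writeFeatureTable <- function(table, path,
                              schema = c("tss", "tep", "tu", "tu_cluster"),
                              genomeId = "genome") {
    schema <- match.arg(schema)
    df <- .coerceSchema(as.data.frame(table), schema)
    key <- .FT_SORT_KEY[[schema]]
    if (nrow(df)) {
        ord <- if ("strand" %in% names(df)) order(df$strand, df[[key]])
               else order(df[[key]])
        df <- df[ord, , drop = FALSE]
    }
    rownames(df) <- NULL
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    if (schema %in% c("tss", "tep") && nrow(df)) {
        bedPath <- sub("\\.tsv$", "", path)
        bedPath <- paste0(bedPath, ".bed")
        scoreCol <- if (schema == "tss") df$tap_plus_count else df$count
        bed <- data.frame(chrom = genomeId,
                          chromStart = df$position - 1L,
                          chromEnd = df$position,
                          name = ifelse(is.na(df$category), ".", df$category),
                          score = scoreCol,
                          strand = df$strand)
        write.table(bed, bedPath, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Read a result table written by [writeFeatureTable()]
#'
#' @param path TSV path.
#' @param schema One of `"tss"`, `"tep"`, `"tu"`, `"tu_cluster"`.
#' @return A data.frame with the schema's column types restored.
#' @export
readFeatureTable <- function(path,
                             schema = c("tss", "tep", "tu", "tu_cluster")) {
    schema <- match.arg(schema)
    spec <- .FT_SCHEMAS[[schema]]
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character", na.strings = "NA")
    if (nrow(df) == 0L) {
        out <- lapply(spec, function(tp) vector(tp, 0L))
        return(as.data.frame(out, stringsAsFactors = FALSE))
    }
    .coerceSchema(df, schema)
}
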