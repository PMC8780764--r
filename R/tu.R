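## Transcription-unit (TU) assembly: pairing classified TSSs with classified
## TEPs, enumerating poly-cistronic gene chains under the 500-bp intergenic
## rule, scanning 1 kbp downstream of antisense/intergenic TSSs, and grouping
## TUs that share genes into TU clusters.

# genes of one strand ordered 5'->3' in transcription direction
.strandOrder <- function(geo, st) {
    idx <- which(geo$strand == st)
    if (st == "+") idx[order(geo$start[idx])]
    else idx[order(geo$end[idx], decreasing = TRUE)]
}

#' Assemble transcription units from classified TSSs and TEPs
#'
#' Pairing rules: (a) every primary, secondary or internal TSS walks the
#' same-strand genes downstream of it (a gene counts only when fully covered,
#' i.e. its start codon is at or downstream of the TSS); the admissible chain
#' extends while consecutive gene-gene intergenic gaps do not exceed
#' `maxIntergenic` (the TSS-to-first-gene distance is not checked — the TSS
#' is already assigned within its association window). For every chain prefix
#' the TSS is paired with each same-strand primary/secondary TEP lying
#' strictly downstream of the prefix's last stop codon and strictly upstream
#' of the next same-strand gene start, yielding TU variants. (b) Each
#' cis-regulatory TEP pairs only with TSSs assigned to its own gene,
#' producing a gene-less TU. (c) Each antisense/intergenic TSS scans
#' `scanWindow` nt downstream: if a same-strand TEP occurs before any gene
#' start codon, a gene-less TU is formed; if a gene start codon occurs first,
#' the TSS is treated as in (a) starting at that gene.
#'
#' Categories are assigned by [classifyTUs()].
#'
#' @param tss Classified TSS table ([classifyTSS()]).
#' @param teps Classified TEP table ([classifyTEP()]).
#' @param genes Gene `GRanges`.
#' @param maxIntergenic Maximum intergenic gap inside a TU (default 500 nt).
#' @param scanWindow Downstream scan for antisense/intergenic TSSs
#'   (default 1000 nt).
#' @param variants `"all"` enumerates every admissible TSS-TEP combination;
#'   `"first"` keeps only the nearest TEP per chain prefix.
#' @param cisDistance Gene-less TUs closer than this to the next downstream
#'   gene start are cis-regulatory, farther ones sRNA (default 500 nt).
#' @return A data.frame in the `tu` schema: `tu_id`, `tss_position`,
#'   `tep_position`, `strand`, `gene_ids` (comma-separated, 5'->3'),
#'   `n_genes`, `category`.
#' @export
assembleTUs <- function(tss, teps, genes, maxIntergenic = 500L,
                        scanWindow = 1000L, variants = c("all", "first"),
                        cisDistance = 500L) {
    variants <- match.arg(variants)
    if (any(tss$category == "U") || any(is.na(teps$category)))
        stop("TSS and TEP tables must be classified first")
    geo <- .geneGeometry(genes)

    rec <- list()
    addTU <- function(tssPos, tepPos, st, geneIds) {
        rec[[length(rec) + 1L]] <<- list(tss = tssPos, tep = tepPos,
                                         strand = st, genes = geneIds)
    }

    psTeps <- teps[teps$category %in% c("P", "S"), , drop = FALSE]
    scanTeps <- teps[teps$category != "C", , drop = FALSE]

    # (a) chain walk from one TSS given the 5'->3' ordered index of its first
    # fully-covered gene
    chainWalk <- function(tssPos, st, ord, firstIdx) {
        chain <- firstIdx
        repeat {
            last <- chain[length(chain)]
            if (last >= length(ord)) break
            gap <- .dirDist(geo$stop3[ord[last]],
                            geo$start5[ord[last + 1L]], st) - 1L
            if (gap > maxIntergenic) break
            chain <- c(chain, last + 1L)
        }
        stTeps <- psTeps[psTeps$strand == st, , drop = FALSE]
        for (k in seq_along(chain)) {
            gk <- ord[chain[k]]
            nextStart <- if (chain[k] < length(ord))
                .dirDist(geo$stop3[gk], geo$start5[ord[chain[k] + 1L]], st)
                else Inf
            dTep <- .dirDist(geo$stop3[gk], stTeps$position, st)
            ok <- dTep > 0 & dTep < nextStart &
                .dirDist(tssPos, stTeps$position, st) > 0
            if (!any(ok)) next
            hits <- which(ok)
            if (variants == "first")
                hits <- hits[which.min(dTep[hits])]
            for (h in hits)
                addTU(tssPos, stTeps$position[h], st,
                      geo$gene_id[ord[chain[seq_len(k)]]])
        }
    }

    for (st in c("+", "-")) {
        ord <- .strandOrder(geo, st)
        start5 <- geo$start5[ord]

        # (a) primary / secondary / internal TSSs
        aRows <- which(tss$strand == st & tss$category %in% c("P", "S", "I"))
        for (i in aRows) {
            p <- tss$position[i]
            covered <- which(.dirDist(p, start5, st) >= 0)
            if (!length(covered)) next
            chainWalk(p, st, ord, min(covered))
        }

        # (c) antisense / intergenic TSSs: 1-kbp downstream scan,
        # nearest feature (TEP vs gene start codon) wins
        cRows <- which(tss$strand == st & tss$category %in% c("A", "N"))
        stScan <- scanTeps[scanTeps$strand == st, , drop = FALSE]
        for (i in cRows) {
            p <- tss$position[i]
            dT <- .dirDist(p, stScan$position, st)
            dT <- dT[dT > 0 & dT <= scanWindow]
            dG <- .dirDist(p, start5, st)
            gIdx <- which(dG > 0 & dG <= scanWindow)
            dTep <- if (length(dT)) min(dT) else Inf
            dGene <- if (length(gIdx)) min(dG[gIdx]) else Inf
            if (!is.finite(dTep) && !is.finite(dGene)) next
            if (dTep <= dGene) {
                addTU(p, p + .dirOf(st) * as.integer(dTep), st, character(0))
            } else {
                firstIdx <- gIdx[which.min(dG[gIdx])]
                chainWalk(p, st, ord, firstIdx)
            }
        }
    }

    # (b) cis-regulatory TEPs pair only with TSSs assigned to their gene
    cTeps <- teps[teps$category == "C", , drop = FALSE]
    for (i in seq_len(nrow(cTeps))) {
        g <- cTeps$gene_id[i]
        mates <- which(tss$gene_id %in% g & tss$category %in% c("P", "S") &
                       tss$strand == cTeps$strand[i])
        for (m in mates) {
            if (.dirDist(tss$position[m], cTeps$position[i],
                         cTeps$strand[i]) <= 0) next
            addTU(tss$position[m], cTeps$position[i], cTeps$strand[i],
                  character(0))
        }
    }

    if (!length(rec)) {
        tus <- data.frame(tu_id = character(0), tss_position = integer(0),
                          tep_position = integer(0), strand = character(0),
                          gene_ids = character(0), n_genes = integer(0),
                          category = character(0))
        return(tus)
    }
    tus <- data.frame(
        tss_position = vapply(rec, `[[`, numeric(1), "tss"),
        tep_position = vapply(rec, `[[`, numeric(1), "tep"),
        strand = vapply(rec, `[[`, character(1), "strand"),
        gene_ids = vapply(rec, function(r)
            paste(r$genes, collapse = ","), character(1)),
        stringsAsFactors = FALSE)
    tus <- tus[!duplicated(tus), , drop = FALSE]
    tus <- tus[order(tus$strand, tus$tss_position, tus$tep_position), ,
               drop = FALSE]
    tus$n_genes <- ifelse(nzchar(tus$gene_ids),
                          lengths(strsplit(tus$gene_ids, ",")), 0L)
    tus$tu_id <- sprintf("TU%04d", seq_len(nrow(tus)))
    rownames(tus) <- NULL
    tus <- tus[c("tu_id", "tss_position", "tep_position", "strand",
                 "gene_ids", "n_genes")]
    classifyTUs(tus, genes, cisDistance = cisDistance)
}

#' Categorize transcription units
#'
#' TUs with two or more associated genes are poly-cistronic, with one gene
#' mono-cistronic. Gene-less TUs are cis-regulatory when the strand-aware
#' distance from their TSS to the nearest downstream same-strand gene start
#' codon is below `cisDistance`, and sRNA otherwise.
#'
#' @param tus TU table from [assembleTUs()] (category column may be absent).
#' @param genes Gene `GRanges`.
#' @param cisDistance Threshold distinguishing cis-regulatory from sRNA TUs
#'   (default 500 nt).
#' @return The TU table with a `category` column.
#' @export
classifyTUs <- function(tus, genes, cisDistance = 500L) {
    geo <- .geneGeometry(genes)
    n <- nrow(tus)
    category <- character(n)
    for (i in seq_len(n)) {
        if (tus$n_genes[i] >= 2L) { category[i] <- "poly_cistronic"; next }
        if (tus$n_genes[i] == 1L) { category[i] <- "mono_cistronic"; next }
        st <- tus$strand[i]
        same <- which(geo$strand == st)
        d <- .dirDist(tus$tss_position[i], geo$start5[same], st)
        d <- d[d >= 0]
        category[i] <- if (length(d) && min(d) < cisDistance)
            "cis_regulatory" else "sRNA"
    }
    tus$category <- category
    tus
}

#' Group transcription units into TU clusters
#'
#' A TU cluster is a maximal set of TUs connected by shared genes: the
#' connected components of the bipartite TU-gene graph, restricted to
#' gene-containing TUs. Gene-less TUs form singleton clusters.
#'
#' @param tus Classified TU table.
#' @return A data.frame in the `tu_cluster` schema: `cluster_id`, `tu_ids`,
#'   `gene_ids` (comma-separated), `n_tus`, `n_genes`.
#' @export
clusterTUs <- function(tus) {
    withGenes <- tus[tus$n_genes > 0L, , drop = FALSE]
    clusters <- list()
    if (nrow(withGenes)) {
        geneLists <- strsplit(withGenes$gene_ids, ",")
        edges <- data.frame(
            tu = rep(paste0("tu:", withGenes$tu_id), lengths(geneLists)),
            gene = paste0("gene:", unlist(geneLists)),
            stringsAsFactors = FALSE)
        g <- igraph::graph_from_data_frame(edges, directed = FALSE)
        comp <- igraph::components(g)
        memb <- comp$membership
        for (cid in seq_len(comp$no)) {
            vs <- names(memb)[memb == cid]
            tuIds <- sub("^tu:", "", vs[startsWith(vs, "tu:")])
            geneIds <- sub("^gene:", "", vs[startsWith(vs, "gene:")])
            clusters[[length(clusters) + 1L]] <- list(
                tu_ids = sort(tuIds), gene_ids = sort(geneIds))
        }
    }
    for (id in tus$tu_id[tus$n_genes == 0L])
        clusters[[length(clusters) + 1L]] <- list(tu_ids = id,
                                                  gene_ids = character(0))
    data.frame(
        cluster_id = sprintf("TUC%04d", seq_along(clusters)),
        tu_ids = vapply(clusters, function(cl)
            paste(cl$tu_ids, collapse = ","), character(1)),
        gene_ids = vapply(clusters, function(cl)
            paste(cl$gene_ids, collapse = ","), character(1)),
        n_tus = vapply(clusters, function(cl)
            length(cl$tu_ids), integer(1)),
        n_genes = vapply(clusters, function(cl)
            length(cl$gene_ids), integer(1)),
        stringsAsFactors = FALSE)
}
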