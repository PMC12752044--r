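#' Read gene models from a GTF file
#'
#' Builds a \code{\linkS4class{GeneModelSet}} from \code{gene},
#' \code{transcript}, \code{exon} and \code{CDS} features. Exons from all
#' transcripts of a gene are merged (union) into a single non-overlapping,
#' sorted exon set. The first coding base in transcription order is derived
#' from CDS features: the minimum CDS coordinate for \code{+} strand genes
#' and the maximum CDS coordinate for \code{-} strand genes; genes without
#' CDS features are treated as non-coding. If a transcript appears without
#' an enclosing gene feature, a gene record is synthesized from the
#' transcript span with a warning.
#'
#' @param gtf_path path to a GTF file with attributes \code{gene_id} and,
#'   optionally, \code{gene_name} and \code{gene_type}.
#' @return a \code{GeneModelSet}
#' @examples
#' gtf <- system.file("extdata", "toy_genes.gtf", package = "fuseval")
#' gm <- readGeneModels(gtf)
#' gm
#' @importFrom rtracklayer import
#' @importFrom GenomicRanges reduce
#' @importFrom IRanges subsetByOverlaps
#' @export
readGeneModels <- function(gtf_path) {
    if (!file.exists(gtf_path))
        stop("GTF file not found: ", gtf_path)
    .checkGtfLines(gtf_path)
    gr <- rtracklayer::import(gtf_path, format = "gtf")
    if (!"gene_id" %in% colnames(mcols(gr)))
        stop("GTF lacks gene_id attributes: ", gtf_path)
    type <- as.character(gr$type)

    genes <- gr[type == "gene"]
    tx <- gr[type == "transcript"]
    orphan <- setdiff(unique(tx$gene_id), unique(genes$gene_id))
    if (length(orphan)) {
        warning("synthesizing gene records from transcript spans for: ",
                paste(orphan, collapse = ", "))
        for (gid in orphan) {
            t <- tx[tx$gene_id == gid]
            syn <- GRanges(seqnames(t)[1],
                           IRanges(min(start(t)), max(end(t))),
                           strand = strand(t)[1])
            mcols(syn) <- mcols(t)[1, , drop = FALSE]
            suppressWarnings(genes <- c(genes, syn))
        }
    }
    if (length(genes) == 0L)
        stop("no gene or transcript features in GTF: ", gtf_path)
    if (any(width(genes) < 1L))
        stop("rejected gene record with end < start in: ", gtf_path)

    gid <- as.character(genes$gene_id)
    sym <- if ("gene_name" %in% colnames(mcols(genes)))
        as.character(genes$gene_name) else gid
    sym[is.na(sym)] <- gid[is.na(sym)]
    biotype <- if ("gene_type" %in% colnames(mcols(genes)))
        as.character(genes$gene_type) else rep(NA_character_, length(genes))

    exons <- gr[type == "exon"]
    cds <- gr[type == "CDS"]
    exl <- vector("list", length(genes))
    coding_start <- rep(NA_real_, length(genes))
    for (i in seq_along(genes)) {
        ex <- exons[exons$gene_id == gid[i]]
        ex <- if (length(ex)) reduce(sort(granges(ex))) else granges(genes[i])
        strand(ex) <- strand(genes)[i]
        exl[[i]] <- ex
        gc <- cds[cds$gene_id == gid[i]]
        if (length(gc)) {
            coding_start[i] <- if (as.character(strand(genes)[i]) == "-")
                max(end(gc)) else min(start(gc))
        }
    }
    g <- granges(genes)
    mcols(g) <- DataFrame(gene_id = gid, symbol = sym, biotype = biotype,
                          coding_start = coding_start)
    names(exl) <- gid
    new("GeneModelSet", genes = g, exons = GRangesList(exl))
}

## cheap structural scan so malformed lines are reported with their number
.checkGtfLines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    body <- !startsWith(lines, "#") & nzchar(lines)
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- which(body)[nf < 9L]
    if (length(bad))
        stop("malformed GTF line ", bad[1L], " in ", path,
             " (expected >= 9 tab-separated fields)")
    invisible(TRUE)
}

#' Gene-level ranges of a GeneModelSet
#' @param x a \code{GeneModelSet}
#' @return a \code{GRanges} with one range per gene
#' @export
geneRanges <- function(x) {
    stopifnot(is(x, "GeneModelSet"))
    x@genes
}

#' Exon structure of a GeneModelSet
#' @param x a \code{GeneModelSet}
#' @return a \code{GRangesList} named by gene id
#' @export
exonsByGene <- function(x) {
    stopifnot(is(x, "GeneModelSet"))
    x@exons
}

#' Look up a single gene by id or symbol
#'
#' @param x a \code{GeneModelSet}
#' @param key a gene id or gene symbol.
#' @return a one-row \code{GRanges}, or \code{NULL} when absent. Symbol
#'   lookup returns the first match when a symbol is ambiguous.
#' @export
getGene <- function(x, key) {
    g <- geneRanges(x)
    i <- match(key, mcols(g)$gene_id)
    if (is.na(i)) i <- match(key, mcols(g)$symbol)
    if (is.na(i)) return(NULL)
    g[i]
}

#' Genes covering a genomic point
#'
#' Point query against the gene interval index; boundaries are inclusive
#' (a position equal to the gene start or end is inside the gene).
#'
#' @param x a \code{GeneModelSet}
#' @param chrom chromosome name
#' @param pos 1-based position
#' @return a \code{GRanges} of covering genes (possibly empty)
#' @importFrom IRanges subsetByOverlaps
#' @export
genesAtPoint <- function(x, chrom, pos) {
    q <- GRanges(chrom, IRanges(pos, pos))
    subsetByOverlaps(geneRanges(x), q, ignore.strand = TRUE)
}

#' Transcription-order endpoints of a gene
#'
#' \code{txStart} is the first transcribed genomic position (genomic start
#' for \code{+} genes, genomic end for \code{-} genes); \code{txEnd} is the
#' last.
#'
#' @param gene a one-row \code{GRanges}
#' @return a genomic position
#' @export
txStart <- function(gene) {
    if (as.character(strand(gene)) == "-") end(gene) else start(gene)
}

#' @rdname txStart
#' @export
txEnd <- function(gene) {
    if (as.character(strand(gene)) == "-") start(gene) else end(gene)
}

#' Compare two positions in transcription order
#'
#' Returns TRUE when \code{a} strictly precedes \code{b} along the
#' transcription direction of \code{strand}.
#'
#' @param a,b genomic positions
#' @param strand \code{"+"} or \code{"-"}
#' @return logical
#' @export
txPrecedes <- function(a, b, strand) {
    ifelse(strand == "-", a > b, a < b)
}
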