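#' Pre-validation filtering of fusion calls
#'
#' Applies the pre-validation filters: (1) both junctions must fall inside
#' the genomic coordinates \code{[start, end]} of their named partner gene
#' (inclusive boundaries; a junction in a gene's flank but outside the gene
#' body counts as intergenic, as does a caller-reported intergenic site or
#' a partner symbol absent from the gene set); (2) the event must involve
#' two distinct genes; (3) for Arriba calls, both transcribed strands must
#' have been predicted; (4) for STAR-Fusion calls, neither partner may
#' match the immunoglobulin superlocus pattern. Each dropped call receives
#' exactly one primary reason, checked in the order ig_superlocus,
#' intergenic_junction, not_two_gene_fusion, strand_unpredicted (IG first
#' because IG-superlocus genes are typically absent from the gene
#' annotation and would otherwise register as intergenic).
#'
#' Filtering is idempotent: re-filtering the kept set drops nothing.
#'
#' @param calls a \code{\linkS4class{FusionCallSet}}.
#' @param genes a \code{\linkS4class{GeneModelSet}}.
#' @param ig_pattern regular expression identifying immunoglobulin
#'   superlocus symbols (configurable; default \code{"^IG[HKL]@?"}).
#' @return a list with elements \code{kept} (a \code{FusionCallSet}) and
#'   \code{dropped} (a \code{DataFrame} of dropped calls with a
#'   \code{reason} column drawn from \code{intergenic_junction},
#'   \code{not_two_gene_fusion}, \code{strand_unpredicted},
#'   \code{ig_superlocus}).
#' @examples
#' gtf <- system.file("extdata", "toy_genes.gtf", package = "fuseval")
#' gm <- readGeneModels(gtf)
#' @export
filterCalls <- function(calls, genes, ig_pattern = "^IG[HKL]@?") {
    df <- fusionCalls(calls)
    n <- nrow(df)
    reason <- rep(NA_character_, n)

    inGene <- function(symbol, id, chrom, pos) {
        g <- NULL
        if (!is.na(id)) g <- getGene(genes, id)
        if (is.null(g)) g <- getGene(genes, symbol)
        if (is.null(g)) return(FALSE)
        as.character(seqnames(g)) == chrom && pos >= start(g) && pos <= end(g)
    }

    for (i in seq_len(n)) {
        ## IG check first: IG-superlocus genes are typically absent from
        ## the gene annotation, and their exclusion is a distinct rule,
        ## not an intergenic-junction call
        if (df$caller[i] == "starfusion" &&
            (grepl(ig_pattern, df$gene5[i]) || grepl(ig_pattern, df$gene3[i]))) {
            reason[i] <- "ig_superlocus"
            next
        }
        bad5 <- !inGene(df$gene5[i], df$gene_id5[i], df$chrom5[i], df$pos5[i])
        bad3 <- !inGene(df$gene3[i], df$gene_id3[i], df$chrom3[i], df$pos3[i])
        site_ig <- identical(df$site5[i], "intergenic") ||
            identical(df$site3[i], "intergenic")
        if (bad5 || bad3 || site_ig) {
            if ((bad5 && is.null(getGene(genes, df$gene5[i]))) ||
                (bad3 && is.null(getGene(genes, df$gene3[i]))))
                warning("call ", df$gene5[i], "::", df$gene3[i],
                        " references a gene absent from the gene set")
            reason[i] <- "intergenic_junction"
            next
        }
        if (df$gene5[i] == df$gene3[i]) {
            reason[i] <- "not_two_gene_fusion"
            next
        }
        if (df$caller[i] == "arriba" &&
            (df$transcribed_strand5[i] == "unknown" ||
             df$transcribed_strand3[i] == "unknown")) {
            reason[i] <- "strand_unpredicted"
        }
    }
    keep <- is.na(reason)
    dropped <- DataFrame(df[!keep, , drop = FALSE])
    dropped$reason <- reason[!keep]
    list(kept = FusionCallSet(df[keep, , drop = FALSE]), dropped = dropped)
}

#' Write a filter report as TSV
#'
#' One row per input call with a \code{kept} flag and, for dropped calls,
#' the primary reason.
#'
#' @param report the list returned by \code{\link{filterCalls}}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeFilterReport <- function(report, path) {
    fmt <- function(df, kept) {
        if (nrow(df) == 0L) return(NULL)
        data.frame(cell_line = df$cell_line, caller = df$caller,
                   gene5 = df$gene5, gene3 = df$gene3,
                   junction5 = paste0(df$chrom5, ":", df$pos5),
                   junction3 = paste0(df$chrom3, ":", df$pos3),
                   kept = kept,
                   reason = if (kept) "" else df$reason,
                   stringsAsFactors = FALSE)
    }
    out <- rbind(fmt(as.data.frame(fusionCalls(report$kept)), TRUE),
                 fmt(as.data.frame(report$dropped), FALSE))
    if (is.null(out))
        out <- data.frame(cell_line = character(), caller = character(),
                          gene5 = character(), gene3 = character(),
                          junction5 = character(), junction3 = character(),
                          kept = logical(), reason = character())
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
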