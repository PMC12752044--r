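#' Build strand-aware search regions for a fusion call
#'
#' The 5' partner's search area spans, in transcription order, from the
#' fusion junction to the transcriptional gene end; the 3' partner's spans
#' from the transcriptional gene start to the junction. The junction-side
#' boundary is then extended by \code{junction_flank} and the gene-end-side
#' boundary by \code{gene_flank}, with extension directions resolved by the
#' gene strand, so the returned genomic intervals always satisfy
#' start <= end.
#'
#' For a \code{+} strand 5' partner spanning 10000-20000 with junction at
#' 15000 and default flanks, the region is 14500-22000; the mirrored
#' \code{-} strand case (gene 50000-60000, junction 54000) gives
#' 48000-54500.
#'
#' @param call a single-row \code{FusionCallSet} or a one-row call
#'   data.frame.
#' @param genes a \code{GeneModelSet}.
#' @param params a \code{\linkS4class{ValidationParams}}.
#' @return a list with elements \code{five_prime} and \code{three_prime},
#'   each a list with \code{chrom}, \code{start}, \code{end}, \code{role},
#'   \code{gene} (one-row \code{GRanges}) and \code{junction}.
#' @export
buildSearchRegions <- function(call, genes, params = validationParams()) {
    df <- if (is(call, "FusionCallSet")) as.data.frame(call) else
        as.data.frame(call)
    stopifnot(nrow(df) == 1L)
    g5 <- .resolveOrStop(genes, df$gene_id5, df$gene5, df)
    g3 <- .resolveOrStop(genes, df$gene_id3, df$gene3, df)
    list(five_prime = .searchRegion(g5, df$pos5, "five_prime", params),
         three_prime = .searchRegion(g3, df$pos3, "three_prime", params))
}

.resolveOrStop <- function(genes, id, symbol, df) {
    g <- NULL
    if (!is.na(id)) g <- getGene(genes, id)
    if (is.null(g)) g <- getGene(genes, symbol)
    if (is.null(g))
        stop("cannot resolve partner gene '", symbol, "' for call ",
             df$gene5, "::", df$gene3, " in ", df$cell_line)
    g
}

## One side's region. The 5' role runs junction -> transcriptional gene
## end; the 3' role runs transcriptional gene start -> junction. Flanks
## extend each boundary outward along the genome.
.searchRegion <- function(gene, junction, role, params) {
    str <- as.character(strand(gene))
    jf <- params@junction_flank
    gf <- params@gene_flank
    if (role == "five_prime") {
        if (str == "-") {            # transcriptional gene end = genomic start
            s <- start(gene) - gf
            e <- junction + jf
        } else {
            s <- junction - jf
            e <- end(gene) + gf
        }
    } else {
        if (str == "-") {            # transcriptional gene start = genomic end
            s <- junction - jf
            e <- end(gene) + gf
        } else {
            s <- start(gene) - gf
            e <- junction + jf
        }
    }
    list(chrom = as.character(seqnames(gene)), start = max(1, s), end = e,
         role = role, gene = gene, junction = junction)
}
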