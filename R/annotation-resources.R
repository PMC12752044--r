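#' Read annotation resource tables
#'
#' Loads the resource files used to annotate validated fusions:
#' \itemize{
#'   \item kinases: TSV with columns \code{symbol}, \code{group}
#'     (kinase group, e.g. AGC, CAMK, CMGC, STE, TK, TKL, CK1, Other,
#'     Atypical);
#'   \item mirnas: BED-like TSV with columns \code{chrom}, \code{start},
#'     \code{end}, \code{name}, \code{strand} (hairpin precursor
#'     coordinates, 1-based inclusive);
#'   \item known_fusions: TSV with columns \code{source}
#'     (\code{mitelman} or \code{tumorfusions}), \code{gene5},
#'     \code{gene3}, \code{tissue} and optional \code{junction5},
#'     \code{junction3} (\code{"chr:pos"});
#'   \item cancer_genes: one symbol per line;
#'   \item tissue_map: TSV with columns \code{sample_tissue},
#'     \code{db_tissue}, \code{relation} (\code{exact} or \code{related}).
#' }
#'
#' @param kinases,mirnas,known_fusions,cancer_genes,tissue_map file paths;
#'   any may be \code{NULL} to leave that layer empty.
#' @return a list of class \code{annotation_resources}.
#' @export
readAnnotationResources <- function(kinases = NULL, mirnas = NULL,
                                    known_fusions = NULL,
                                    cancer_genes = NULL, tissue_map = NULL) {
    rd <- function(p) if (is.null(p)) NULL else
        utils::read.delim(p, stringsAsFactors = FALSE)
    res <- list(
        kinases = rd(kinases),
        mirnas = rd(mirnas),
        known_fusions = rd(known_fusions),
        cancer_genes = if (is.null(cancer_genes)) character() else
            readLines(cancer_genes, warn = FALSE),
        tissue_map = rd(tissue_map))
    if (is.null(res$kinases))
        res$kinases <- data.frame(symbol = character(), group = character())
    if (is.null(res$mirnas))
        res$mirnas <- data.frame(chrom = character(), start = integer(),
                                 end = integer(), name = character(),
                                 strand = character())
    if (is.null(res$known_fusions))
        res$known_fusions <- data.frame(source = character(),
                                        gene5 = character(),
                                        gene3 = character(),
                                        tissue = character(),
                                        junction5 = character(),
                                        junction3 = character())
    if (is.null(res$tissue_map))
        res$tissue_map <- data.frame(sample_tissue = character(),
                                     db_tissue = character(),
                                     relation = character())
    res$cancer_genes <- res$cancer_genes[nzchar(res$cancer_genes)]
    class(res) <- "annotation_resources"
    res
}
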