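## Fusion-drug association analysis over a secondary drug-screen table:
## per-treatment concentration selection, eligible-gene identification,
## Welch tests and one global Benjamini-Hochberg correction.

#' Read a drug-screen response table
#'
#' @param path TSV with columns \code{cell_line}, \code{drug},
#'   \code{plate}, \code{concentration} (micromolar), \code{value}
#'   (replicate log2 fold change vs vehicle control) and optionally
#'   \code{replicate}.
#' @return a data.frame; a treatment is a (drug, plate) pair.
#' @export
readDrugResponses <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("cell_line", "drug", "plate", "concentration", "value")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("malformed response table ", path, ": missing column(s) ",
             paste(miss, collapse = ", "))
    df$concentration <- as.numeric(df$concentration)
    df$value <- as.numeric(df$value)
    if (any(is.na(df$concentration)) || any(df$concentration <= 0))
        stop("malformed response table ", path,
             ": concentrations must be positive numbers")
    df
}

#' Drop sparsely tested drug concentrations
#'
#' Per treatment (drug, plate), removes measurements at concentrations
#' tested in fewer than \code{min_coverage} of the screened cell lines
#' ("at least" semantics: exactly the threshold fraction is kept).
#'
#' @param responses response data.frame (see
#'   \code{\link{readDrugResponses}}).
#' @param cell_lines the screened cell-line universe; defaults to the
#'   cell lines present in \code{responses}.
#' @param min_coverage minimum fraction of cell lines (default 0.8).
#' @return the filtered response data.frame.
#' @export
filterConcentrations <- function(responses,
                                 cell_lines = unique(responses$cell_line),
                                 min_coverage = 0.8) {
    n_univ <- length(cell_lines)
    key <- paste(responses$drug, responses$plate, responses$concentration,
                 sep = "\r")
    cov <- vapply(split(responses$cell_line, key),
                  function(cl) length(unique(cl)) / n_univ, numeric(1))
    keep <- cov[key] >= min_coverage
    responses[keep, , drop = FALSE]
}

#' Select one concentration per treatment
#'
#' Chooses the concentration with the smallest absolute difference from
#' the mean of the treatment's remaining concentrations; ties break toward
#' the smaller concentration. The mean is taken on the linear scale.
#'
#' @param concentrations numeric vector of distinct concentrations for one
#'   treatment.
#' @return the selected concentration, or \code{NA} (with a warning) when
#'   empty.
#' @examples
#' selectTreatmentConcentration(c(0.61, 2.5, 10))  # 2.5
#' @export
selectTreatmentConcentration <- function(concentrations) {
    cc <- sort(unique(concentrations))
    if (length(cc) == 0L) {
        warning("treatment without remaining concentrations dropped")
        return(NA_real_)
    }
    d <- abs(cc - mean(cc))
    cc[which.min(d)]       # sort order makes ties resolve to the smaller
}

#' Identify genes eligible for association testing
#'
#' Genes (in either partner role) involved in an in-frame or candidate
#' promoter-swapping fusion in at least \code{min_cell_lines} distinct
#' screened cell lines.
#'
#' @param groups collapsed gene-pair table from
#'   \code{\link{collapseGenePairs}} (needs \code{has_in_frame} and
#'   \code{promoter_swap}).
#' @param screened_cell_lines cell lines present in the drug screen.
#' @param min_cell_lines minimum number of distinct cell lines
#'   (default 2).
#' @return a character vector of eligible gene symbols, sorted.
#' @export
eligibleGenes <- function(groups, screened_cell_lines, min_cell_lines = 2) {
    df <- as.data.frame(groups)
    df <- df[df$cell_line %in% screened_cell_lines &
             (df$has_in_frame | df$promoter_swap), , drop = FALSE]
    if (nrow(df) == 0L) return(character(0))
    long <- rbind(data.frame(gene = df$gene5, cell_line = df$cell_line),
                  data.frame(gene = df$gene3, cell_line = df$cell_line))
    counts <- vapply(split(long$cell_line, long$gene),
                     function(cl) length(unique(cl)), integer(1))
    sort(names(counts)[counts >= min_cell_lines])
}

#' Welch's two-sample t-test
#'
#' Two-sided Welch test with Satterthwaite degrees of freedom. Degenerate
#' zero-variance groups are handled by convention rather than raising:
#' when both variances are zero, p is 0 if the means differ and 1 if they
#' are equal, and the result is flagged.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return a list with \code{t}, \code{df}, \code{p}, \code{mean_diff}
#'   (mean(a) - mean(b)) and \code{degenerate} flag; \code{NULL} (test
#'   skipped) when either group has fewer than two values.
#' @examples
#' welchT(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
welchT <- function(a, b) {
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    va <- stats::var(a)
    vb <- stats::var(b)
    md <- mean(a) - mean(b)
    if (va == 0 && vb == 0) {
        return(list(t = if (md == 0) 0 else sign(md) * Inf,
                    df = NA_real_, p = if (md == 0) 1 else 0,
                    mean_diff = md, degenerate = TRUE))
    }
    se2 <- va / length(a) + vb / length(b)
    tstat <- md / sqrt(se2)
    dfree <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                      (vb / length(b))^2 / (length(b) - 1))
    list(t = tstat, df = dfree, p = 2 * stats::pt(-abs(tstat), dfree),
         mean_diff = md, degenerate = FALSE)
}

#' Fusion-drug association analysis
#'
#' For every combination of eligible fusion partner gene and retained
#' treatment: group screened cell lines by presence of an in-frame or
#' promoter-swap fusion involving the gene, collapse replicate log2 fold
#' changes at the treatment's selected concentration to one value per
#' cell line (replicate mean), run a two-sided Welch test, and finally
#' apply one global Benjamini-Hochberg correction across all performed
#' tests.
#'
#' @param groups collapsed gene-pair table from
#'   \code{\link{collapseGenePairs}}.
#' @param responses response data.frame (see
#'   \code{\link{readDrugResponses}}).
#' @param min_coverage concentration coverage threshold (default 0.8).
#' @param min_cell_lines minimum fusion cell lines per gene (default 2).
#' @return a data.frame sorted by adjusted p with columns \code{gene},
#'   \code{drug}, \code{plate}, \code{concentration}, \code{n_with},
#'   \code{n_without}, \code{mean_diff}, \code{t}, \code{df}, \code{p},
#'   \code{p_adj}, \code{degenerate}.
#' @export
runFusionDrugAssociation <- function(groups, responses, min_coverage = 0.8,
                                     min_cell_lines = 2) {
    screened <- unique(responses$cell_line)
    resp <- filterConcentrations(responses, screened, min_coverage)
    genes <- eligibleGenes(groups, screened, min_cell_lines)
    empty <- data.frame(gene = character(), drug = character(),
                        plate = character(), concentration = numeric(),
                        n_with = integer(), n_without = integer(),
                        mean_diff = numeric(), t = numeric(),
                        df = numeric(), p = numeric(), p_adj = numeric(),
                        degenerate = logical())
    if (length(genes) == 0L || nrow(resp) == 0L) return(empty)

    gdf <- as.data.frame(groups)
    gdf <- gdf[gdf$has_in_frame | gdf$promoter_swap, , drop = FALSE]
    linesWith <- function(gene)
        unique(gdf$cell_line[gdf$gene5 == gene | gdf$gene3 == gene])

    tkey <- paste(resp$drug, resp$plate, sep = "\r")
    treatments <- sort(unique(tkey))
    rows <- list()
    for (tk in treatments) {
        sub <- resp[tkey == tk, , drop = FALSE]
        conc <- selectTreatmentConcentration(sub$concentration)
        if (is.na(conc)) next
        sub <- sub[sub$concentration == conc, , drop = FALSE]
        per_line <- vapply(split(sub$value, sub$cell_line), mean, numeric(1))
        for (gene in genes) {
            with_lines <- intersect(linesWith(gene), names(per_line))
            a <- per_line[names(per_line) %in% with_lines]
            b <- per_line[!names(per_line) %in% with_lines]
            res <- welchT(a, b)
            if (is.null(res)) next
            rows[[length(rows) + 1L]] <- data.frame(
                gene = gene, drug = sub$drug[1], plate = sub$plate[1],
                concentration = conc, n_with = length(a),
                n_without = length(b), mean_diff = res$mean_diff,
                t = res$t, df = res$df, p = res$p,
                degenerate = res$degenerate, stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
    out$p_adj <- bhAdjust(out$p)
    out <- out[order(out$p_adj, out$p, out$gene, out$drug), ]
    rownames(out) <- NULL
    out[, c("gene", "drug", "plate", "concentration", "n_with",
            "n_without", "mean_diff", "t", "df", "p", "p_adj",
            "degenerate")]
}
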