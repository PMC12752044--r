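#' Round a fraction to a whole percent, half up
#'
#' Percent formatting convention used throughout the reports:
#' \code{round(100 x)} with halves rounded up (so 0.845 prints as 85, not
#' 84 as banker's rounding would give).
#'
#' @param x fraction(s) in [0, 1].
#' @return integer percent(s).
#' @examples
#' percentHalfUp(8753 / 27258)  # 32
#' @export
percentHalfUp <- function(x) {
    as.integer(floor(100 * x + 0.5))
}

#' Summarize validation outcomes
#'
#' Per group: the number of input calls, the number validated with at
#' least discordant read support, the number additionally
#' breakpoint-supported, the validation rate over the input, and the
#' breakpoint fraction among validated calls. Rates are computed over the
#' filtered calls that were input to the validation pipeline.
#'
#' @param results per-call table from \code{\link{validateFusions}} (needs
#'   a \code{status} column).
#' @param group_by character vector of grouping columns (e.g.
#'   \code{"caller"}, \code{"confidence"}); empty for one overall row.
#' @return a data.frame with the grouping columns plus \code{n_input},
#'   \code{n_discordant_supported}, \code{n_breakpoint_supported},
#'   \code{rate_validated} and \code{rate_breakpoint_among_validated},
#'   rows in deterministic (sorted key) order.
#' @export
validationSummary <- function(results, group_by = character()) {
    df <- as.data.frame(results)
    if (nrow(df) == 0L)
        return(data.frame(n_input = integer(),
                          n_discordant_supported = integer(),
                          n_breakpoint_supported = integer(),
                          rate_validated = numeric(),
                          rate_breakpoint_among_validated = numeric()))
    status <- factor(as.character(df$status), levels = .STATUS_LEVELS,
                     ordered = TRUE)
    key <- if (length(group_by))
        do.call(paste, c(df[group_by], sep = "\r")) else rep("all", nrow(df))
    groups <- split(seq_len(nrow(df)), key)
    groups <- groups[order(names(groups))]
    rows <- lapply(groups, function(idx) {
        n <- length(idx)
        nd <- sum(status[idx] >= "discordant_supported")
        nb <- sum(status[idx] == "breakpoint_supported")
        cbind(if (length(group_by))
                  df[idx[1], group_by, drop = FALSE]
              else data.frame(row.names = NULL)[1, , drop = FALSE],
              data.frame(n_input = n, n_discordant_supported = nd,
                         n_breakpoint_supported = nb,
                         rate_validated = nd / n,
                         rate_breakpoint_among_validated =
                             if (nd > 0) nb / nd else NA_real_))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Feature-fraction table over collapsed gene pairs
#'
#' Computes the fraction of groups positive for a feature, with partner
#' sub-rows ("5' only", "3' only", "both partners") computed over the
#' feature-positive subset, in the shape of an annotation summary table.
#'
#' @param groups collapsed gene-pair table from
#'   \code{\link{collapseGenePairs}}.
#' @param feature one of \code{"kinase"}, \code{"mirna_host"},
#'   \code{"cgc"} (paired 5'/3' logical columns), \code{"promoter_swap"},
#'   \code{"alt_splice"}, \code{"has_in_frame"} (single logical columns),
#'   or \code{"mitelman"}, \code{"tumorfusions"} (match categories; the
#'   sub-rows are the tissue categories over the matched subset).
#' @return a data.frame with columns \code{row}, \code{count},
#'   \code{fraction}. The first row is the feature fraction over all
#'   groups; remaining rows are fractions over the feature-positive
#'   subset.
#' @export
fractionTable <- function(groups, feature) {
    df <- as.data.frame(groups)
    n <- nrow(df)
    paired <- c(kinase = "kinase", mirna_host = "mirna_host", cgc = "cgc")
    single <- c("promoter_swap", "alt_splice", "has_in_frame")
    dbf <- c(mitelman = "mitelman_match", tumorfusions = "tumorfusions_match")
    if (feature %in% names(paired)) {
        c5 <- df[[paste0(feature, "5")]]
        c3 <- df[[paste0(feature, "3")]]
        if (is.null(c5) || is.null(c3)) stop("unknown feature: ", feature)
        pos <- c5 | c3
        np <- sum(pos)
        sub <- data.frame(
            row = c("5' only", "3' only", "both partners"),
            count = c(sum(pos & c5 & !c3), sum(pos & !c5 & c3),
                      sum(pos & c5 & c3)))
        sub$fraction <- if (np > 0) sub$count / np else rep(NA_real_, 3)
        rbind(data.frame(row = feature, count = np,
                         fraction = if (n > 0) np / n else NA_real_), sub)
    } else if (feature %in% single) {
        if (is.null(df[[feature]])) stop("unknown feature: ", feature)
        np <- sum(df[[feature]])
        data.frame(row = feature, count = np,
                   fraction = if (n > 0) np / n else NA_real_)
    } else if (feature %in% names(dbf)) {
        col <- df[[dbf[[feature]]]]
        if (is.null(col)) stop("unknown feature: ", feature)
        pos <- col != "none"
        np <- sum(pos)
        cats <- c("exact_tissue", "related_tissue", "no_tissue_match",
                  "unknown_tissue")
        sub <- data.frame(row = cats,
                          count = vapply(cats, function(cc) sum(col == cc),
                                         integer(1)))
        sub$fraction <- if (np > 0) sub$count / np else rep(NA_real_, 4)
        rbind(data.frame(row = feature, count = np,
                         fraction = if (n > 0) np / n else NA_real_), sub)
    } else stop("unknown feature: ", feature)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value computed by summing, over all tables with the
#' observed margins, the hypergeometric probabilities that do not exceed
#' the observed table's probability. Probabilities are accumulated in
#' log space so the computation is numerically stable for large counts.
#' The odds ratio reported is the sample odds ratio \code{(a d)/(b c)}.
#'
#' @param a,b,c,d the table counts (rows = group, columns = outcome); or
#'   pass a 2x2 matrix as \code{a}.
#' @return a list with \code{odds_ratio} and \code{p}.
#' @examples
#' fisherExact(2, 0, 0, 2)$p  # 1/3
#' @export
fisherExact <- function(a, b = NULL, c = NULL, d = NULL) {
    if (is.matrix(a)) {
        stopifnot(all(dim(a) == c(2L, 2L)))
        d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
    }
    counts <- c(a, b, c, d)
    stopifnot(all(counts >= 0), sum(counts) > 0)
    m <- a + b      # row 1 margin
    nn <- c + d     # row 2 margin
    k <- a + c      # column 1 margin
    if (m == 0 || nn == 0 || k == 0 || (b + d) == 0) {
        warning("a margin of the contingency table is zero; p = 1")
        return(list(odds_ratio = NaN, p = 1))
    }
    or <- (a * d) / (b * c)
    ## support of the number in cell (1,1) given fixed margins
    lo <- max(0, k - nn)
    hi <- min(k, m)
    x <- lo:hi
    logp <- lgamma(m + 1) - lgamma(x + 1) - lgamma(m - x + 1) +
        lgamma(nn + 1) - lgamma(k - x + 1) - lgamma(nn - (k - x) + 1) -
        (lgamma(m + nn + 1) - lgamma(k + 1) - lgamma(m + nn - k + 1))
    obs <- logp[x == a]
    keep <- logp <= obs + 1e-7
    mx <- max(logp[keep])
    p <- exp(mx + log(sum(exp(logp[keep] - mx))))
    list(odds_ratio = or, p = min(1, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: sort the p-values,
#' scale the i-th smallest by n/i, take the cumulative minimum from the
#' largest down, and map back to input positions.
#'
#' @param pvals numeric vector of p-values in [0, 1] (may be empty).
#' @return adjusted p-values in input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(pvals) {
    if (length(pvals) == 0L) return(numeric(0))
    if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0, 1]")
    n <- length(pvals)
    o <- order(pvals)
    adj <- pvals[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

#' Enrichment tests relating prediction sharing and splicing to validation
#'
#' Builds, per caller, (i) a shared-vs-single-caller by validated 2x2
#' table, where a call is "shared" when a call with identical
#' (cell line, junction5, junction3) exists from the other caller
#' (annotation equality is not required here), and (ii) an
#' alternative-splicing-candidate by validated 2x2 table over the input
#' call set, and runs \code{\link{fisherExact}} on each.
#'
#' @param results per-call table from \code{\link{validateFusions}}
#'   containing both callers' calls with \code{status}.
#' @return a list per caller with elements \code{shared} and
#'   \code{alt_splice}, each carrying \code{table} (2x2 matrix, rows =
#'   feature yes/no, columns = validated yes/no), \code{odds_ratio} and
#'   \code{p}. When only one caller is present a partial report is
#'   returned with a warning.
#' @export
enrichmentTests <- function(results) {
    df <- as.data.frame(results)
    df$validated <- factor(as.character(df$status),
                           levels = .STATUS_LEVELS, ordered = TRUE) >=
        "discordant_supported"
    callers <- intersect(.CALLERS, unique(df$caller))
    if (length(callers) < 2L)
        warning("only one caller present; returning a partial report")
    jkey <- paste(df$cell_line, df$chrom5, df$pos5, df$chrom3, df$pos3,
                  sep = "\r")
    df <- assignAltSpliceIds(df)
    out <- list()
    for (cl in callers) {
        mine <- df$caller == cl
        other_keys <- unique(jkey[df$caller != cl])
        shared <- mine & jkey %in% other_keys
        tab_shared <- matrix(c(sum(shared & df$validated),
                               sum(shared & !df$validated),
                               sum(mine & !shared & df$validated),
                               sum(mine & !shared & !df$validated)),
                             nrow = 2, byrow = TRUE,
                             dimnames = list(c("shared", "single"),
                                             c("validated", "not")))
        alt <- mine & !is.na(df$alt_splice_id)
        tab_alt <- matrix(c(sum(alt & df$validated),
                            sum(alt & !df$validated),
                            sum(mine & !alt & df$validated),
                            sum(mine & !alt & !df$validated)),
                          nrow = 2, byrow = TRUE,
                          dimnames = list(c("alt_splice", "single_junction"),
                                          c("validated", "not")))
        fs <- fisherExact(tab_shared)
        fa <- fisherExact(tab_alt)
        out[[cl]] <- list(
            shared = list(table = tab_shared, odds_ratio = fs$odds_ratio,
                          p = fs$p),
            alt_splice = list(table = tab_alt, odds_ratio = fa$odds_ratio,
                              p = fa$p))
    }
    out
}
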