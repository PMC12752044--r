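## Planting fusion events: RNA junctions at exon boundaries, DNA
## breakpoints in the adjacent introns, with geometry- and strand-aware
## gene pairing.

## exons of a gene in transcription order (data.frame start/end rows)
.txExonIndex <- function(n, strand, i) {
    if (strand == "-") n - i + 1L else i
}

#' Plant fusion events into a synthetic gene set
#'
#' Chooses gene pairs honouring each event's geometry (interchromosomal:
#' partners on different chromosomes; deletion: same chromosome, both
#' \code{+} strand, 5' partner upstream; inversion: same chromosome,
#' opposite strands), puts the RNA junctions at exon boundaries (after the
#' second exon in transcription order for the 5' partner, falling back to
#' the first exon for two-exon genes; before the second exon for the 3'
#' partner) and samples the DNA breakpoints inside the adjacent introns,
#' so that each breakpoint lies within its side's search region.
#' RNA-only false calls reference additional gene pairs with no DNA
#' event. Reading frames and confidence labels cycle deterministically
#' over the events.
#'
#' @param genes a \code{GeneModelSet} from \code{\link{makeGenomeAndGenes}}.
#' @param spec a \code{SimSpec}.
#' @param cell_line sample name recorded in the truth set.
#' @return a truth-set list with data.frames \code{events} and
#'   \code{false_calls}.
#' @export
plantFusionEvents <- function(genes, spec, cell_line = "SYN-CL-1") {
    set.seed(spec@seed + 1L)
    g <- geneRanges(genes)
    gdf <- data.frame(gene_id = mcols(g)$gene_id, symbol = mcols(g)$symbol,
                      chrom = as.character(seqnames(g)), start = start(g),
                      end = end(g), strand = as.character(strand(g)),
                      coding_start = mcols(g)$coding_start,
                      stringsAsFactors = FALSE)
    gdf <- gdf[order(gdf$chrom, gdf$start), ]
    used <- rep(FALSE, nrow(gdf))

    pickPair <- function(geom) {
        if (geom == "interchromosomal") {
            chroms <- unique(gdf$chrom)
            for (c1 in chroms) for (c2 in setdiff(chroms, c1)) {
                i <- which(!used & gdf$chrom == c1)[1]
                j <- which(!used & gdf$chrom == c2)[1]
                if (!is.na(i) && !is.na(j)) return(c(i, j))
            }
        } else if (geom == "deletion") {
            for (ch in unique(gdf$chrom)) {
                idx <- which(!used & gdf$chrom == ch & gdf$strand == "+")
                if (length(idx) >= 2L) return(idx[1:2])
            }
        } else {
            for (ch in unique(gdf$chrom)) {
                ip <- which(!used & gdf$chrom == ch & gdf$strand == "+")
                im <- which(!used & gdf$chrom == ch & gdf$strand == "-")
                if (length(ip) && length(im)) return(c(ip[1], im[1]))
            }
        }
        stop("infeasible SimSpec: not enough gene pairs for geometry ", geom)
    }

    junctionAndBreak <- function(row, role) {
        ex <- as.data.frame(exonsByGene(genes)[[row$gene_id]])
        n <- nrow(ex)
        if (role == "five_prime") {
            j <- min(2L, n - 1L)              # tx exon whose end is joined
            lo <- .txExonIndex(n, row$strand, j)
            hi <- .txExonIndex(n, row$strand, j + 1L)
            junction <- if (row$strand == "-") ex$start[lo] else ex$end[lo]
        } else {
            j <- 2L                           # tx exon whose start is joined
            lo <- .txExonIndex(n, row$strand, j - 1L)
            hi <- .txExonIndex(n, row$strand, j)
            junction <- if (row$strand == "-") ex$end[hi] else ex$start[hi]
        }
        ## intron between the two genomic exons involved
        ilo <- min(ex$end[c(lo, hi)]) + 10L
        ihi <- max(ex$start[c(lo, hi)]) - 10L
        stopifnot(ihi > ilo)
        bp <- sample(seq.int(ilo, ihi), 1L)
        list(junction = junction, bp = bp, promoter_swap =
                 txPrecedes(junction, row$coding_start, row$strand))
    }

    frames <- c("in-frame", "out-of-frame", "unknown")
    confs <- c("high", "medium", "low")
    geoms <- rep(spec@geometries,
                 length.out = max(1L, spec@n_true_fusions))

    events <- list()
    for (k in seq_len(spec@n_true_fusions)) {
        pair <- pickPair(geoms[k])
        if (geoms[k] == "inversion") {
            ## 5' partner is the + strand gene by convention
            if (gdf$strand[pair[1]] == "-") pair <- rev(pair)
        }
        used[pair] <- TRUE
        r5 <- gdf[pair[1], ]
        r3 <- gdf[pair[2], ]
        a <- junctionAndBreak(r5, "five_prime")
        b <- junctionAndBreak(r3, "three_prime")
        events[[k]] <- data.frame(
            event_id = sprintf("EV%02d", k), cell_line = cell_line,
            gene5 = r5$symbol, gene_id5 = r5$gene_id,
            gene3 = r3$symbol, gene_id3 = r3$gene_id,
            chrom5 = r5$chrom, junction5 = a$junction, bp5 = a$bp,
            chrom3 = r3$chrom, junction3 = b$junction, bp3 = b$bp,
            strand5 = r5$strand, strand3 = r3$strand,
            geometry = geoms[k],
            reading_frame = frames[((k - 1L) %% 3L) + 1L],
            confidence = confs[((k - 1L) %% 3L) + 1L],
            promoter_swap_expected = a$promoter_swap,
            expected_status = "breakpoint_supported",
            stringsAsFactors = FALSE)
    }

    false_calls <- list()
    for (k in seq_len(spec@n_false_calls)) {
        idx <- which(!used)
        if (length(idx) < 2L)
            stop("infeasible SimSpec: not enough genes for false calls")
        pair <- idx[1:2]
        used[pair] <- TRUE
        r5 <- gdf[pair[1], ]
        r3 <- gdf[pair[2], ]
        a <- junctionAndBreak(r5, "five_prime")
        b <- junctionAndBreak(r3, "three_prime")
        kk <- spec@n_true_fusions + k
        false_calls[[k]] <- data.frame(
            event_id = sprintf("FC%02d", k), cell_line = cell_line,
            gene5 = r5$symbol, gene_id5 = r5$gene_id,
            gene3 = r3$symbol, gene_id3 = r3$gene_id,
            chrom5 = r5$chrom, junction5 = a$junction,
            chrom3 = r3$chrom, junction3 = b$junction,
            strand5 = r5$strand, strand3 = r3$strand,
            reading_frame = frames[((kk - 1L) %% 3L) + 1L],
            confidence = confs[((kk - 1L) %% 3L) + 1L],
            promoter_swap_expected = a$promoter_swap,
            expected_status = "unsupported",
            stringsAsFactors = FALSE)
    }

    list(events = if (length(events)) do.call(rbind, events) else NULL,
         false_calls = if (length(false_calls))
             do.call(rbind, false_calls) else NULL)
}
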