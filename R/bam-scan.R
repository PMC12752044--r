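#' Scan a BAM region for usable reads
#'
#' Returns primary, mapped, non-duplicate, non-secondary,
#' non-supplementary reads overlapping the region with mapping quality at
#' least \code{min_mapq}. Duplicate and supplementary alignments are
#' always excluded to avoid double counting evidence.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param region a region list as produced by
#'   \code{\link{buildSearchRegions}} (fields \code{chrom}, \code{start},
#'   \code{end}).
#' @param params a \code{ValidationParams}.
#' @return a \code{DataFrame} with one row per read: \code{name},
#'   \code{chrom}, \code{pos}, \code{strand}, \code{mapq}, \code{cigar},
#'   \code{seq}, \code{qual}, \code{mate_chrom}, \code{mate_pos},
#'   \code{isize}, \code{flag}, \code{proper_pair}, \code{first_in_pair}.
#' @importFrom Rsamtools BamFile ScanBamParam scanBamFlag scanBam
#'   scanBamHeader
#' @export
scanRegion <- function(bam, region, params = validationParams()) {
    bf <- BamFile(bam)
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
        stop("missing BAM index for ", bam)
    hdr <- scanBamHeader(bf)
    if (!region$chrom %in% names(hdr$targets)) {
        warning("chromosome ", region$chrom, " absent from BAM header")
        return(.emptyReadFrame())
    }
    which <- GRanges(region$chrom, IRanges(region$start, region$end))
    flag <- scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE,
                        isSecondaryAlignment = FALSE,
                        isSupplementaryAlignment = FALSE)
    p <- ScanBamParam(which = which, flag = flag,
                      mapqFilter = as.integer(params@min_mapq),
                      what = c("qname", "flag", "rname", "strand", "pos",
                               "mapq", "cigar", "mrnm", "mpos", "isize",
                               "seq", "qual"))
    res <- scanBam(bf, param = p)[[1]]
    n <- length(res$qname)
    if (n == 0L) return(.emptyReadFrame())
    DataFrame(name = res$qname,
              chrom = as.character(res$rname),
              pos = res$pos,
              strand = as.character(res$strand),
              mapq = res$mapq,
              cigar = res$cigar,
              seq = as.character(res$seq),
              qual = as.character(res$qual),
              mate_chrom = as.character(res$mrnm),
              mate_pos = res$mpos,
              isize = res$isize,
              flag = res$flag,
              proper_pair = bitwAnd(res$flag, 2L) > 0L,
              first_in_pair = bitwAnd(res$flag, 64L) > 0L)
}

.emptyReadFrame <- function() {
    DataFrame(name = character(), chrom = character(), pos = integer(),
              strand = character(), mapq = integer(), cigar = character(),
              seq = character(), qual = character(),
              mate_chrom = character(), mate_pos = integer(),
              isize = integer(), flag = integer(), proper_pair = logical(),
              first_in_pair = logical())
}

#' Find discordant read pairs spanning two search regions
#'
#' A pair qualifies when one mate's alignment lies within the 5' search
#' region and the other's within the 3' search region, and the pair is
#' discordant: mates on different chromosomes, or the proper-pair flag
#' unset, or the template span exceeding
#' \code{max_concordant_insert}. Pairs are deduplicated by read name and
#' returned in deterministic (name) order.
#'
#' @inheritParams scanRegion
#' @param region5,region3 the 5' and 3' search regions from
#'   \code{\link{buildSearchRegions}}.
#' @return a \code{DataFrame} with one row per pair: \code{name} plus the
#'   \code{pos}, \code{strand} and \code{chrom} of the mate in each region
#'   (columns suffixed \code{_5} and \code{_3}).
#' @export
findDiscordantPairs <- function(bam, region5, region3,
                                params = validationParams()) {
    r5 <- scanRegion(bam, region5, params)
    r3 <- scanRegion(bam, region3, params)
    if (nrow(r5) == 0L || nrow(r3) == 0L) return(.emptyPairFrame())
    common <- intersect(r5$name, r3$name)
    if (length(common) == 0L) return(.emptyPairFrame())
    out <- vector("list", length(common))
    k <- 0L
    for (nm in sort(common)) {
        a <- r5[r5$name == nm, , drop = FALSE]
        b <- r3[r3$name == nm, , drop = FALSE]
        found <- FALSE
        for (i in seq_len(nrow(a))) {
            if (found) break
            for (j in seq_len(nrow(b))) {
                ## the two records must be the two mates, not one read seen
                ## in both (possibly overlapping) regions
                if (a$first_in_pair[i] == b$first_in_pair[j]) next
                span <- abs(a$isize[i])
                disc <- a$chrom[i] != b$chrom[j] ||
                    !a$proper_pair[i] || !b$proper_pair[j] ||
                    (!is.na(span) && span > params@max_concordant_insert)
                if (!disc) next
                k <- k + 1L
                out[[k]] <- DataFrame(
                    name = nm,
                    chrom_5 = a$chrom[i], pos_5 = a$pos[i],
                    strand_5 = a$strand[i],
                    chrom_3 = b$chrom[j], pos_3 = b$pos[j],
                    strand_3 = b$strand[j])
                found <- TRUE
                break
            }
        }
    }
    if (k == 0L) return(.emptyPairFrame())
    do.call(rbind, out[seq_len(k)])
}

.emptyPairFrame <- function() {
    DataFrame(name = character(), chrom_5 = character(), pos_5 = integer(),
              strand_5 = character(), chrom_3 = character(),
              pos_3 = integer(), strand_3 = character())
}
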