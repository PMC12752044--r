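## Soft-clip breakpoint calling and the per-call validation driver.

## minimal CIGAR arithmetic (M/I/D/N/S/H/P/=/X)
.cigarParse <- function(cigar) {
    len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
    list(len = len, op = op)
}

.cigarRefLen <- function(cigar) {
    c <- .cigarParse(cigar)
    sum(c$len[c$op %in% c("M", "D", "N", "=", "X")])
}

.softClipLen <- function(cigar, side) {
    c <- .cigarParse(cigar)
    op <- c$op[c$op != "H"]
    len <- c$len[c$op != "H"]
    if (length(op) == 0L) return(0L)
    if (side == "left") {
        if (op[1] == "S") len[1] else 0L
    } else {
        if (op[length(op)] == "S") len[length(len)] else 0L
    }
}

.meanPhred <- function(qual_chars) {
    mean(as.integer(charToRaw(qual_chars))) - 33
}

#' Call candidate genomic breakpoints from soft-clipped reads
#'
#' For each side of a fusion, reads in the search region carrying a soft
#' clip of at least \code{min_clip_len} on the junction-facing end of the
#' alignment are collected. The junction-facing end points toward the
#' transcriptional gene end for the 5' partner and toward the
#' transcriptional gene start for the 3' partner, mirrored for \code{-}
#' strand genes. Clips whose bases have mean quality below
#' \code{min_clip_mean_qual} are discarded. Each surviving clip sequence
#' (reverse-complemented when the two partners lie on opposite strands) is
#' searched ungapped, allowing at most \code{max_clip_mismatch_frac}
#' mismatches, in the reference within \code{mate_window} bp of the
#' position of some discordant mate on the other side. Passing clips vote
#' for their clip-boundary coordinate (alignment end for a right-side
#' clip, alignment start for a left-side clip); the candidate per side is
#' the modal coordinate, ties broken toward the smaller coordinate.
#'
#' @inheritParams findDiscordantPairs
#' @param pairs discordant pairs from \code{\link{findDiscordantPairs}};
#'   breakpoint search is conditioned on discordant support and is skipped
#'   when empty.
#' @param reference path to an indexed FASTA file (or
#'   \code{\link[Rsamtools]{FaFile}}) for mate-window sequence retrieval.
#' @return a \code{DataFrame} with zero to two rows: \code{side}
#'   (\code{five_prime}/\code{three_prime}), \code{chrom}, \code{pos},
#'   \code{support} and \code{clip_seq}.
#' @importFrom Rsamtools FaFile scanFa scanFaIndex indexFa
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   countPattern
#' @export
callBreakpoints <- function(bam, region5, region3, pairs, reference,
                            params = validationParams()) {
    if (nrow(pairs) == 0L) return(.emptyBreakpointFrame())
    fa <- .asFaFile(reference)
    idx <- scanFaIndex(fa)
    seqlens <- stats::setNames(width(idx), as.character(seqnames(idx)))
    sameStrand <- as.character(strand(region5$gene)) ==
        as.character(strand(region3$gene))
    res5 <- .sideBreakpoint(bam, region5, region3, pairs$pos_3,
                            pairs$chrom_3, sameStrand, fa, seqlens, params)
    res3 <- .sideBreakpoint(bam, region3, region5, pairs$pos_5,
                            pairs$chrom_5, sameStrand, fa, seqlens, params)
    rbind(res5, res3)
}

.asFaFile <- function(reference) {
    if (is(reference, "FaFile")) return(reference)
    if (!file.exists(paste0(reference, ".fai"))) indexFa(reference)
    FaFile(reference)
}

.clipSideFor <- function(region) {
    str <- as.character(strand(region$gene))
    if (region$role == "five_prime") {
        if (str == "+") "right" else "left"
    } else {
        if (str == "+") "left" else "right"
    }
}

.sideBreakpoint <- function(bam, region, other_region, mate_pos, mate_chrom,
                            sameStrand, fa, seqlens, params) {
    reads <- scanRegion(bam, region, params)
    if (nrow(reads) == 0L) return(.emptyBreakpointFrame())
    clip_side <- .clipSideFor(region)
    windows <- .mateWindows(mate_pos, mate_chrom, fa, seqlens, params)
    ## vectorized clip-length screen before the per-read work
    cl_all <- integer(nrow(reads))
    if (clip_side == "left") {
        hit <- grepl("^[0-9]+S", reads$cigar)
        cl_all[hit] <- as.integer(sub("^([0-9]+)S.*$", "\\1",
                                      reads$cigar[hit]))
    } else {
        hit <- grepl("[0-9]+S$", reads$cigar)
        cl_all[hit] <- as.integer(sub("^.*?([0-9]+)S$", "\\1",
                                      reads$cigar[hit], perl = TRUE))
    }
    reads <- reads[cl_all >= params@min_clip_len, , drop = FALSE]
    cl_all <- cl_all[cl_all >= params@min_clip_len]
    if (nrow(reads) == 0L) return(.emptyBreakpointFrame())
    votes <- integer(0)
    clips <- character(0)
    for (i in seq_len(nrow(reads))) {
        cl <- cl_all[i]
        seq <- reads$seq[i]
        qual <- reads$qual[i]
        if (clip_side == "right") {
            clip <- substring(seq, nchar(seq) - cl + 1L, nchar(seq))
            clipq <- substring(qual, nchar(qual) - cl + 1L, nchar(qual))
            boundary <- reads$pos[i] + .cigarRefLen(reads$cigar[i]) - 1L
        } else {
            clip <- substring(seq, 1L, cl)
            clipq <- substring(qual, 1L, cl)
            boundary <- reads$pos[i]
        }
        if (.meanPhred(clipq) < params@min_clip_mean_qual) next
        if (boundary < region$start || boundary > region$end) next
        probe <- if (sameStrand) clip else
            as.character(reverseComplement(DNAString(clip)))
        if (!.clipMatchesWindows(probe, windows, params)) next
        votes <- c(votes, boundary)
        clips <- c(clips, clip)
    }
    if (length(votes) == 0L) return(.emptyBreakpointFrame())
    tab <- table(votes)
    best <- as.integer(names(tab)[tab == max(tab)])
    pos <- min(best)                       # tie toward smaller coordinate
    support <- as.integer(max(tab))
    sel <- clips[votes == pos]
    DataFrame(side = region$role, chrom = region$chrom, pos = pos,
              support = support,
              clip_seq = sel[which.max(nchar(sel))])
}

## merged +/- mate_window intervals around the discordant mates on the
## other side, fetched from the reference once per side
.mateWindows <- function(mate_pos, mate_chrom, fa, seqlens, params) {
    known <- mate_chrom %in% names(seqlens)
    if (any(!known))
        warning("reference sequence unavailable for mate window on ",
                paste(unique(mate_chrom[!known]), collapse = ", "),
                "; clip skipped")
    if (!any(known)) return(DNAStringSet())
    mw <- as.integer(params@mate_window)
    gr <- GRanges(mate_chrom[known],
                  IRanges(pmax(1L, mate_pos[known] - mw),
                          pmin(seqlens[mate_chrom[known]],
                               mate_pos[known] + mw)))
    scanFa(fa, GenomicRanges::reduce(gr))
}

.clipMatchesWindows <- function(probe, windows, params) {
    if (length(windows) == 0L) return(FALSE)
    max_mm <- floor(params@max_clip_mismatch_frac * nchar(probe))
    p <- DNAString(probe)
    for (k in seq_along(windows)) {
        if (countPattern(p, windows[[k]], max.mismatch = max_mm,
                         with.indels = FALSE) > 0L)
            return(TRUE)
    }
    FALSE
}

.emptyBreakpointFrame <- function() {
    DataFrame(side = character(), chrom = character(), pos = integer(),
              support = integer(), clip_seq = character())
}

#' Validate one fusion call against matched WGS data
#'
#' Runs the full per-call pipeline: build strand-aware search regions,
#' find discordant read pairs spanning them, and (when discordant support
#' is present) call candidate genomic breakpoints from soft-clipped
#' reads. Status is \code{breakpoint_supported} when at least one
#' breakpoint candidate is found (and discordant support exists),
#' \code{discordant_supported} when only the required number of discordant
#' pairs is found, otherwise \code{unsupported}. Discordant read support
#' alone is sufficient for a fusion to count as validated.
#'
#' @inheritParams buildSearchRegions
#' @param bam path to the coordinate-sorted, indexed WGS BAM.
#' @param reference indexed FASTA of the reference genome.
#' @return a list with \code{call} (one-row data.frame), \code{status},
#'   \code{n_discordant}, \code{pairs} and \code{breakpoints}.
#' @export
validateFusion <- function(call, bam, genes, reference,
                           params = validationParams()) {
    df <- if (is(call, "FusionCallSet")) as.data.frame(call) else
        as.data.frame(call)
    stopifnot(nrow(df) == 1L)
    regions <- buildSearchRegions(df, genes, params)
    pairs <- findDiscordantPairs(bam, regions$five_prime,
                                 regions$three_prime, params)
    n_disc <- nrow(pairs)
    bps <- .emptyBreakpointFrame()
    if (n_disc >= params@min_discordant_pairs && n_disc > 0L)
        bps <- callBreakpoints(bam, regions$five_prime, regions$three_prime,
                               pairs, reference, params)
    status <- if (n_disc >= params@min_discordant_pairs && nrow(bps) > 0L)
        "breakpoint_supported"
    else if (n_disc >= params@min_discordant_pairs)
        "discordant_supported"
    else "unsupported"
    list(call = df, status = status, n_discordant = n_disc, pairs = pairs,
         breakpoints = bps)
}

#' Validate a set of fusion calls
#'
#' Applies \code{\link{validateFusion}} to every call and collects a
#' per-call result table.
#'
#' @inheritParams validateFusion
#' @param calls a \code{FusionCallSet} (normally the kept set from
#'   \code{\link{filterCalls}}).
#' @return a \code{DataFrame} with the call identity columns plus
#'   \code{status} (ordered \code{unsupported} <
#'   \code{discordant_supported} < \code{breakpoint_supported}),
#'   \code{n_discordant}, and breakpoint coordinates/support per side
#'   (\code{bp5_pos}, \code{bp5_support}, \code{bp3_pos},
#'   \code{bp3_support}, \code{NA} when absent).
#' @export
validateFusions <- function(calls, bam, genes, reference,
                            params = validationParams()) {
    df <- as.data.frame(calls)
    n <- nrow(df)
    status <- character(n)
    n_disc <- integer(n)
    bp5_pos <- bp3_pos <- rep(NA_integer_, n)
    bp5_support <- bp3_support <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        r <- validateFusion(df[i, , drop = FALSE], bam, genes, reference,
                            params)
        status[i] <- r$status
        n_disc[i] <- r$n_discordant
        b <- r$breakpoints
        if (nrow(b)) {
            i5 <- which(b$side == "five_prime")
            i3 <- which(b$side == "three_prime")
            if (length(i5)) { bp5_pos[i] <- b$pos[i5[1]]
                              bp5_support[i] <- b$support[i5[1]] }
            if (length(i3)) { bp3_pos[i] <- b$pos[i3[1]]
                              bp3_support[i] <- b$support[i3[1]] }
        }
    }
    out <- DataFrame(df)
    out$status <- factor(status, levels = .STATUS_LEVELS, ordered = TRUE)
    out$n_discordant <- n_disc
    out$bp5_pos <- bp5_pos
    out$bp5_support <- bp5_support
    out$bp3_pos <- bp3_pos
    out$bp3_support <- bp3_support
    out
}

#' Write validation results as TSV
#'
#' One row per fusion call with status, discordant-pair count and
#' breakpoint coordinates; every validation parameter is logged in a
#' header comment block.
#'
#' @param results the \code{DataFrame} from \code{\link{validateFusions}}.
#' @param path output TSV path.
#' @param params the \code{ValidationParams} used (logged in the header).
#' @return invisibly, the path.
#' @export
writeValidationTsv <- function(results, path,
                               params = validationParams()) {
    con <- file(path, "w")
    on.exit(close(con))
    pl <- paramsAsList(params)
    for (nm in names(pl))
        writeLines(paste0("# ", nm, " = ", pl[[nm]]), con)
    df <- as.data.frame(results)
    df$raw <- NULL
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
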