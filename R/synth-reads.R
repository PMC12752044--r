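## Paired-end WGS read simulator. Reads are written as already-aligned
## SAM records (the simulator computes reference placements, flags and
## CIGARs itself), then converted to a coordinate-sorted, indexed BAM.
## Background pairs are sampled from the unrearranged genome with proper-
## pair flags; for each planted event, fragments sampled across a fusion
## contig are projected back to reference coordinates: straddling pairs
## become discordant, and breakpoint-crossing reads become soft-clipped
## exactly at the planted breakpoint with the clipped bases taken from
## the partner side.

.rcChar <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

.subseqChar <- function(genome, chrom, s, e) {
    as.character(Biostrings::subseq(genome[[chrom]], s, e))
}

## substitution errors at the given per-base rate
.applyErrors <- function(seqs, rate) {
    if (rate <= 0) return(seqs)
    nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
    for (i in which(nerr > 0L)) {
        ch <- strsplit(seqs[i], "")[[1]]
        pos <- sample.int(length(ch), nerr[i])
        ch[pos] <- sample(.BASES, nerr[i], replace = TRUE)
        seqs[i] <- paste(ch, collapse = "")
    }
    seqs
}

## fusion contig: W bases ending at bp5 in the 5' partner's transcription
## orientation, then W bases starting at bp3 in the 3' partner's
.fusionContig <- function(genome, ev, W) {
    A <- if (ev$strand5 == "-")
        .rcChar(.subseqChar(genome, ev$chrom5, ev$bp5, ev$bp5 + W - 1L))
    else .subseqChar(genome, ev$chrom5, ev$bp5 - W + 1L, ev$bp5)
    B <- if (ev$strand3 == "-")
        .rcChar(.subseqChar(genome, ev$chrom3, ev$bp3 - W + 1L, ev$bp3))
    else .subseqChar(genome, ev$chrom3, ev$bp3, ev$bp3 + W - 1L)
    paste0(A, B)
}

## project a contig subinterval [x, y] (1-based, within one side) back to
## reference coordinates
.projectInterval <- function(ev, W, x, y) {
    if (y <= W) {                       # side A (5' partner)
        if (ev$strand5 == "-") {
            list(side = "A", chrom = ev$chrom5, flip = TRUE,
                 start = ev$bp5 + (W - y), end = ev$bp5 + (W - x))
        } else {
            list(side = "A", chrom = ev$chrom5, flip = FALSE,
                 start = ev$bp5 - W + x, end = ev$bp5 - W + y)
        }
    } else {                            # side B (3' partner)
        u <- x - W; v <- y - W
        if (ev$strand3 == "-") {
            list(side = "B", chrom = ev$chrom3, flip = TRUE,
                 start = ev$bp3 - v + 1L, end = ev$bp3 - u + 1L)
        } else {
            list(side = "B", chrom = ev$chrom3, flip = FALSE,
                 start = ev$bp3 + u - 1L, end = ev$bp3 + v - 1L)
        }
    }
}

## one aligned record from a contig read interval [a, b]
.projectRead <- function(ev, W, contig, a, b, rev_on_contig) {
    rl <- b - a + 1L
    crossing <- a <= W && b > W
    if (!crossing) {
        pr <- .projectInterval(ev, W, a, b)
        cigar <- paste0(rl, "M")
        pos <- pr$start
        flip <- pr$flip
    } else {
        lenA <- W - a + 1L
        lenB <- b - W
        if (lenA >= lenB) {             # align on side A, clip the B part
            pr <- .projectInterval(ev, W, a, W)
            clip <- lenB
            clip_right <- !pr$flip
            mlen <- lenA
        } else {
            pr <- .projectInterval(ev, W, W + 1L, b)
            clip <- lenA
            clip_right <- pr$flip
            mlen <- lenB
        }
        cigar <- if (clip_right) paste0(mlen, "M", clip, "S") else
            paste0(clip, "S", mlen, "M")
        pos <- pr$start
        flip <- pr$flip
    }
    seq <- substring(contig, a, b)
    if (flip) seq <- .rcChar(seq)
    list(chrom = pr$chrom, pos = pos, cigar = cigar, seq = seq,
         reverse = xor(rev_on_contig, flip))
}

#' Simulate WGS reads for a synthetic fusion study
#'
#' Writes a coordinate-sorted, indexed BAM containing background read
#' pairs over the whole genome at the specified depth plus
#' breakpoint-spanning discordant pairs and soft-clipped split reads for
#' every planted event. Identical seeds give identical BAM content.
#'
#' @param genome a named \code{DNAStringSet} from
#'   \code{\link{makeGenomeAndGenes}}.
#' @param truth the truth set from \code{\link{plantFusionEvents}}.
#' @param spec the \code{SimSpec}.
#' @param prefix output path prefix; the BAM is written to
#'   \code{<prefix>.bam} with index \code{<prefix>.bam.bai}.
#' @return the BAM path.
#' @importFrom Rsamtools asBam sortBam indexBam
#' @export
simulateWgsReads <- function(genome, truth, spec, prefix) {
    set.seed(spec@seed + 2L)
    rl <- spec@read_len
    recs <- list()

    addRec <- function(qname, flag, rname, pos, cigar, rnext, pnext, tlen,
                       seq) {
        recs[[length(recs) + 1L]] <<- data.frame(
            qname = qname, flag = flag, rname = rname, pos = pos,
            mapq = 60L, cigar = cigar, rnext = rnext, pnext = pnext,
            tlen = tlen, seq = seq, stringsAsFactors = FALSE)
    }

    ## background: proper FR pairs over the unrearranged genome
    for (ch in names(genome)) {
        len <- nchar(as.character(genome[[ch]]))
        n <- round(spec@depth * len / (2 * rl))
        L <- pmin(len, pmax(rl, round(stats::rnorm(n, spec@insert_mean,
                                                   spec@insert_sd))))
        s <- vapply(L, function(l) sample.int(len - l + 1L, 1L), integer(1))
        e <- s + L - 1L
        seq1 <- substring(as.character(genome[[ch]]), s, s + rl - 1L)
        seq2 <- .rcChar(substring(as.character(genome[[ch]]), e - rl + 1L, e))
        nm <- sprintf("bg_%s_%06d", ch, seq_len(n))
        recs[[length(recs) + 1L]] <- data.frame(
            qname = c(nm, nm),
            flag = c(rep(99L, n), rep(147L, n)),
            rname = ch, pos = c(s, e - rl + 1L), mapq = 60L,
            cigar = paste0(rl, "M"), rnext = "=",
            pnext = c(e - rl + 1L, s), tlen = c(L, -L),
            seq = c(seq1, seq2), stringsAsFactors = FALSE)
    }

    ## event reads from fusion contigs
    W <- 700L
    events <- truth$events
    for (k in seq_len(NROW(events))) {
        ev <- events[k, ]
        contig <- .fusionContig(genome, ev, W)
        clen <- nchar(contig)
        n <- round(spec@depth * clen / (2 * rl))
        for (i in seq_len(n)) {
            L <- min(clen, max(rl, round(stats::rnorm(1, spec@insert_mean,
                                                      spec@insert_sd))))
            s <- sample.int(clen - L + 1L, 1L)
            e <- s + L - 1L
            if (!(s <= W && e > W)) next  # fragment must span the junction
            nm <- sprintf("%s_frag%05d", ev$event_id, i)
            r1 <- .projectRead(ev, W, contig, s, s + rl - 1L, FALSE)
            r2 <- .projectRead(ev, W, contig, e - rl + 1L, e, TRUE)
            flag1 <- 1L + 64L + (if (r1$reverse) 16L else 0L) +
                (if (r2$reverse) 32L else 0L)
            flag2 <- 1L + 128L + (if (r2$reverse) 16L else 0L) +
                (if (r1$reverse) 32L else 0L)
            rnext1 <- if (r1$chrom == r2$chrom) "=" else r2$chrom
            rnext2 <- if (r1$chrom == r2$chrom) "=" else r1$chrom
            addRec(nm, flag1, r1$chrom, r1$pos, r1$cigar, rnext1, r2$pos,
                   0L, r1$seq)
            addRec(nm, flag2, r2$chrom, r2$pos, r2$cigar, rnext2, r1$pos,
                   0L, r2$seq)
        }
    }

    sam <- do.call(rbind, recs)
    sam$seq <- .applyErrors(sam$seq, spec@base_error)
    sam$qual <- vapply(nchar(sam$seq),
                       function(n) paste(rep("F", n), collapse = ""),
                       character(1))

    sam_path <- paste0(prefix, ".sam")
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                vapply(names(genome), function(ch)
                    sprintf("@SQ\tSN:%s\tLN:%d", ch,
                            nchar(as.character(genome[[ch]]))),
                    character(1)))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                    sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                    sam$cigar, sam$rnext, sam$pnext, sam$tlen, sam$seq,
                    sam$qual)
    writeLines(c(header, body), sam_path)

    bam_tmp <- asBam(sam_path, paste0(prefix, "_unsorted"),
                     overwrite = TRUE, indexDestination = FALSE)
    sorted <- sortBam(bam_tmp, prefix)
    indexBam(sorted)
    file.remove(sam_path, bam_tmp)
    sorted
}
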