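## Synthetic genome and gene models. Everything is seed-reproducible:
## each generator stage reseeds deterministically from the SimSpec seed.

.BASES <- c("A", "C", "G", "T")

#' Generate a random genome with annotated genes
#'
#' Creates \code{n_chroms} random chromosomes and places \code{n_genes}
#' non-overlapping multi-exon genes (2-6 exons) on both strands, with a
#' coding region starting at the second exon in transcription order.
#' Writes an indexed FASTA and a GTF with gene, transcript, exon and CDS
#' features. Identical seeds produce byte-identical files.
#'
#' @param spec a \code{\linkS4class{SimSpec}}.
#' @param dir output directory (created if needed).
#' @return a list with \code{genome} (a \code{DNAStringSet}),
#'   \code{genes} (a \code{GeneModelSet}), \code{fasta} and \code{gtf}
#'   (paths).
#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @export
makeGenomeAndGenes <- function(spec, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(spec@seed)
    chroms <- paste0("chrS", seq_len(spec@n_chroms))
    genome <- DNAStringSet(vapply(chroms, function(ch)
        paste(sample(.BASES, spec@chrom_len, replace = TRUE), collapse = ""),
        character(1)))
    names(genome) <- chroms

    per_chrom <- rep(spec@n_genes %/% spec@n_chroms, spec@n_chroms)
    extra <- spec@n_genes %% spec@n_chroms
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    strand_pattern <- c("+", "+", "-", "+", "-", "+")

    gene_rows <- list()
    exon_list <- list()
    gi <- 0L
    for (ci in seq_len(spec@n_chroms)) {
        cursor <- 2500L
        for (k in seq_len(per_chrom[ci])) {
            gi <- gi + 1L
            n_ex <- sample(2:6, 1L)
            ex_w <- sample(120:200, n_ex, replace = TRUE)
            in_w <- if (n_ex > 1L) sample(300:700, n_ex - 1L,
                                          replace = TRUE) else integer(0)
            span <- sum(ex_w) + sum(in_w)
            if (cursor + span + 2500L > spec@chrom_len)
                stop("infeasible SimSpec: genes do not fit on ",
                     chroms[ci], " (increase chrom_len or reduce n_genes)")
            starts <- cursor + cumsum(c(0L, ex_w[-n_ex] + in_w))
            ends <- starts + ex_w - 1L
            strand <- strand_pattern[((k - 1L) %% length(strand_pattern)) + 1L]
            gid <- sprintf("SYNG%04d", gi)
            sym <- sprintf("GENE%02d", gi)
            gene_rows[[gi]] <- data.frame(
                gene_id = gid, symbol = sym, chrom = chroms[ci],
                start = cursor, end = cursor + span - 1L, strand = strand,
                stringsAsFactors = FALSE)
            exon_list[[gid]] <- data.frame(start = starts, end = ends)
            cursor <- cursor + span + 4000L
        }
    }
    gdf <- do.call(rbind, gene_rows)

    fasta <- file.path(dir, "genome.fa")
    writeXStringSet(genome, fasta)
    if (file.exists(paste0(fasta, ".fai"))) file.remove(paste0(fasta, ".fai"))
    Rsamtools::indexFa(fasta)
    gtf <- file.path(dir, "genes.gtf")
    .writeSynthGtf(gdf, exon_list, gtf)
    list(genome = genome, genes = readGeneModels(gtf), fasta = fasta,
         gtf = gtf)
}

## CDS covers exons 2..n in transcription order (whole exons), so the
## coding start is the transcription-order first base of the second exon.
.writeSynthGtf <- function(gdf, exon_list, path) {
    lines <- character(0)
    attr_str <- function(gid, sym)
        sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s"; gene_type "protein_coding";',
                gid, gid, sym)
    for (i in seq_len(nrow(gdf))) {
        g <- gdf[i, ]
        ex <- exon_list[[g$gene_id]]
        a <- attr_str(g$gene_id, g$symbol)
        lines <- c(lines,
            paste(g$chrom, "synth", "gene", g$start, g$end, ".", g$strand,
                  ".", a, sep = "\t"),
            paste(g$chrom, "synth", "transcript", g$start, g$end, ".",
                  g$strand, ".", a, sep = "\t"))
        for (j in seq_len(nrow(ex)))
            lines <- c(lines, paste(g$chrom, "synth", "exon", ex$start[j],
                                    ex$end[j], ".", g$strand, ".", a,
                                    sep = "\t"))
        ## CDS exons: drop the transcription-order first exon
        cds_idx <- if (g$strand == "-") seq_len(nrow(ex) - 1L) else
            seq(2L, nrow(ex))
        if (nrow(ex) >= 2L) {
            for (j in cds_idx)
                lines <- c(lines, paste(g$chrom, "synth", "CDS", ex$start[j],
                                        ex$end[j], ".", g$strand, "0", a,
                                        sep = "\t"))
        }
    }
    writeLines(lines, path)
}
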