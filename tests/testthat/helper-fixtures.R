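## Shared fixtures, built in code. The synthetic reference dataset and its
## validation results are generated once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

toyGenes <- function() {
    if (is.null(.fixture_cache$toy))
        .fixture_cache$toy <- readGeneModels(
            system.file("extdata", "toy_genes.gtf", package = "fuseval"))
    .fixture_cache$toy
}

## default synthetic study at seed 1, generated once
sharedDataset <- function() {
    if (is.null(.fixture_cache$ds)) {
        dir <- file.path(tempdir(), "fuseval_shared_ds")
        .fixture_cache$ds <- simulateDataset(simSpec(seed = 1L), dir)
    }
    .fixture_cache$ds
}

## filtered calls + validation results over the shared dataset
sharedValidation <- function() {
    if (is.null(.fixture_cache$val)) {
        ds <- sharedDataset()
        genes <- ds$genes
        calls <- rbind(
            as.data.frame(readArribaCalls(ds$arriba, genes, "SYN-CL-1")),
            as.data.frame(readStarFusionCalls(ds$starfusion, genes,
                                              "SYN-CL-1")))
        filt <- filterCalls(FusionCallSet(calls), genes)
        res <- validateFusions(filt$kept, ds$bam, genes, ds$fasta)
        .fixture_cache$val <- list(filt = filt, results = res)
    }
    .fixture_cache$val
}

## random DNA of a given length
randomDna <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## write a FASTA (indexed) from a named character vector
makeTestFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
    x <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(x, path)
    Rsamtools::indexFa(path)
    path
}

## one SAM record as a named list with defaults
samRecord <- function(qname, flag, rname, pos, cigar, seq,
                      mapq = 60L, rnext = "=", pnext = pos, tlen = 0L,
                      qual = NULL) {
    if (is.null(qual)) qual <- paste(rep("F", nchar(seq)), collapse = "")
    list(qname = qname, flag = flag, rname = rname, pos = pos, mapq = mapq,
         cigar = cigar, rnext = rnext, pnext = pnext, tlen = tlen,
         seq = seq, qual = qual)
}

## write records to a coordinate-sorted indexed BAM
makeTestBam <- function(records, seqlens, prefix = tempfile()) {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
    body <- vapply(records, function(r)
        sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, r$rnext,
                r$pnext, r$tlen, r$seq, r$qual), character(1))
    sam <- paste0(prefix, ".sam")
    writeLines(c(header, body), sam)
    bam0 <- Rsamtools::asBam(sam, paste0(prefix, "_u"), overwrite = TRUE,
                             indexDestination = FALSE)
    sorted <- Rsamtools::sortBam(bam0, prefix)
    Rsamtools::indexBam(sorted)
    file.remove(sam, bam0)
    sorted
}

## a clean normalized call row for constructing fixtures
callRow <- function(cell_line = "CL1", caller = "arriba",
                    gene5 = "TOYA", gene3 = "TOYC",
                    gene_id5 = "TOYG0001", gene_id3 = "TOYG0003",
                    chrom5 = "chr1", pos5 = 15000L,
                    chrom3 = "chr2", pos3 = 34000L,
                    gene_strand5 = "+", gene_strand3 = "+",
                    transcribed_strand5 = "sense",
                    transcribed_strand3 = "sense",
                    reading_frame = "in-frame",
                    confidence = if (caller == "arriba") "high" else
                        "not-applicable",
                    event_type = "translocation",
                    split_reads = 5L, spanning_pairs = 3L,
                    site5 = "splice-site", site3 = "splice-site",
                    raw = ".") {
    data.frame(cell_line = cell_line, caller = caller, gene5 = gene5,
               gene3 = gene3, gene_id5 = gene_id5, gene_id3 = gene_id3,
               chrom5 = chrom5, pos5 = pos5, chrom3 = chrom3, pos3 = pos3,
               gene_strand5 = gene_strand5, gene_strand3 = gene_strand3,
               transcribed_strand5 = transcribed_strand5,
               transcribed_strand3 = transcribed_strand3,
               reading_frame = reading_frame, confidence = confidence,
               event_type = event_type, split_reads = split_reads,
               spanning_pairs = spanning_pairs, site5 = site5,
               site3 = site3, raw = raw, stringsAsFactors = FALSE)
}

## brute-force two-sided Fisher p by enumerating all tables with the
## observed margins (independent oracle for small tables)
bruteFisherP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    prob <- vapply(xs, function(x)
        choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
    obs <- prob[xs == a]
    sum(prob[prob <= obs * (1 + 1e-7)])
}

## brute-force BH step-up definition (sort, scale, cumulative min, unsort)
bruteBH <- function(p) {
    n <- length(p)
    if (n == 0L) return(numeric(0))
    o <- order(p)
    scaled <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) if (n > 1)
        scaled[i] <- min(scaled[i], scaled[i + 1])
    out <- numeric(n)
    out[o] <- pmin(scaled, 1)
    out
}
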