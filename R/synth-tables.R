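## Caller-style tables, annotation fixtures and the dataset orchestrator
## for the synthetic study.

## normalized call rows for the planted events and false calls
.truthToCalls <- function(truth, caller) {
    mk <- function(t, has_bp) {
        if (is.null(t) || nrow(t) == 0L) return(NULL)
        data.frame(
            cell_line = t$cell_line, caller = caller,
            gene5 = t$gene5, gene3 = t$gene3,
            gene_id5 = t$gene_id5, gene_id3 = t$gene_id3,
            chrom5 = t$chrom5, pos5 = t$junction5,
            chrom3 = t$chrom3, pos3 = t$junction3,
            gene_strand5 = t$strand5, gene_strand3 = t$strand3,
            transcribed_strand5 = "sense", transcribed_strand3 = "sense",
            reading_frame = t$reading_frame,
            confidence = if (caller == "arriba") t$confidence else
                "not-applicable",
            event_type = if (caller == "arriba") {
                if (has_bp) c(interchromosomal = "translocation",
                              deletion = "deletion",
                              inversion = "inversion")[t$geometry]
                else "translocation"
            } else "ONLY_REF_SPLICE",
            split_reads = 5L, spanning_pairs = 3L,
            site5 = "splice-site", site3 = "splice-site",
            raw = ".", stringsAsFactors = FALSE)
    }
    out <- rbind(mk(truth$events, TRUE), mk(truth$false_calls, FALSE))
    rownames(out) <- NULL
    out
}

## noise rows exercising each pre-validation filter reason exactly once
.noiseCalls <- function(truth, genes, cell_line) {
    g <- geneRanges(genes)
    sym <- mcols(g)$symbol
    base <- .truthToCalls(truth, "arriba")[1, , drop = FALSE]
    noise <- list()
    ## intergenic junction: real pair, 5' junction in a gene desert
    r <- base
    r$pos5 <- 100L
    r$site5 <- "intergenic"
    r$reason <- "intergenic_junction"
    noise[["intergenic"]] <- r
    ## same gene on both sides
    r <- base
    r$gene3 <- r$gene5; r$gene_id3 <- r$gene_id5
    r$chrom3 <- r$chrom5
    r$pos3 <- r$pos5
    r$reason <- "not_two_gene_fusion"
    noise[["same_gene"]] <- r
    ## unpredicted transcribed strand
    r <- base
    r$transcribed_strand3 <- "unknown"
    r$reason <- "strand_unpredicted"
    noise[["strand"]] <- r
    ## IG superlocus partner (starfusion dialect)
    r <- base
    r$caller <- "starfusion"
    r$gene5 <- "IGH@"; r$gene_id5 <- NA_character_
    r$confidence <- "not-applicable"
    r$transcribed_strand5 <- "sense"; r$transcribed_strand3 <- "sense"
    r$reason <- "ig_superlocus"
    noise[["ig"]] <- r
    out <- do.call(rbind, noise)
    rownames(out) <- NULL
    out
}

#' Emit caller-dialect tables for a truth set
#'
#' Writes every true event and false call in both the Arriba and the
#' STAR-Fusion dialect with correct junctions, strands, frames and
#' confidence labels. With \code{noise = TRUE}, extra syntactically valid
#' rows are added that trigger each pre-validation filter reason exactly
#' once (three in the Arriba table, one in the STAR-Fusion table).
#'
#' @param truth truth set from \code{\link{plantFusionEvents}}.
#' @param genes the \code{GeneModelSet}.
#' @param dir output directory.
#' @param noise add filter-triggering noise rows (default TRUE).
#' @return a list with paths \code{arriba}, \code{starfusion} and a
#'   data.frame \code{noise} describing the expected filter reasons.
#' @export
emitCallerTables <- function(truth, genes, dir, noise = TRUE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ar <- .truthToCalls(truth, "arriba")
    sf <- .truthToCalls(truth, "starfusion")
    ndf <- NULL
    if (noise) {
        ndf <- .noiseCalls(truth, genes,
                           truth$events$cell_line[1])
        nn <- ndf[, setdiff(names(ndf), "reason")]
        ar <- rbind(ar, nn[nn$caller == "arriba", ])
        sf <- rbind(sf, nn[nn$caller == "starfusion", ])
    }
    arriba_path <- file.path(dir, "arriba.tsv")
    sf_path <- file.path(dir, "starfusion.tsv")
    writeArribaTable(FusionCallSet(ar), arriba_path)
    writeStarFusionTable(FusionCallSet(sf), sf_path)
    list(arriba = arriba_path, starfusion = sf_path, noise = ndf)
}

#' Emit annotation resource fixtures for a truth set
#'
#' Builds small resource tables wired to the planted events: a kinase
#' table containing the 3' partners of the first two events, miRNA
#' hairpins planted inside the first event's 3' fused portion plus two
#' boundary probes relative to the second event's 3' partner (one ending
#' exactly 2 kb downstream of the gene end, one just beyond), known-fusion
#' entries for the first two event pairs (mitelman and tumorfusions, the
#' latter with recorded junctions), a cancer-gene list and a tissue map.
#'
#' @param genes the \code{GeneModelSet}.
#' @param truth truth set from \code{\link{plantFusionEvents}}.
#' @param dir output directory.
#' @param sample_tissue tissue recorded for the simulated cell line.
#' @return a list of file paths plus \code{mirna_expect}, a data.frame of
#'   planted hairpins and whether each should be annotated.
#' @export
emitAnnotationFixtures <- function(genes, truth, dir,
                                   sample_tissue = "lung") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ev <- truth$events
    stopifnot(NROW(ev) >= 1L)
    e1 <- ev[1, ]
    e2 <- ev[min(2L, nrow(ev)), ]

    kin <- data.frame(symbol = unique(c(e1$gene3, e2$gene3)),
                      group = c("TK", "AGC")[seq_along(unique(c(e1$gene3,
                                                                e2$gene3)))])
    kin_path <- file.path(dir, "kinases.tsv")
    utils::write.table(kin, kin_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    ## hairpin inside the fused portion of e1's 3' partner
    g1 <- getGene(genes, e1$gene_id3)
    if (as.character(strand(g1)) == "-") {
        mid <- floor((start(g1) + e1$junction3) / 2)
    } else {
        mid <- floor((e1$junction3 + end(g1)) / 2)
    }
    ## boundary probes downstream of e2's 3' partner gene end
    g2 <- getGene(genes, e2$gene_id3)
    if (as.character(strand(g2)) == "-") {
        at_edge <- c(start(g2) - 2000L, start(g2) - 2000L + 59L)
        beyond <- c(start(g2) - 2060L, start(g2) - 2001L)
    } else {
        at_edge <- c(end(g2) + 2000L - 59L, end(g2) + 2000L)
        beyond <- c(end(g2) + 2001L, end(g2) + 2060L)
    }
    mi <- data.frame(
        chrom = c(e1$chrom3, e2$chrom3, e2$chrom3),
        start = c(mid, at_edge[1], beyond[1]),
        end = c(mid + 59L, at_edge[2], beyond[2]),
        name = c("syn-mir-1", "syn-mir-2", "syn-mir-3"),
        strand = "+", stringsAsFactors = FALSE)
    mi_path <- file.path(dir, "mirnas.tsv")
    utils::write.table(mi, mi_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mirna_expect <- data.frame(
        name = mi$name,
        host_gene = c(e1$gene3, e2$gene3, e2$gene3),
        event_id = c(e1$event_id, e2$event_id, e2$event_id),
        expected = c(TRUE, TRUE, FALSE))

    kf <- data.frame(
        source = c("mitelman", "tumorfusions"),
        gene5 = c(e1$gene5, e2$gene5),
        gene3 = c(e1$gene3, e2$gene3),
        tissue = c(sample_tissue, sample_tissue),
        junction5 = c(NA, paste0(e2$chrom5, ":", e2$junction5)),
        junction3 = c(NA, paste0(e2$chrom3, ":", e2$junction3)),
        stringsAsFactors = FALSE)
    kf_path <- file.path(dir, "known_fusions.tsv")
    utils::write.table(kf, kf_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    cgc <- unique(c(e1$gene5, e2$gene3))
    cgc_path <- file.path(dir, "cancer_genes.txt")
    writeLines(cgc, cgc_path)

    tm <- data.frame(sample_tissue = c(sample_tissue, sample_tissue),
                     db_tissue = c(sample_tissue, "bronchus"),
                     relation = c("exact", "related"))
    tm_path <- file.path(dir, "tissue_map.tsv")
    utils::write.table(tm, tm_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(kinases = kin_path, mirnas = mi_path, known_fusions = kf_path,
         cancer_genes = cgc_path, tissue_map = tm_path,
         mirna_expect = mirna_expect, sample_tissue = sample_tissue)
}

#' Generate a complete synthetic fusion dataset
#'
#' Runs the whole generator: genome and gene models, planted fusion
#' events, simulated WGS reads, caller tables, annotation fixtures and
#' truth tables, all under one output directory with a manifest recording
#' the simulation conditions, seed and file checksums. All outputs are
#' bit-reproducible under a fixed seed.
#'
#' @param spec a \code{SimSpec}.
#' @param dir output directory.
#' @param noise include filter-triggering noise rows in the caller tables.
#' @return a list with all file paths (\code{fasta}, \code{gtf},
#'   \code{bam}, \code{arriba}, \code{starfusion}, resource files,
#'   \code{truth_events}, \code{truth_false_calls}, \code{manifest}) plus
#'   the in-memory \code{genes}, \code{truth}, \code{noise} and
#'   \code{spec}.
#' @export
simulateDataset <- function(spec, dir, noise = TRUE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gg <- makeGenomeAndGenes(spec, dir)
    truth <- plantFusionEvents(gg$genes, spec)
    bam <- simulateWgsReads(gg$genome, truth, spec, file.path(dir, "wgs"))
    tables <- emitCallerTables(truth, gg$genes, dir, noise = noise)
    fixtures <- emitAnnotationFixtures(gg$genes, truth, dir)

    te_path <- file.path(dir, "truth_events.tsv")
    utils::write.table(truth$events, te_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tf_path <- file.path(dir, "truth_false_calls.tsv")
    utils::write.table(truth$false_calls, tf_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)

    files <- c(fasta = gg$fasta, gtf = gg$gtf, bam = bam,
               arriba = tables$arriba, starfusion = tables$starfusion,
               kinases = fixtures$kinases, mirnas = fixtures$mirnas,
               known_fusions = fixtures$known_fusions,
               cancer_genes = fixtures$cancer_genes,
               tissue_map = fixtures$tissue_map,
               truth_events = te_path, truth_false_calls = tf_path)
    manifest <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(list(spec = simSpecAsList(spec),
                          files = as.list(tools::md5sum(sort(unname(files))))),
                     manifest)
    c(as.list(files), list(manifest = manifest, genes = gg$genes,
                           truth = truth, noise = tables$noise,
                           spec = spec,
                           sample_tissue = fixtures$sample_tissue,
                           mirna_expect = fixtures$mirna_expect))
}
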