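test_that("genome and gene generation is deterministic and sized", {
    spec <- simSpec(seed = 5L, n_genes = 4L, n_chroms = 2L,
                    chrom_len = 30000L, n_true_fusions = 1L,
                    n_false_calls = 0L)
    d1 <- file.path(tempdir(), "synth_det1")
    d2 <- file.path(tempdir(), "synth_det2")
    g1 <- makeGenomeAndGenes(spec, d1)
    g2 <- makeGenomeAndGenes(spec, d2)
    expect_identical(readLines(g1$fasta), readLines(g2$fasta))
    expect_identical(readLines(g1$gtf), readLines(g2$gtf))
    expect_equal(length(g1$genes), 4L)
    expect_equal(sum(grepl("\tgene\t", readLines(g1$gtf))), 4L)
})

test_that("an infeasible genome spec raises an error", {
    spec <- simSpec(seed = 1L, n_genes = 40L, chrom_len = 12000L)
    expect_error(makeGenomeAndGenes(spec, tempdir()), "infeasible")
})

test_that("planted events honour their geometries and intron placement", {
    ds <- sharedDataset()
    ev <- ds$truth$events
    genes <- ds$genes
    for (i in seq_len(nrow(ev))) {
        e <- ev[i, ]
        if (e$geometry == "interchromosomal") {
            expect_true(e$chrom5 != e$chrom3)
        } else {
            expect_equal(e$chrom5, e$chrom3)
            if (e$geometry == "deletion") expect_lt(e$bp5, e$bp3)
            if (e$geometry == "inversion")
                expect_true(e$strand5 != e$strand3)
        }
        ## junctions at exon boundaries, breakpoints in introns
        for (side in c("5", "3")) {
            gid <- e[[paste0("gene_id", side)]]
            ex <- as.data.frame(exonsByGene(genes)[[gid]])
            jx <- e[[paste0("junction", side)]]
            bp <- e[[paste0("bp", side)]]
            expect_true(jx %in% c(ex$start, ex$end))
            expect_false(any(bp >= ex$start & bp <= ex$end))
        }
        ## breakpoints inside their side's search region
        call <- callRow(cell_line = e$cell_line,
                        gene5 = e$gene5, gene_id5 = e$gene_id5,
                        gene3 = e$gene3, gene_id3 = e$gene_id3,
                        chrom5 = e$chrom5, pos5 = e$junction5,
                        chrom3 = e$chrom3, pos3 = e$junction3,
                        gene_strand5 = e$strand5,
                        gene_strand3 = e$strand3)
        r <- buildSearchRegions(call, genes)
        expect_true(e$bp5 >= r$five_prime$start &&
                    e$bp5 <= r$five_prime$end)
        expect_true(e$bp3 >= r$three_prime$start &&
                    e$bp3 <= r$three_prime$end)
    }
    expect_equal(nrow(ds$truth$false_calls), 2L)
})

test_that("caller tables round-trip junctions and count rows as planned", {
    ds <- sharedDataset()
    ar <- as.data.frame(readArribaCalls(ds$arriba, ds$genes, "SYN-CL-1"))
    ## 3 true + 2 false + 3 arriba noise rows
    expect_equal(nrow(ar), 8L)
    sf <- as.data.frame(readStarFusionCalls(ds$starfusion, ds$genes,
                                            "SYN-CL-1"))
    expect_equal(nrow(sf), 6L)                   # 5 + 1 IG noise row
    ev <- ds$truth$events
    ## noise rows reuse event gene pairs; compare against the kept set
    ar <- as.data.frame(filterCalls(FusionCallSet(ar), ds$genes)$kept)
    for (i in seq_len(nrow(ev))) {
        row <- ar[ar$gene5 == ev$gene5[i] & ar$gene3 == ev$gene3[i], ]
        expect_equal(row$pos5, ev$junction5[i])
        expect_equal(row$pos3, ev$junction3[i])
        expect_equal(row$reading_frame, ev$reading_frame[i])
        expect_equal(row$confidence, ev$confidence[i])
    }
})

test_that("simulated reads are well-formed and carry the planted evidence", {
    ds <- sharedDataset()
    ## external format validation of the generated BAM
    expect_equal(system2("samtools", c("quickcheck", ds$bam)), 0L)
    ## breakpoint-spanning discordant pairs at roughly the physical
    ## coverage implied by the insert model (binomial-scale tolerance)
    spec <- ds$spec
    expected <- spec@depth * spec@insert_mean / (2 * spec@read_len)
    ev <- ds$truth$events[1, ]
    call <- callRow(gene5 = ev$gene5, gene_id5 = ev$gene_id5,
                    gene3 = ev$gene3, gene_id3 = ev$gene_id3,
                    chrom5 = ev$chrom5, pos5 = ev$junction5,
                    chrom3 = ev$chrom3, pos3 = ev$junction3,
                    gene_strand5 = ev$strand5, gene_strand3 = ev$strand3)
    r <- buildSearchRegions(call, ds$genes)
    pairs <- findDiscordantPairs(ds$bam, r$five_prime, r$three_prime)
    expect_gt(nrow(pairs), 0L)
    expect_lt(abs(nrow(pairs) - expected), 3 * sqrt(expected) + 3)
    ## split-read soft clips vote for exactly the planted coordinates
    bps <- callBreakpoints(ds$bam, r$five_prime, r$three_prime, pairs,
                           ds$fasta)
    expect_equal(sort(bps$pos), sort(c(ev$bp5, ev$bp3)))
})

test_that("the full generator is bit-reproducible under a fixed seed", {
    spec <- simSpec(seed = 3L, chrom_len = 30000L, n_genes = 6L,
                    n_true_fusions = 1L, n_false_calls = 1L,
                    geometries = "interchromosomal")
    d1 <- file.path(tempdir(), "ds_rep1")
    d2 <- file.path(tempdir(), "ds_rep2")
    r1 <- simulateDataset(spec, d1)
    r2 <- simulateDataset(spec, d2)
    for (f in c("fasta", "gtf", "bam", "arriba", "starfusion",
                "truth_events")) {
        expect_identical(unname(tools::md5sum(r1[[f]])),
                         unname(tools::md5sum(r2[[f]])),
                         info = f)
    }
})

test_that("planted annotation fixtures behave at the 2 kb boundary", {
    ds <- sharedDataset()
    res <- readAnnotationResources(
        kinases = ds$kinases, mirnas = ds$mirnas,
        known_fusions = ds$known_fusions, cancer_genes = ds$cancer_genes,
        tissue_map = ds$tissue_map)
    ev <- ds$truth$events
    calls <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
        callRow(cell_line = ev$cell_line[i],
                gene5 = ev$gene5[i], gene_id5 = ev$gene_id5[i],
                gene3 = ev$gene3[i], gene_id3 = ev$gene_id3[i],
                chrom5 = ev$chrom5[i], pos5 = ev$junction5[i],
                chrom3 = ev$chrom3[i], pos3 = ev$junction3[i],
                gene_strand5 = ev$strand5[i],
                gene_strand3 = ev$strand3[i])))
    out <- annotateMirnaHosts(calls, ds$genes, res)
    expect_out <- ds$mirna_expect
    hosts <- strsplit(out$mirna_host3, ",")
    for (j in seq_len(nrow(expect_out))) {
        i <- match(expect_out$event_id[j], ev$event_id)
        expect_equal(expect_out$name[j] %in% hosts[[i]],
                     expect_out$expected[j],
                     info = expect_out$name[j])
    }
})
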