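## small resource fixture written to disk and read back through the
## resource loader
annoResources <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        d <- file.path(tempdir(), "anno_fixtures")
        dir.create(d, showWarnings = FALSE)
        write.table(data.frame(symbol = c("TOYC", "TOYB"),
                               group = c("TK", "AGC")),
                    file.path(d, "kin.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write.table(data.frame(
            chrom = c("chr2", "chr2", "chr2", "chr2"),
            start = c(34100L, 41441L, 42001L, 33000L),
            end = c(34160L, 41500L, 42060L, 33060L),
            name = c("mir-in", "mir-downstream", "mir-beyond",
                     "mir-upstream"),
            strand = "+"),
            file.path(d, "mir.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        write.table(data.frame(
            source = c("mitelman", "mitelman", "tumorfusions",
                       "tumorfusions"),
            gene5 = c("TOYA", "TOYB", "TOYA", "TOYA"),
            gene3 = c("TOYC", "TOYA", "TOYC", "TOYB"),
            tissue = c("lung", "weird_tissue", "lung", "lung"),
            junction5 = c(NA, NA, "chr1:15000", NA),
            junction3 = c(NA, NA, "chr2:34000", NA)),
            file.path(d, "kf.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        writeLines(c("TOYA", "TOYB"), file.path(d, "cgc.txt"))
        write.table(data.frame(sample_tissue = c("lung", "lung"),
                               db_tissue = c("lung", "bronchus"),
                               relation = c("exact", "related")),
                    file.path(d, "tm.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        cache <<- readAnnotationResources(
            kinases = file.path(d, "kin.tsv"),
            mirnas = file.path(d, "mir.tsv"),
            known_fusions = file.path(d, "kf.tsv"),
            cancer_genes = file.path(d, "cgc.txt"),
            tissue_map = file.path(d, "tm.tsv"))
        cache
    }
})

test_that("alternative-splicing ids group distinct junctions only", {
    df <- rbind(
        callRow(pos3 = 34000L), callRow(pos3 = 39000L),   # same pair, 2 jxn
        callRow(cell_line = "CL2"),                       # other cell line
        callRow(gene5 = "TOYB", gene_id5 = "TOYG0002", chrom5 = "chr2",
                pos5 = 54000L),                           # lone pair
        callRow(gene5 = "TOYB", gene_id5 = "TOYG0002", chrom5 = "chr2",
                pos5 = 54000L))                           # exact duplicate
    out <- assignAltSpliceIds(df)
    expect_equal(out$alt_splice_id[1], out$alt_splice_id[2])
    expect_false(is.na(out$alt_splice_id[1]))
    ## identical junctions are duplicates, not splicing; singletons and
    ## cross-cell-line repeats get nothing
    expect_true(all(is.na(out$alt_splice_id[3:5])))
    ## deterministic under permutation
    perm <- assignAltSpliceIds(df[c(4, 2, 5, 1, 3), ])
    expect_equal(sort(table(out$alt_splice_id)),
                 sort(table(perm$alt_splice_id)))
})

test_that("promoter-swap flags compare junction and coding start in tx order", {
    gm <- toyGenes()
    ## TOYA (+): coding start 14000
    expect_true(flagPromoterSwap(callRow(pos5 = 11500L), gm)$promoter_swap)
    expect_false(flagPromoterSwap(callRow(pos5 = 15000L), gm)$promoter_swap)
    ## TOYB (-): coding start 54600; genomically higher = upstream
    minus <- callRow(gene5 = "TOYB", gene_id5 = "TOYG0002",
                     chrom5 = "chr2", pos5 = 59000L, gene_strand5 = "-")
    expect_true(flagPromoterSwap(minus, gm)$promoter_swap)
    minus$pos5 <- 50500L
    expect_false(flagPromoterSwap(minus, gm)$promoter_swap)
    ## non-coding 5' partner is always a candidate
    gtf <- tempfile(fileext = ".gtf")
    writeLines(c(
        paste("chr1", "t", "gene", 100, 900, ".", "+", ".",
              'gene_id "NC1"; gene_name "NCA"; gene_type "lncRNA";',
              sep = "\t"),
        paste("chr1", "t", "exon", 100, 900, ".", "+", ".",
              'gene_id "NC1"; gene_name "NCA"; gene_type "lncRNA";',
              sep = "\t")), gtf)
    ncg <- readGeneModels(gtf)
    nc <- callRow(gene5 = "NCA", gene_id5 = "NC1", chrom5 = "chr1",
                  pos5 = 800L)
    expect_true(flagPromoterSwap(nc, ncg)$promoter_swap)
})

test_that("kinase lookup respects frame and the antisense exclusion", {
    res <- annoResources()
    out <- annotateKinases(callRow(), res)       # 3' partner TOYC is TK
    expect_equal(out$kinase3, "TK")
    expect_true(is.na(out$kinase5))
    expect_true(out$in_frame_kinase)
    out2 <- annotateKinases(callRow(reading_frame = "out-of-frame"), res)
    expect_false(out2$in_frame_kinase)
    out3 <- annotateKinases(callRow(transcribed_strand3 = "antisense"),
                            res)
    expect_true(is.na(out3$kinase3))
    out4 <- annotateKinases(callRow(gene3 = "TOYA",
                                    gene_id3 = "TOYG0001",
                                    chrom3 = "chr1", pos3 = 16000L), res)
    expect_true(is.na(out4$kinase5) && is.na(out4$kinase3))
})

test_that("miRNA hosts require the hairpin inside the fused portion", {
    res <- annoResources()
    gm <- toyGenes()
    ## TOYC (+) as 3' partner, junction 34000, gene end 40000 (+2 kb)
    out <- annotateMirnaHosts(callRow(), gm, res)
    hosts <- strsplit(out$mirna_host3, ",")[[1]]
    expect_true("mir-in" %in% hosts)             # inside fused portion
    expect_true("mir-downstream" %in% hosts)     # 1.5 kb downstream
    expect_false("mir-beyond" %in% hosts)        # past the 2 kb window
    expect_false("mir-upstream" %in% hosts)      # before the junction
    ## antisense partners are never annotated
    anti <- annotateMirnaHosts(callRow(transcribed_strand3 = "antisense"),
                               gm, res)
    expect_equal(anti$mirna_host3, "")
    ## the exact 2 kb boundary is inclusive
    expect_true(41500 <= 40000 + 2000)
})

test_that("database matching is order-sensitive with tissue categories", {
    res <- annoResources()
    out <- matchKnownFusionDb(callRow(), res, tissue = c(CL1 = "lung"))
    expect_equal(out$mitelman_match, "exact_tissue")
    expect_equal(out$tumorfusions_match, "exact_tissue")
    expect_true(out$junction_match_tumorfusions)
    ## reversed pair does not match
    rev_pair <- callRow(gene5 = "TOYC", gene_id5 = "TOYG0003",
                        chrom5 = "chr2", pos5 = 34000L,
                        gene3 = "TOYA", gene_id3 = "TOYG0001",
                        chrom3 = "chr1", pos3 = 15000L)
    out2 <- matchKnownFusionDb(rev_pair, res, tissue = c(CL1 = "lung"))
    expect_equal(out2$mitelman_match, "none")
    ## junction mismatch clears the junction flag but not the match
    shifted <- callRow(pos3 = 39000L)
    out3 <- matchKnownFusionDb(shifted, res, tissue = c(CL1 = "lung"))
    expect_equal(out3$tumorfusions_match, "exact_tissue")
    expect_false(out3$junction_match_tumorfusions)
    ## a database tissue absent from the tissue map
    unk <- callRow(gene5 = "TOYB", gene_id5 = "TOYG0002", chrom5 = "chr2",
                   pos5 = 54000L, gene3 = "TOYA", gene_id3 = "TOYG0001",
                   chrom3 = "chr1", pos3 = 15000L)
    out4 <- matchKnownFusionDb(unk, res, tissue = c(CL1 = "lung"))
    expect_equal(out4$mitelman_match, "unknown_tissue")
    ## antisense pairs are excluded from matching
    anti <- matchKnownFusionDb(callRow(transcribed_strand5 = "antisense"),
                               res, tissue = c(CL1 = "lung"))
    expect_equal(anti$mitelman_match, "none")
})

test_that("cancer-gene flags follow membership per partner", {
    res <- annoResources()
    out <- annotateCgc(callRow(), res)
    expect_true(out$cgc5)                        # TOYA listed
    expect_false(out$cgc3)                       # TOYC not listed
    both <- annotateCgc(callRow(gene3 = "TOYB", gene_id3 = "TOYG0002",
                                chrom3 = "chr2", pos3 = 54000L), res)
    expect_true(both$cgc5 && both$cgc3)
    neither <- annotateCgc(callRow(gene5 = "TOYC", gene_id5 = "TOYG0003",
                                   chrom5 = "chr2", pos5 = 34000L,
                                   gene3 = "TOYC", gene_id3 = "TOYG0003",
                                   chrom3 = "chr2", pos3 = 34000L), res)
    expect_false(neither$cgc5 || neither$cgc3)
})

test_that("twins need different callers and identical annotations", {
    a <- callRow(caller = "arriba")
    s <- callRow(caller = "starfusion", confidence = "not-applicable")
    base <- rbind(a, s)
    out <- assignTwinIds(base)
    expect_equal(out$twin_id[1], out$twin_id[2])
    expect_false(is.na(out$twin_id[1]))
    ## differing reading frame breaks annotation equality
    s2 <- s; s2$reading_frame <- "out-of-frame"
    out2 <- assignTwinIds(rbind(a, s2))
    expect_true(all(is.na(out2$twin_id)))
    ## same caller twice never twins
    out3 <- assignTwinIds(rbind(a, a))
    expect_true(all(is.na(out3$twin_id)))
    ## the relation forms disjoint pairs
    out4 <- assignTwinIds(rbind(a, a, s, s))
    expect_equal(sum(!is.na(out4$twin_id)), 4L)
    expect_equal(max(table(out4$twin_id)), 2L)
})

test_that("gene-pair collapsing counts each pair once with any-semantics", {
    df <- rbind(
        callRow(pos3 = 34000L, reading_frame = "in-frame"),
        callRow(pos3 = 39000L, reading_frame = "out-of-frame"),
        callRow(pos3 = 34000L, reading_frame = "out-of-frame"),
        callRow(gene5 = "TOYB", gene_id5 = "TOYG0002", chrom5 = "chr2",
                pos5 = 54000L, reading_frame = "unknown"))
    groups <- collapseGenePairs(df)
    expect_equal(nrow(groups), 2L)
    g1 <- groups[groups$gene5 == "TOYA", ]
    expect_equal(g1$n_transcripts, 3L)
    expect_equal(g1$n_junctions, 2L)
    expect_true(g1$alt_splice)
    expect_true(g1$has_in_frame)                 # any member in-frame
    expect_false(groups[groups$gene5 == "TOYB", ]$has_in_frame)
    ## group count never exceeds transcript count; equality iff unique
    expect_lte(nrow(groups), nrow(df))
    expect_equal(nrow(collapseGenePairs(df[c(1, 4), ])), 2L)
    expect_equal(nrow(collapseGenePairs(df[0, ])), 0L)
    ## permutation invariance
    perm <- collapseGenePairs(df[c(3, 1, 4, 2), ])
    expect_equal(perm[order(perm$gene5), c("n_transcripts", "n_junctions")],
                 groups[order(groups$gene5),
                        c("n_transcripts", "n_junctions")])
})

test_that("annotation operations are pure", {
    res <- annoResources()
    gm <- toyGenes()
    df <- rbind(callRow(), callRow(pos3 = 39000L))
    once <- annotateFusions(df, gm, res, tissue = c(CL1 = "lung"))
    twice <- annotateFusions(df, gm, res, tissue = c(CL1 = "lung"))
    expect_identical(once, twice)
    ## validation evidence columns are untouched
    expect_identical(once$pos5, df$pos5)
    expect_identical(once$split_reads, df$split_reads)
})
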