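## build a synthetic secondary-screen response table: `lines` cell lines,
## per treatment the same concentration ladder, triplicate values
makeScreen <- function(lines, drugs, concs = c(0.61, 2.5, 10),
                       shift_gene_lines = character(0), shift = 0,
                       shift_drug = NULL, seed = 1) {
    set.seed(seed)
    rows <- list()
    for (dg in drugs) for (cl in lines) for (cc in concs) for (r in 1:3) {
        mu <- if (!is.null(shift_drug) && dg == shift_drug &&
                  cl %in% shift_gene_lines) shift else 0
        rows[[length(rows) + 1L]] <- data.frame(
            cell_line = cl, drug = dg, plate = "P1", concentration = cc,
            value = stats::rnorm(1, mu, 0.5), replicate = r,
            stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

## a collapsed-group table with in-frame fusions of one gene in given
## lines; the 3' partners are line-specific so only `gene` recurs
fusionGroups <- function(gene, lines) {
    do.call(rbind, lapply(lines, function(cl)
        data.frame(cell_line = cl, caller = "arriba", gene5 = gene,
                   gene3 = paste0("OTH_", cl), n_transcripts = 1L,
                   n_junctions = 1L, alt_splice = FALSE,
                   has_in_frame = TRUE, promoter_swap = FALSE,
                   stringsAsFactors = FALSE)))
}

test_that("sparse concentrations are removed at the 80% boundary", {
    lines <- sprintf("CL%03d", 1:100)
    resp <- makeScreen(lines, "drugA", concs = c(1, 2))
    ## concentration 2 present in only 79 of 100 lines
    drop79 <- !(resp$concentration == 2 &
                resp$cell_line %in% lines[80:100])
    got <- filterConcentrations(resp[drop79, ], lines)
    expect_false(2 %in% got$concentration)
    ## exactly 80% is kept ("at least 80%")
    drop80 <- !(resp$concentration == 2 &
                resp$cell_line %in% lines[81:100])
    got80 <- filterConcentrations(resp[drop80, ], lines)
    expect_true(2 %in% got80$concentration)
    ## universal concentrations pass unchanged
    expect_equal(nrow(filterConcentrations(resp, lines)), nrow(resp))
})

test_that("one concentration is selected closest to the mean", {
    expect_equal(selectTreatmentConcentration(c(0.61, 2.5, 10)), 2.5)
    expect_equal(selectTreatmentConcentration(5), 5)
    ## tie between 1 and 3 around mean 2 breaks toward the smaller
    expect_equal(selectTreatmentConcentration(c(1, 3)), 1)
    expect_warning(sel <- selectTreatmentConcentration(numeric(0)),
                   "dropped")
    expect_true(is.na(sel))
})

test_that("gene eligibility needs qualifying fusions in enough lines", {
    screened <- c("CL1", "CL2", "CL3")
    expect_equal(eligibleGenes(fusionGroups("KIN1", c("CL1", "CL2")),
                               screened), "KIN1")
    expect_equal(eligibleGenes(fusionGroups("KIN1", "CL1"), screened),
                 character(0))
    oof <- fusionGroups("KIN1", c("CL1", "CL2"))
    oof$has_in_frame <- FALSE
    expect_equal(eligibleGenes(oof, screened), character(0))
    ## promoter-swap fusions qualify too
    oof$promoter_swap <- TRUE
    expect_equal(eligibleGenes(oof, screened), "KIN1")
    ## fusions in unscreened lines do not count
    expect_equal(eligibleGenes(fusionGroups("KIN1", c("X1", "X2")),
                               screened), character(0))
})

test_that("the Welch test matches the formula and handles degeneracy", {
    r <- welchT(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r$t, 0)
    expect_equal(r$p, 1)
    ## hand computation via the Welch/Satterthwaite formulae
    a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
    se2 <- var(a) / 4 + var(b) / 4
    t_hand <- (mean(a) - mean(b)) / sqrt(se2)
    df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
    r2 <- welchT(a, b)
    expect_equal(r2$t, t_hand)
    expect_equal(r2$df, df_hand)
    expect_equal(r2$p, 2 * pt(-abs(t_hand), df_hand))
    ## independent library cross-check
    tt <- stats::t.test(a, b)
    expect_equal(r2$t, unname(tt$statistic))
    expect_equal(r2$p, tt$p.value)
    ## zero-variance groups: flagged convention, not an error
    r3 <- welchT(c(0, 0, 0, 0), c(1, 1, 1, 1))
    expect_true(r3$degenerate)
    expect_equal(r3$p, 0)
    expect_equal(welchT(c(2, 2), c(2, 2))$p, 1)
    ## groups below two values skip the test
    expect_null(welchT(1, c(1, 2)))
})

test_that("a planted response shift wins the association table", {
    lines <- sprintf("CL%02d", 1:25)
    fused <- lines[1:5]
    resp <- makeScreen(lines, c("drugA", "drugB", "drugC"),
                       shift_gene_lines = fused, shift = -2,
                       shift_drug = "drugB", seed = 3)
    groups <- fusionGroups("KIN1", fused)
    assoc <- runFusionDrugAssociation(groups, resp)
    expect_equal(nrow(assoc), 3L)                # one gene x three drugs
    expect_equal(assoc$gene[1], "KIN1")
    expect_equal(assoc$drug[1], "drugB")         # smallest adjusted p
    expect_lt(assoc$p_adj[1], 0.05)
    expect_equal(assoc$n_with[1], 5L)
    expect_equal(assoc$n_without[1], 20L)
    expect_lt(assoc$mean_diff[1], 0)
    ## selected concentration is the one closest to the ladder mean
    expect_equal(unique(assoc$concentration), 2.5)
    ## BH is applied once across all tests
    expect_equal(assoc$p_adj, bhAdjust(assoc$p)[order(bhAdjust(assoc$p))])
    ## invariance to cell-line ordering
    assoc2 <- runFusionDrugAssociation(groups,
                                       resp[rev(seq_len(nrow(resp))), ])
    expect_equal(assoc$p, assoc2$p)
    ## empty eligible set gives an empty table
    empty <- runFusionDrugAssociation(fusionGroups("KIN1", "CL01"), resp)
    expect_equal(nrow(empty), 0L)
})

test_that("a malformed response table is rejected with a clear error", {
    f <- tempfile()
    write.table(data.frame(cell_line = "CL1", drug = "d"), f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    expect_error(readDrugResponses(f), "missing column")
    f2 <- tempfile()
    write.table(data.frame(cell_line = "CL1", drug = "d", plate = "P1",
                           concentration = -1, value = 0), f2, sep = "\t",
                quote = FALSE, row.names = FALSE)
    expect_error(readDrugResponses(f2), "positive")
})
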