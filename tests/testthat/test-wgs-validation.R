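## Custom read fixtures around a TOYA(+) -> TOYC(+) fusion with planted
## breakpoints chr1:15230 / chr2:33800 (RNA junctions 15000 / 34000).

bpFixture <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        set.seed(11)
        chr1 <- randomDna(25000)
        chr2 <- randomDna(45000)
        fasta <- makeTestFasta(c(chr1 = chr1, chr2 = chr2))
        sub <- function(s, a, b) substring(s, a, b)
        bp5 <- 15230L; bp3 <- 33800L
        qual70_30 <- function(q1, q2)
            paste0(strrep("F", 70), strrep(q2, 30))
        pairs <- list()
        for (i in 1:3) {
            aPos <- 15040L + 10L * i
            bPos <- 33800L + 10L * i
            mapq <- if (i == 3) 10L else 60L     # third pair fails MAPQ
            pairs <- c(pairs, list(
                samRecord(paste0("dp", i), 65L, "chr1", aPos, "100M",
                          sub(chr1, aPos, aPos + 99L), mapq = mapq,
                          rnext = "chr2", pnext = bPos),
                samRecord(paste0("dp", i), 129L, "chr2", bPos, "100M",
                          sub(chr2, bPos, bPos + 99L), rnext = "chr1",
                          pnext = aPos)))
        }
        splitA <- lapply(1:4, function(i)
            samRecord(paste0("sa", i), 0L, "chr1", 15161L, "70M30S",
                      paste0(sub(chr1, 15161L, bp5),
                             sub(chr2, bp3, bp3 + 29L))))
        splitB <- lapply(1:4, function(i)
            samRecord(paste0("sb", i), 0L, "chr2", bp3, "30S70M",
                      paste0(sub(chr1, bp5 - 29L, bp5),
                             sub(chr2, bp3, bp3 + 69L))))
        lowq <- lapply(splitA, function(r) {
            r$qual <- qual70_30("F", "&")        # clip bases at phred 5
            r$qname <- paste0(r$qname, "_lowq")
            r
        })
        randclip <- lapply(1:4, function(i)
            samRecord(paste0("rc", i), 0L, "chr1", 15161L, "70M30S",
                      paste0(sub(chr1, 15161L, bp5), randomDna(30))))
        concordant <- lapply(1:50, function(i) {
            s <- 15000L + 20L * i
            samRecord(paste0("bg", i), 99L, "chr1", s, "100M",
                      sub(chr1, s, s + 99L), pnext = s + 200L,
                      tlen = 300L)
        })
        seqlens <- c(chr1 = 25000L, chr2 = 45000L)
        cache <<- list(
            fasta = fasta, seqlens = seqlens, chr1 = chr1, chr2 = chr2,
            bp5 = bp5, bp3 = bp3,
            full = makeTestBam(c(pairs, splitA, splitB, concordant),
                               seqlens),
            pairs_only = makeTestBam(c(pairs, concordant), seqlens),
            lowq_clips = makeTestBam(c(pairs, lowq), seqlens),
            rand_clips = makeTestBam(c(pairs, randclip), seqlens),
            background_only = makeTestBam(concordant, seqlens))
        cache
    }
})

toyCall <- function() callRow()                  # TOYA -> TOYC

toyRegions <- function() buildSearchRegions(toyCall(), toyGenes())

test_that("region scans keep only primary, unique, well-mapped reads", {
    fx <- bpFixture()
    reads <- lapply(1:50, function(i) {
        s <- 15000L + 20L * i
        samRecord(paste0("r", i), 0L, "chr1", s, "100M",
                  substring(fx$chr1, s, s + 99L))
    })
    extra <- list(
        samRecord("zero_mapq", 0L, "chr1", 15100L, "100M",
                  substring(fx$chr1, 15100L, 15199L), mapq = 0L),
        samRecord("dup", 1024L, "chr1", 15100L, "100M",
                  substring(fx$chr1, 15100L, 15199L)),
        samRecord("secondary", 256L, "chr1", 15100L, "100M",
                  substring(fx$chr1, 15100L, 15199L)),
        samRecord("suppl", 2048L, "chr1", 15100L, "100M",
                  substring(fx$chr1, 15100L, 15199L)))
    bam <- makeTestBam(c(reads, extra), fx$seqlens)
    got <- scanRegion(bam, toyRegions()$five_prime)
    expect_equal(nrow(got), 50L)
    expect_false(any(got$name %in% c("zero_mapq", "dup", "secondary",
                                     "suppl")))
})

test_that("a chromosome absent from the BAM header yields an empty warning", {
    fx <- bpFixture()
    region <- toyRegions()$five_prime
    region$chrom <- "chrZ"
    expect_warning(got <- scanRegion(fx$full, region), "absent")
    expect_equal(nrow(got), 0L)
})

test_that("discordant pairs span the two regions; MAPQ failures drop out", {
    fx <- bpFixture()
    r <- toyRegions()
    pairs <- findDiscordantPairs(fx$full, r$five_prime, r$three_prime)
    ## three planted pairs, one with a low-MAPQ region-5 mate
    expect_equal(nrow(pairs), 2L)
    expect_equal(pairs$name, c("dp1", "dp2"))
    expect_true(all(pairs$chrom_5 == "chr1" & pairs$chrom_3 == "chr2"))
})

test_that("proper pairs between nearby same-chromosome regions give none", {
    fx <- bpFixture()
    reads <- unlist(lapply(1:30, function(i) {
        s <- 14000L + 150L * i
        list(samRecord(paste0("p", i), 99L, "chr1", s, "100M",
                       substring(fx$chr1, s, s + 99L), pnext = s + 200L,
                       tlen = 300L),
             samRecord(paste0("p", i), 147L, "chr1", s + 200L, "100M",
                       substring(fx$chr1, s + 200L, s + 299L), pnext = s,
                       tlen = -300L))
    }), recursive = FALSE)
    bam <- makeTestBam(reads, fx$seqlens)
    r5 <- list(chrom = "chr1", start = 14000L, end = 16000L,
               role = "five_prime", gene = getGene(toyGenes(), "TOYA"),
               junction = 15000L)
    r3 <- list(chrom = "chr1", start = 21000L, end = 23000L,
               role = "three_prime", gene = getGene(toyGenes(), "TOYA"),
               junction = 22000L)
    expect_equal(nrow(findDiscordantPairs(bam, r5, r3)), 0L)
})

test_that("clean split reads call the planted breakpoints exactly", {
    fx <- bpFixture()
    r <- toyRegions()
    pairs <- findDiscordantPairs(fx$full, r$five_prime, r$three_prime)
    bps <- callBreakpoints(fx$full, r$five_prime, r$three_prime, pairs,
                           fx$fasta)
    expect_equal(nrow(bps), 2L)
    b5 <- bps[bps$side == "five_prime", ]
    b3 <- bps[bps$side == "three_prime", ]
    expect_equal(b5$pos, fx$bp5)
    expect_equal(b5$support, 4L)
    expect_equal(b3$pos, fx$bp3)
    expect_equal(b3$support, 4L)
})

test_that("low-quality clips yield no candidates (status stays discordant)", {
    fx <- bpFixture()
    res <- validateFusion(toyCall(), fx$lowq_clips, toyGenes(), fx$fasta)
    expect_equal(res$status, "discordant_supported")
    expect_equal(nrow(res$breakpoints), 0L)
})

test_that("clips that match nowhere near a mate are rejected", {
    fx <- bpFixture()
    res <- validateFusion(toyCall(), fx$rand_clips, toyGenes(), fx$fasta)
    expect_equal(res$status, "discordant_supported")
})

test_that("three-level status follows the available evidence", {
    fx <- bpFixture()
    full <- validateFusion(toyCall(), fx$full, toyGenes(), fx$fasta)
    expect_equal(full$status, "breakpoint_supported")
    expect_equal(full$n_discordant, 2L)
    pairs_only <- validateFusion(toyCall(), fx$pairs_only, toyGenes(),
                                 fx$fasta)
    expect_equal(pairs_only$status, "discordant_supported")
    none <- validateFusion(toyCall(), fx$background_only, toyGenes(),
                           fx$fasta)
    expect_equal(none$status, "unsupported")
    expect_equal(none$n_discordant, 0L)
})

test_that("evidence is monotone in reads and antitone in thresholds", {
    fx <- bpFixture()
    base <- validateFusion(toyCall(), fx$pairs_only, toyGenes(), fx$fasta)
    more <- validateFusion(toyCall(), fx$full, toyGenes(), fx$fasta)
    expect_gte(more$n_discordant, base$n_discordant)

    strict_mapq <- validateFusion(toyCall(), fx$full, toyGenes(), fx$fasta,
                                  validationParams(min_mapq = 70))
    expect_lte(strict_mapq$n_discordant, more$n_discordant)
    expect_equal(strict_mapq$n_discordant, 0L)

    strict_clip <- validateFusion(toyCall(), fx$full, toyGenes(), fx$fasta,
                                  validationParams(min_clip_len = 40))
    expect_equal(strict_clip$status, "discordant_supported")
})
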