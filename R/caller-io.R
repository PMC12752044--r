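## Readers and writers for the two supported fusion-caller TSV dialects.
## Both are normalized into the FusionCallSet representation; the original
## record is kept verbatim in the `raw` column.

.readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                            stringsAsFactors = FALSE, colClasses = "character")
    names(df)[1] <- sub("^#", "", names(df)[1])
    df
}

.requireColumns <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop("format error in ", path, ": missing required column(s) ",
             paste(miss, collapse = ", "))
}

## "chrN:pos" or "chrN:pos:strand" -> list(chrom, pos, strand)
.parseBreakpoint <- function(x, path, line) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L || is.na(suppressWarnings(as.integer(parts[2]))))
        stop("unparsable coordinate '", x, "' at data line ", line,
             " of ", path)
    list(chrom = parts[1], pos = as.integer(parts[2]),
         strand = if (length(parts) >= 3L) parts[3] else NA_character_)
}

.resolveGeneId <- function(symbol, genes) {
    g <- getGene(genes, symbol)
    if (is.null(g)) NA_character_ else mcols(g)$gene_id
}

#' Read an Arriba fusion table
#'
#' Parses the Arriba TSV dialect into a \code{\linkS4class{FusionCallSet}}.
#' Breakpoint columns \code{"chrN:pos"} become junction coordinates; strand
#' columns \code{"X/Y"} are split into the gene strand \code{X} and the
#' transcribed (fusion) strand \code{Y}. The transcription type is
#' \code{sense} when the transcribed strand equals the gene strand,
#' \code{antisense} when it is the opposite strand, and \code{unknown} when
#' the fusion-strand field is \code{"."}.
#'
#' @param path path to an Arriba output TSV.
#' @param genes a \code{GeneModelSet} used to resolve gene ids from symbols.
#' @param cell_line sample identifier recorded on every call.
#' @return a \code{FusionCallSet}
#' @export
readArribaCalls <- function(path, genes, cell_line) {
    df <- .readTsv(path)
    req <- c("gene1", "gene2", "strand1(gene/fusion)", "strand2(gene/fusion)",
             "breakpoint1", "breakpoint2", "site1", "site2", "type",
             "confidence", "reading_frame", "split_reads1", "split_reads2",
             "discordant_mates")
    .requireColumns(df, req, path)
    n <- nrow(df)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        b5 <- .parseBreakpoint(df$breakpoint1[i], path, i)
        b3 <- .parseBreakpoint(df$breakpoint2[i], path, i)
        s5 <- strsplit(df$`strand1(gene/fusion)`[i], "/", fixed = TRUE)[[1]]
        s3 <- strsplit(df$`strand2(gene/fusion)`[i], "/", fixed = TRUE)[[1]]
        if (length(s5) != 2L || length(s3) != 2L)
            stop("unparsable strand field at data line ", i, " of ", path)
        tx5 <- if (s5[2] == ".") "unknown" else
            if (s5[2] == s5[1]) "sense" else "antisense"
        tx3 <- if (s3[2] == ".") "unknown" else
            if (s3[2] == s3[1]) "sense" else "antisense"
        frame <- df$reading_frame[i]
        if (!frame %in% .FRAMES) frame <- "unknown"
        out[[i]] <- data.frame(
            cell_line = cell_line, caller = "arriba",
            gene5 = df$gene1[i], gene3 = df$gene2[i],
            gene_id5 = .resolveGeneId(df$gene1[i], genes),
            gene_id3 = .resolveGeneId(df$gene2[i], genes),
            chrom5 = b5$chrom, pos5 = b5$pos,
            chrom3 = b3$chrom, pos3 = b3$pos,
            gene_strand5 = s5[1], gene_strand3 = s3[1],
            transcribed_strand5 = tx5, transcribed_strand3 = tx3,
            reading_frame = frame, confidence = df$confidence[i],
            event_type = df$type[i],
            split_reads = as.integer(df$split_reads1[i]) +
                as.integer(df$split_reads2[i]),
            spanning_pairs = as.integer(df$discordant_mates[i]),
            site5 = df$site1[i], site3 = df$site2[i],
            raw = paste(unlist(df[i, ]), collapse = "\t"),
            stringsAsFactors = FALSE)
    }
    calls <- if (n) do.call(rbind, out) else .emptyCallFrame()
    FusionCallSet(calls)
}

#' Read a STAR-Fusion abridged fusion table
#'
#' Parses the STAR-Fusion TSV dialect. \code{FusionName} (\code{"A--B"}) is
#' split into the partner symbols; breakpoints \code{"chr:pos:strand"}
#' provide junctions and gene strands. The coding-effect frame column
#' (\code{PROT_FUSION_TYPE}), when present, is mapped \code{INFRAME} to
#' in-frame and \code{FRAMESHIFT} to out-of-frame; everything else is
#' unknown (this caller has no stop-codon class). Confidence is always
#' \code{not-applicable} and transcribed strands are always \code{sense}.
#'
#' @inheritParams readArribaCalls
#' @param path path to a STAR-Fusion (abridged or coding-effect) TSV.
#' @return a \code{FusionCallSet}
#' @export
readStarFusionCalls <- function(path, genes, cell_line) {
    df <- .readTsv(path)
    req <- c("FusionName", "JunctionReadCount", "SpanningFragCount",
             "LeftGene", "LeftBreakpoint", "RightGene", "RightBreakpoint")
    .requireColumns(df, req, path)
    n <- nrow(df)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        pair <- strsplit(df$FusionName[i], "--", fixed = TRUE)[[1]]
        if (length(pair) != 2L)
            stop("unparsable FusionName '", df$FusionName[i],
                 "' at data line ", i, " of ", path)
        b5 <- .parseBreakpoint(df$LeftBreakpoint[i], path, i)
        b3 <- .parseBreakpoint(df$RightBreakpoint[i], path, i)
        frame <- "unknown"
        if ("PROT_FUSION_TYPE" %in% names(df)) {
            frame <- switch(df$PROT_FUSION_TYPE[i],
                            INFRAME = "in-frame",
                            FRAMESHIFT = "out-of-frame",
                            "unknown")
        }
        out[[i]] <- data.frame(
            cell_line = cell_line, caller = "starfusion",
            gene5 = pair[1], gene3 = pair[2],
            gene_id5 = .resolveGeneId(pair[1], genes),
            gene_id3 = .resolveGeneId(pair[2], genes),
            chrom5 = b5$chrom, pos5 = b5$pos,
            chrom3 = b3$chrom, pos3 = b3$pos,
            gene_strand5 = ifelse(is.na(b5$strand), "+", b5$strand),
            gene_strand3 = ifelse(is.na(b3$strand), "+", b3$strand),
            transcribed_strand5 = "sense", transcribed_strand3 = "sense",
            reading_frame = frame, confidence = "not-applicable",
            event_type = if ("SpliceType" %in% names(df))
                df$SpliceType[i] else ".",
            split_reads = as.integer(df$JunctionReadCount[i]),
            spanning_pairs = as.integer(df$SpanningFragCount[i]),
            site5 = ".", site3 = ".",
            raw = paste(unlist(df[i, ]), collapse = "\t"),
            stringsAsFactors = FALSE)
    }
    calls <- if (n) do.call(rbind, out) else .emptyCallFrame()
    FusionCallSet(calls)
}

.emptyCallFrame <- function() {
    cols <- fusionCallColumns()
    df <- as.data.frame(sapply(cols, function(x) character(0),
                               simplify = FALSE))
    for (col in c("pos5", "pos3", "split_reads", "spanning_pairs"))
        df[[col]] <- integer(0)
    df
}

#' Serialize a FusionCallSet back into a caller dialect
#'
#' Writes the Arriba or STAR-Fusion TSV dialect from normalized calls.
#' Round-tripping through the matching reader recovers the same normalized
#' fields (the verbatim \code{raw} column aside).
#'
#' @param x a \code{FusionCallSet} (single caller).
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeArribaTable <- function(x, path) {
    df <- as.data.frame(x)
    stopifnot(all(df$caller == "arriba"))
    fus5 <- ifelse(df$transcribed_strand5 == "unknown", ".",
            ifelse(df$transcribed_strand5 == "sense", df$gene_strand5,
                   ifelse(df$gene_strand5 == "+", "-", "+")))
    fus3 <- ifelse(df$transcribed_strand3 == "unknown", ".",
            ifelse(df$transcribed_strand3 == "sense", df$gene_strand3,
                   ifelse(df$gene_strand3 == "+", "-", "+")))
    out <- data.frame(
        `#gene1` = df$gene5, gene2 = df$gene3,
        `strand1(gene/fusion)` = paste0(df$gene_strand5, "/", fus5),
        `strand2(gene/fusion)` = paste0(df$gene_strand3, "/", fus3),
        breakpoint1 = paste0(df$chrom5, ":", df$pos5),
        breakpoint2 = paste0(df$chrom3, ":", df$pos3),
        site1 = df$site5, site2 = df$site3, type = df$event_type,
        confidence = df$confidence,
        reading_frame = ifelse(df$reading_frame == "unknown", ".",
                               df$reading_frame),
        split_reads1 = df$split_reads, split_reads2 = 0L,
        discordant_mates = df$spanning_pairs,
        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeArribaTable
#' @export
writeStarFusionTable <- function(x, path) {
    df <- as.data.frame(x)
    stopifnot(all(df$caller == "starfusion"))
    frame <- ifelse(df$reading_frame == "in-frame", "INFRAME",
             ifelse(df$reading_frame == "out-of-frame", "FRAMESHIFT", "."))
    out <- data.frame(
        `#FusionName` = paste0(df$gene5, "--", df$gene3),
        JunctionReadCount = df$split_reads,
        SpanningFragCount = df$spanning_pairs,
        SpliceType = df$event_type,
        LeftGene = paste0(df$gene5, "^", ifelse(is.na(df$gene_id5), ".",
                                                df$gene_id5)),
        LeftBreakpoint = paste0(df$chrom5, ":", df$pos5, ":",
                                df$gene_strand5),
        RightGene = paste0(df$gene3, "^", ifelse(is.na(df$gene_id3), ".",
                                                 df$gene_id3)),
        RightBreakpoint = paste0(df$chrom3, ":", df$pos3, ":",
                                 df$gene_strand3),
        PROT_FUSION_TYPE = frame,
        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## unknown frame re-reads as unknown; arriba "." handled in reader
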