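## Annotation layers for validated fusions. All operations are pure: they
## take a per-call table (the DataFrame from validateFusions, or any table
## with the same call columns), add columns, and never modify validation
## evidence.

.dbCategories <- c("none", "unknown_tissue", "no_tissue_match",
                   "related_tissue", "exact_tissue")

#' Assign alternative-splicing candidate identifiers
#'
#' Within each (cell_line, caller, gene5, gene3) group that contains at
#' least two distinct junction pairs, all members receive one shared
#' identifier; other calls get \code{NA}. Duplicated identical junctions
#' alone do not qualify. Identifiers are deterministic under any input
#' ordering (assigned over the sorted group keys).
#'
#' @param df per-call table (data.frame or DataFrame) with columns
#'   \code{cell_line}, \code{caller}, \code{gene5}, \code{gene3},
#'   \code{chrom5}, \code{pos5}, \code{chrom3}, \code{pos3}.
#' @return the table with an \code{alt_splice_id} column added.
#' @export
assignAltSpliceIds <- function(df) {
    df <- as.data.frame(df)
    key <- paste(df$cell_line, df$caller, df$gene5, df$gene3, sep = "\r")
    jxn <- paste(df$chrom5, df$pos5, df$chrom3, df$pos3, sep = "\r")
    qual <- vapply(split(jxn, key), function(j) length(unique(j)) >= 2L,
                   logical(1))
    qkeys <- sort(names(qual)[qual])
    ids <- stats::setNames(sprintf("AS%03d", seq_along(qkeys)), qkeys)
    df$alt_splice_id <- ifelse(key %in% qkeys, ids[key], NA_character_)
    df
}

#' Flag possible promoter-swapping events
#'
#' A fusion is a promoter-swap candidate when, in the transcription order
#' of the 5' partner, the 5' fusion junction strictly precedes the start
#' of the coding region. A non-coding 5' partner (no coding start) is
#' always a candidate, since no coding sequence of the 5' gene can be
#' included.
#'
#' @param df per-call table with \code{gene5}/\code{gene_id5},
#'   \code{pos5} columns.
#' @param genes a \code{GeneModelSet}.
#' @return the table with a logical \code{promoter_swap} column added.
#' @export
flagPromoterSwap <- function(df, genes) {
    df <- as.data.frame(df)
    ps <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
        g <- .resolveOrStop(genes, df$gene_id5[i], df$gene5[i],
                            df[i, , drop = FALSE])
        cs <- mcols(g)$coding_start
        ps[i] <- is.na(cs) ||
            txPrecedes(df$pos5[i], cs, as.character(strand(g)))
    }
    df$promoter_swap <- ps
    df
}

#' Annotate kinase partners
#'
#' Looks up both partner symbols in the kinase table. Partners transcribed
#' antisense to the annotated gene are never annotated.
#' \code{in_frame_kinase} is true when a kinase partner is present and the
#' call is in-frame.
#'
#' @param df per-call table.
#' @param resources an \code{annotation_resources} list.
#' @return the table with \code{kinase5}, \code{kinase3} (kinase group or
#'   \code{NA}) and \code{in_frame_kinase} columns added.
#' @export
annotateKinases <- function(df, resources) {
    df <- as.data.frame(df)
    kt <- resources$kinases
    look <- function(sym) {
        i <- match(sym, kt$symbol)
        ifelse(is.na(i), NA_character_, kt$group[i])
    }
    k5 <- look(df$gene5)
    k3 <- look(df$gene3)
    k5[df$transcribed_strand5 == "antisense"] <- NA_character_
    k3[df$transcribed_strand3 == "antisense"] <- NA_character_
    df$kinase5 <- k5
    df$kinase3 <- k3
    df$in_frame_kinase <- (!is.na(k5) | !is.na(k3)) &
        df$reading_frame == "in-frame"
    df
}

#' Annotate miRNA host-gene partners
#'
#' A partner hosts a miRNA when the hairpin precursor lies inside the gene
#' body or within \code{downstream_window} bp downstream (strand-aware) of
#' the gene's 3' end, and additionally lies within the fused portion of
#' the transcript: between the transcription start and the 5' junction for
#' the 5' partner, and between the 3' junction and the gene's 3' end plus
#' the downstream window for the 3' partner. Hairpin containment is
#' full-interval; hairpin strand is not required to match the host.
#' Antisense-transcribed partners are never annotated.
#'
#' @inheritParams annotateKinases
#' @param genes a \code{GeneModelSet}.
#' @param downstream_window bp downstream of the gene 3' end still
#'   considered hostable (default 2000).
#' @return the table with \code{mirna_host5} and \code{mirna_host3}
#'   columns (comma-separated miRNA names, \code{""} when none).
#' @export
annotateMirnaHosts <- function(df, genes, resources,
                               downstream_window = 2000) {
    df <- as.data.frame(df)
    mi <- resources$mirnas
    hostIn <- function(gene, lo, hi) {
        hit <- mi$chrom == as.character(seqnames(gene)) &
            mi$start >= lo & mi$end <= hi
        paste(mi$name[hit], collapse = ",")
    }
    h5 <- character(nrow(df))
    h3 <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
        if (df$transcribed_strand5[i] != "antisense") {
            g <- .resolveOrStop(genes, df$gene_id5[i], df$gene5[i],
                                df[i, , drop = FALSE])
            ## fused portion of the 5' partner: tx start -> junction
            if (as.character(strand(g)) == "-")
                h5[i] <- hostIn(g, df$pos5[i], end(g))
            else
                h5[i] <- hostIn(g, start(g), df$pos5[i])
        }
        if (df$transcribed_strand3[i] != "antisense") {
            g <- .resolveOrStop(genes, df$gene_id3[i], df$gene3[i],
                                df[i, , drop = FALSE])
            ## fused portion of the 3' partner: junction -> tx end + window
            if (as.character(strand(g)) == "-")
                h3[i] <- hostIn(g, start(g) - downstream_window, df$pos3[i])
            else
                h3[i] <- hostIn(g, df$pos3[i], end(g) + downstream_window)
        }
    }
    df$mirna_host5 <- h5
    df$mirna_host3 <- h3
    df
}

#' Match fusions against known-fusion databases
#'
#' Matching is order-sensitive on the (5', 3') symbol pair, per source.
#' Matches are categorized by tissue: \code{exact_tissue} when a matching
#' entry's tissue maps exactly to the sample tissue,
#' \code{related_tissue} for a related mapping, \code{no_tissue_match}
#' when matching entries carry mapped tissues that do not relate to the
#' sample, and \code{unknown_tissue} when every matching entry's tissue is
#' absent from the tissue map. Pairs with any antisense-transcribed
#' partner are not matched. For the \code{tumorfusions} source,
#' \code{junction_match_tumorfusions} flags entries whose two recorded
#' junction coordinates both equal the call's.
#'
#' @inheritParams annotateKinases
#' @param tissue sample tissue per cell line: a named character vector
#'   (names are cell lines), a single value recycled to all calls, or
#'   \code{NULL} (tissue categories then fall back to
#'   \code{no_tissue_match}/\code{unknown_tissue}).
#' @return the table with \code{mitelman_match},
#'   \code{tumorfusions_match} and \code{junction_match_tumorfusions}
#'   columns added.
#' @export
matchKnownFusionDb <- function(df, resources, tissue = NULL) {
    df <- as.data.frame(df)
    kf <- resources$known_fusions
    tm <- resources$tissue_map
    sampleTissue <- function(cl) {
        if (is.null(tissue)) return(NA_character_)
        if (is.null(names(tissue))) return(tissue[1])
        if (cl %in% names(tissue)) tissue[[cl]] else NA_character_
    }
    category <- function(entries, st) {
        if (nrow(entries) == 0L) return("none")
        mapped <- entries$tissue %in% tm$db_tissue
        rel <- rep(NA_character_, nrow(entries))
        if (!is.na(st)) {
            for (j in seq_len(nrow(entries))) {
                hit <- tm[tm$sample_tissue == st &
                          tm$db_tissue == entries$tissue[j], , drop = FALSE]
                if (nrow(hit)) rel[j] <- hit$relation[1]
            }
        }
        if (any(rel == "exact", na.rm = TRUE)) return("exact_tissue")
        if (any(rel == "related", na.rm = TRUE)) return("related_tissue")
        if (any(mapped)) return("no_tissue_match")
        "unknown_tissue"
    }
    mit <- tf <- character(nrow(df))
    jm <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
        antis <- df$transcribed_strand5[i] == "antisense" ||
            df$transcribed_strand3[i] == "antisense"
        if (antis) { mit[i] <- "none"; tf[i] <- "none"; next }
        st <- sampleTissue(df$cell_line[i])
        hit <- kf[kf$gene5 == df$gene5[i] & kf$gene3 == df$gene3[i], ,
                  drop = FALSE]
        mit[i] <- category(hit[hit$source == "mitelman", , drop = FALSE], st)
        tfe <- hit[hit$source == "tumorfusions", , drop = FALSE]
        tf[i] <- category(tfe, st)
        if (nrow(tfe) && all(c("junction5", "junction3") %in% names(tfe))) {
            j5 <- paste0(df$chrom5[i], ":", df$pos5[i])
            j3 <- paste0(df$chrom3[i], ":", df$pos3[i])
            jm[i] <- any(!is.na(tfe$junction5) & !is.na(tfe$junction3) &
                         tfe$junction5 == j5 & tfe$junction3 == j3)
        }
    }
    df$mitelman_match <- mit
    df$tumorfusions_match <- tf
    df$junction_match_tumorfusions <- jm
    df
}

#' Annotate cancer-gene membership
#'
#' Flags partners present in the cancer-gene list; antisense-transcribed
#' partners are never annotated.
#'
#' @inheritParams annotateKinases
#' @return the table with logical \code{cgc5} and \code{cgc3} columns.
#' @export
annotateCgc <- function(df, resources) {
    df <- as.data.frame(df)
    df$cgc5 <- df$gene5 %in% resources$cancer_genes &
        df$transcribed_strand5 != "antisense"
    df$cgc3 <- df$gene3 %in% resources$cancer_genes &
        df$transcribed_strand3 != "antisense"
    df
}

## canonical serialized annotation tuple; absent (NA) fields compare equal
.twinTuple <- function(df) {
    cols <- intersect(c("reading_frame", "bp5_pos", "bp3_pos",
                        "kinase5", "kinase3", "mirna_host5", "mirna_host3",
                        "promoter_swap", "mitelman_match",
                        "tumorfusions_match", "junction_match_tumorfusions",
                        "cgc5", "cgc3"), names(df))
    apply(df[, cols, drop = FALSE], 1L,
          function(r) paste(ifelse(is.na(r), "<NA>", as.character(r)),
                            collapse = "\r"))
}

#' Assign twin identifiers across callers
#'
#' Two calls are twins when they come from different callers in the same
#' cell line, have identical fusion junctions, and carry identical
#' annotations (reading frame, breakpoint positions when
#' breakpoint-supported, kinase, miRNA host, promoter swap, database
#' matches and cancer-gene fields; absent fields compare equal to
#' absent). Twins share a unique identifier; unmatched calls get
#' \code{NA}. With two callers the twin relation forms disjoint pairs.
#'
#' @param df per-call annotated table containing calls from both callers.
#' @return the table with a \code{twin_id} column added.
#' @export
assignTwinIds <- function(df) {
    df <- as.data.frame(df)
    key <- paste(df$cell_line, df$chrom5, df$pos5, df$chrom3, df$pos3,
                 .twinTuple(df), sep = "\r")
    df$twin_id <- NA_character_
    counter <- 0L
    for (k in sort(unique(key))) {
        rows <- which(key == k)
        ar <- rows[df$caller[rows] == "arriba"]
        sf <- rows[df$caller[rows] == "starfusion"]
        npair <- min(length(ar), length(sf))
        if (npair == 0L) next
        for (p in seq_len(npair)) {
            counter <- counter + 1L
            df$twin_id[c(ar[p], sf[p])] <- sprintf("TW%03d", counter)
        }
    }
    df
}

#' Collapse fusion transcripts into unique gene pairs
#'
#' Groups calls by (cell_line, caller, gene5, gene3) so that each fusion
#' gene pair is counted once per cell line and caller. A boolean
#' annotation is true for the group if it is true for any member; tissue
#' match categories take the strongest category across members; the
#' validation status takes the strongest status.
#'
#' @param df per-call annotated table.
#' @return a data.frame with one row per group: the key columns,
#'   \code{n_transcripts}, \code{n_junctions}, \code{alt_splice},
#'   \code{has_in_frame}, and aggregated annotation columns (those present
#'   in the input among \code{promoter_swap}, \code{kinase5/3} as
#'   logicals, \code{in_frame_kinase}, \code{mirna_host5/3} as logicals,
#'   \code{mitelman_match}, \code{tumorfusions_match},
#'   \code{junction_match_tumorfusions}, \code{cgc5/3}, \code{status}).
#' @export
collapseGenePairs <- function(df) {
    df <- as.data.frame(df)
    if (nrow(df) == 0L)
        return(data.frame(cell_line = character(), caller = character(),
                          gene5 = character(), gene3 = character(),
                          n_transcripts = integer(), n_junctions = integer(),
                          alt_splice = logical(), has_in_frame = logical()))
    key <- paste(df$cell_line, df$caller, df$gene5, df$gene3, sep = "\r")
    groups <- split(seq_len(nrow(df)), key)
    groups <- groups[order(names(groups))]
    rows <- lapply(groups, function(idx) {
        g <- df[idx, , drop = FALSE]
        out <- data.frame(cell_line = g$cell_line[1], caller = g$caller[1],
                          gene5 = g$gene5[1], gene3 = g$gene3[1],
                          n_transcripts = nrow(g),
                          n_junctions = length(unique(paste(g$chrom5, g$pos5,
                                                            g$chrom3,
                                                            g$pos3))),
                          stringsAsFactors = FALSE)
        out$alt_splice <- out$n_junctions >= 2L
        out$has_in_frame <- any(g$reading_frame == "in-frame")
        if ("promoter_swap" %in% names(g))
            out$promoter_swap <- any(g$promoter_swap)
        if ("kinase5" %in% names(g)) {
            out$kinase5 <- any(!is.na(g$kinase5))
            out$kinase3 <- any(!is.na(g$kinase3))
            out$in_frame_kinase <- any(g$in_frame_kinase)
        }
        if ("mirna_host5" %in% names(g)) {
            out$mirna_host5 <- any(nzchar(g$mirna_host5))
            out$mirna_host3 <- any(nzchar(g$mirna_host3))
        }
        if ("mitelman_match" %in% names(g)) {
            out$mitelman_match <- .bestCategory(g$mitelman_match)
            out$tumorfusions_match <- .bestCategory(g$tumorfusions_match)
            out$junction_match_tumorfusions <-
                any(g$junction_match_tumorfusions)
        }
        if ("cgc5" %in% names(g)) {
            out$cgc5 <- any(g$cgc5)
            out$cgc3 <- any(g$cgc3)
        }
        if ("status" %in% names(g))
            out$status <- as.character(max(factor(as.character(g$status),
                                                  levels = .STATUS_LEVELS,
                                                  ordered = TRUE)))
        out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.bestCategory <- function(x) {
    .dbCategories[max(match(x, .dbCategories))]
}

#' Run all annotation layers on validation results
#'
#' Applies alternative-splicing identifiers, promoter-swap flags, kinase,
#' miRNA host, known-fusion database and cancer-gene annotation, then twin
#' identifiers, in one pass.
#'
#' @param results per-call table from \code{\link{validateFusions}} (may
#'   contain calls from both callers).
#' @param genes a \code{GeneModelSet}.
#' @param resources an \code{annotation_resources} list.
#' @param tissue see \code{\link{matchKnownFusionDb}}.
#' @return the fully annotated per-call data.frame.
#' @export
annotateFusions <- function(results, genes, resources, tissue = NULL) {
    df <- as.data.frame(results)
    df <- assignAltSpliceIds(df)
    df <- flagPromoterSwap(df, genes)
    df <- annotateKinases(df, resources)
    df <- annotateMirnaHosts(df, genes, resources)
    df <- matchKnownFusionDb(df, resources, tissue)
    df <- annotateCgc(df, resources)
    assignTwinIds(df)
}

#' Write the annotated fusion table as TSV
#'
#' @param annotated the data.frame from \code{\link{annotateFusions}}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeAnnotatedTsv <- function(annotated, path) {
    df <- as.data.frame(annotated)
    df$raw <- NULL
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
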