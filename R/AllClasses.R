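#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end strand
#' @importFrom IRanges IRanges
NULL

## valid factor levels used across the package
.CALLERS <- c("arriba", "starfusion")
.FRAMES <- c("in-frame", "out-of-frame", "stop-codon", "unknown")
.CONFIDENCES <- c("high", "medium", "low", "not-applicable")
.TX_STRANDS <- c("sense", "antisense", "unknown")
.STATUS_LEVELS <- c("unsupported", "discordant_supported", "breakpoint_supported")

#' GeneModelSet: annotated gene models with exon structure
#'
#' Holds one record per gene: genomic span, strand, biotype, the genomic
#' position of the first coding base in transcription order
#' (\code{coding_start}, \code{NA} for non-coding genes) and the exon
#' structure as a \code{GRangesList} named by gene id. An interval index
#' over the gene spans supports point queries (which genes cover a
#' chromosome/position pair), used to decide whether a fusion junction is
#' intergenic.
#'
#' @slot genes a \code{GRanges}, one range per gene, with metadata columns
#'   \code{gene_id}, \code{symbol}, \code{biotype} and \code{coding_start}.
#' @slot exons a \code{GRangesList} named by \code{gene_id}; exons are
#'   non-overlapping and sorted by genomic coordinate.
#' @export
setClass("GeneModelSet",
    representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModelSet", function(object) {
    g <- object@genes
    msg <- character()
    need <- c("gene_id", "symbol", "biotype", "coding_start")
    if (!all(need %in% colnames(mcols(g))))
        return(paste("genes must carry metadata columns:",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(mcols(g)$gene_id))
        msg <- c(msg, "duplicated gene_id")
    if (!setequal(names(object@exons), mcols(g)$gene_id))
        msg <- c(msg, "exons must be named by the gene_id set")
    for (i in seq_along(g)) {
        gid <- mcols(g)$gene_id[i]
        ex <- object@exons[[gid]]
        if (length(ex) == 0L) { msg <- c(msg, paste0(gid, ": no exons")); next }
        if (any(start(ex) < start(g)[i]) || any(end(ex) > end(g)[i]))
            msg <- c(msg, paste0(gid, ": exon outside gene span"))
        if (is.unsorted(start(ex)) ||
            (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)])))
            msg <- c(msg, paste0(gid, ": exons must be sorted, non-overlapping"))
        cs <- mcols(g)$coding_start[i]
        if (!is.na(cs) && !any(cs >= start(ex) & cs <= end(ex)))
            msg <- c(msg, paste0(gid, ": coding_start not inside an exon"))
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn GeneModelSet number of genes
#' @param x,object a \code{GeneModelSet}
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@genes))

setMethod("show", "GeneModelSet", function(object) {
    cat("GeneModelSet with", length(object), "genes on",
        length(unique(as.character(seqnames(object@genes)))),
        "sequence(s)\n")
    ncod <- sum(!is.na(mcols(object@genes)$coding_start))
    cat(" ", ncod, "coding,", length(object) - ncod, "non-coding\n")
})

#' FusionCallSet: normalized fusion-transcript predictions
#'
#' A common representation for fusion-caller output. Each row is one
#' predicted fusion transcript with its 5' and 3' partner genes, RNA-level
#' junction coordinates (1-based), gene and transcribed strands, reading
#' frame, caller confidence and read support. The original source record is
#' preserved in the \code{raw} column.
#'
#' @slot calls a \code{DataFrame} with the fixed column set documented in
#'   \code{\link{fusionCallColumns}}.
#' @export
setClass("FusionCallSet", representation(calls = "DataFrame"))

#' Column set of a FusionCallSet
#'
#' @return character vector of required column names.
#' @export
fusionCallColumns <- function() {
    c("cell_line", "caller", "gene5", "gene3", "gene_id5", "gene_id3",
      "chrom5", "pos5", "chrom3", "pos3",
      "gene_strand5", "gene_strand3",
      "transcribed_strand5", "transcribed_strand3",
      "reading_frame", "confidence", "event_type",
      "split_reads", "spanning_pairs", "site5", "site3", "raw")
}

setValidity("FusionCallSet", function(object) {
    df <- object@calls
    msg <- character()
    miss <- setdiff(fusionCallColumns(), colnames(df))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (nrow(df) == 0L) return(TRUE)
    if (!all(df$caller %in% .CALLERS)) msg <- c(msg, "invalid caller")
    if (!all(df$pos5 >= 1L) || !all(df$pos3 >= 1L))
        msg <- c(msg, "junction positions must be positive integers")
    if (!all(df$reading_frame %in% .FRAMES)) msg <- c(msg, "invalid reading_frame")
    if (!all(df$confidence %in% .CONFIDENCES)) msg <- c(msg, "invalid confidence")
    if (!all(df$transcribed_strand5 %in% .TX_STRANDS) ||
        !all(df$transcribed_strand3 %in% .TX_STRANDS))
        msg <- c(msg, "invalid transcribed strand")
    sf <- df$caller == "starfusion"
    if (any(sf & df$confidence != "not-applicable"))
        msg <- c(msg, "starfusion calls must have confidence 'not-applicable'")
    if (any(sf & (df$transcribed_strand5 != "sense" |
                  df$transcribed_strand3 != "sense")))
        msg <- c(msg, "starfusion calls must have sense transcribed strands")
    if (any(sf & df$reading_frame == "stop-codon"))
        msg <- c(msg, "reading_frame 'stop-codon' is arriba-only")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn FusionCallSet number of calls
#' @param x,object a \code{FusionCallSet}
#' @export
setMethod("length", "FusionCallSet", function(x) nrow(x@calls))

setMethod("show", "FusionCallSet", function(object) {
    df <- object@calls
    cat("FusionCallSet with", nrow(df), "calls")
    if (nrow(df)) {
        tab <- table(df$caller)
        cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")",
            sep = "")
    }
    cat("\n")
    if (nrow(df))
        cat("  cell lines:", paste(unique(df$cell_line), collapse = ", "), "\n")
})

#' Construct a FusionCallSet from a DataFrame or data.frame
#'
#' @param calls a \code{DataFrame} or \code{data.frame} with the columns of
#'   \code{\link{fusionCallColumns}}.
#' @return a \code{FusionCallSet}
#' @export
FusionCallSet <- function(calls) {
    if (is.data.frame(calls)) calls <- DataFrame(calls)
    new("FusionCallSet", calls = calls)
}

#' Extract the call table
#' @param x a \code{FusionCallSet}
#' @return a \code{DataFrame}, one row per call
#' @export
fusionCalls <- function(x) {
    stopifnot(is(x, "FusionCallSet"))
    x@calls
}

#' Subset a FusionCallSet by row
#' @param x a \code{FusionCallSet}
#' @param i row index
#' @param j,drop,... ignored
#' @export
setMethod("[", "FusionCallSet", function(x, i, j, ..., drop = FALSE) {
    FusionCallSet(x@calls[i, , drop = FALSE])
})

#' @describeIn FusionCallSet coerce to data.frame
#' @param row.names,optional,... passed on
#' @export
setMethod("as.data.frame", "FusionCallSet",
    function(x, row.names = NULL, optional = FALSE, ...)
        as.data.frame(x@calls, row.names = row.names, optional = optional, ...))

#' ValidationParams: tunable thresholds of the WGS validation pipeline
#'
#' @slot junction_flank bp added on the junction side of each search region
#'   (default 500).
#' @slot gene_flank bp added on the gene-end side of each search region
#'   (default 2000).
#' @slot min_mapq minimum mapping quality of reads considered (default 20).
#' @slot max_concordant_insert template spans above this are discordant
#'   (default 1000 bp).
#' @slot min_clip_len minimum soft-clip length considered (default 10 bp).
#' @slot min_clip_mean_qual minimum mean base quality of the clipped bases
#'   (default phred 25).
#' @slot mate_window clip sequences must align within this distance of a
#'   discordant mate on the other side (default 500 bp).
#' @slot max_clip_mismatch_frac maximum mismatch fraction for ungapped clip
#'   matching (default 0.10).
#' @slot min_discordant_pairs minimum discordant pairs to call a fusion
#'   discordant-supported (default 1).
#' @export
setClass("ValidationParams",
    representation(junction_flank = "numeric", gene_flank = "numeric",
                   min_mapq = "numeric", max_concordant_insert = "numeric",
                   min_clip_len = "numeric", min_clip_mean_qual = "numeric",
                   mate_window = "numeric", max_clip_mismatch_frac = "numeric",
                   min_discordant_pairs = "numeric"),
    prototype(junction_flank = 500, gene_flank = 2000, min_mapq = 20,
              max_concordant_insert = 1000, min_clip_len = 10,
              min_clip_mean_qual = 25, mate_window = 500,
              max_clip_mismatch_frac = 0.10, min_discordant_pairs = 1))

setValidity("ValidationParams", function(object) {
    vals <- c(object@junction_flank, object@gene_flank, object@min_mapq,
              object@max_concordant_insert, object@min_clip_len,
              object@min_clip_mean_qual, object@mate_window,
              object@min_discordant_pairs)
    if (any(vals < 0)) return("all parameters must be non-negative")
    f <- object@max_clip_mismatch_frac
    if (f < 0 || f >= 1) return("max_clip_mismatch_frac must be in [0,1)")
    TRUE
})

#' Construct validation parameters
#'
#' @param junction_flank,gene_flank,min_mapq,max_concordant_insert
#'   see \code{\linkS4class{ValidationParams}}.
#' @param min_clip_len,min_clip_mean_qual,mate_window,max_clip_mismatch_frac
#'   see \code{\linkS4class{ValidationParams}}.
#' @param min_discordant_pairs see \code{\linkS4class{ValidationParams}}.
#' @return a \code{ValidationParams} object
#' @examples
#' validationParams(min_mapq = 30)
#' @export
validationParams <- function(junction_flank = 500, gene_flank = 2000,
                             min_mapq = 20, max_concordant_insert = 1000,
                             min_clip_len = 10, min_clip_mean_qual = 25,
                             mate_window = 500, max_clip_mismatch_frac = 0.10,
                             min_discordant_pairs = 1) {
    new("ValidationParams", junction_flank = junction_flank,
        gene_flank = gene_flank, min_mapq = min_mapq,
        max_concordant_insert = max_concordant_insert,
        min_clip_len = min_clip_len, min_clip_mean_qual = min_clip_mean_qual,
        mate_window = mate_window,
        max_clip_mismatch_frac = max_clip_mismatch_frac,
        min_discordant_pairs = min_discordant_pairs)
}

setMethod("show", "ValidationParams", function(object) {
    cat("ValidationParams\n")
    for (s in slotNames(object))
        cat(sprintf("  %-22s %s\n", s, slot(object, s)))
})

#' Convert validation parameters to a named list
#' @param params a \code{ValidationParams}
#' @return named list of parameter values
#' @export
paramsAsList <- function(params) {
    stopifnot(is(params, "ValidationParams"))
    sapply(slotNames(params), function(s) slot(params, s), simplify = FALSE)
}

#' SimSpec: conditions of a synthetic fusion dataset
#'
#' Describes one simulated study: genome size, gene count, number and
#' geometry of planted fusion events, RNA-only false calls, and the
#' sequencing model (depth, read length, insert size distribution and base
#' error rate). All randomness is governed by \code{seed}.
#'
#' @slot n_chroms number of chromosomes.
#' @slot chrom_len chromosome length in bp.
#' @slot n_genes total number of genes (spread evenly over chromosomes).
#' @slot n_true_fusions planted DNA-level fusion events.
#' @slot n_false_calls RNA-only spiked false-positive calls (no DNA event).
#' @slot geometries recycled over events: \code{interchromosomal},
#'   \code{deletion}, \code{inversion}.
#' @slot depth fold coverage of the WGS read set.
#' @slot read_len read length in bp.
#' @slot insert_mean,insert_sd insert size distribution (normal, truncated
#'   below at \code{read_len}).
#' @slot base_error per-base substitution error probability.
#' @slot seed integer random seed.
#' @export
setClass("SimSpec",
    representation(n_chroms = "integer", chrom_len = "integer",
                   n_genes = "integer", n_true_fusions = "integer",
                   n_false_calls = "integer", geometries = "character",
                   depth = "numeric", read_len = "integer",
                   insert_mean = "numeric", insert_sd = "numeric",
                   base_error = "numeric", seed = "integer"),
    prototype(n_chroms = 2L, chrom_len = 60000L, n_genes = 12L,
              n_true_fusions = 3L, n_false_calls = 2L,
              geometries = c("interchromosomal", "deletion", "inversion"),
              depth = 30, read_len = 100L, insert_mean = 350,
              insert_sd = 40, base_error = 0.001, seed = 1L))

setValidity("SimSpec", function(object) {
    pos <- c(object@n_chroms, object@chrom_len, object@n_genes,
             object@depth, object@read_len, object@insert_mean,
             object@insert_sd)
    if (any(pos <= 0)) return("sizes, depth and insert model must be positive")
    if (object@n_true_fusions < 0 || object@n_false_calls < 0)
        return("event counts must be non-negative")
    if (object@insert_mean <= object@read_len)
        return("insert_mean must exceed read_len")
    if (!all(object@geometries %in%
             c("interchromosomal", "deletion", "inversion")))
        return("unknown geometry")
    if (object@base_error < 0 || object@base_error >= 1)
        return("base_error must be in [0,1)")
    TRUE
})

#' Construct a simulation specification
#'
#' Defaults describe the package's reference synthetic study: a 2 x 60 kb
#' genome with 12 multi-exon genes on both strands, three planted fusion
#' events (one interchromosomal, one deletion, one inversion) and two
#' RNA-only false calls, sequenced at 30x with 100 bp reads.
#'
#' @param n_chroms,chrom_len,n_genes,n_true_fusions,n_false_calls,geometries
#'   see \code{\linkS4class{SimSpec}}.
#' @param depth,read_len,insert_mean,insert_sd,base_error,seed
#'   see \code{\linkS4class{SimSpec}}.
#' @return a \code{SimSpec}
#' @examples
#' simSpec(seed = 7)
#' @export
simSpec <- function(n_chroms = 2L, chrom_len = 60000L, n_genes = 12L,
                    n_true_fusions = 3L, n_false_calls = 2L,
                    geometries = c("interchromosomal", "deletion", "inversion"),
                    depth = 30, read_len = 100L, insert_mean = 350,
                    insert_sd = 40, base_error = 0.001, seed = 1L) {
    new("SimSpec", n_chroms = as.integer(n_chroms),
        chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
        n_true_fusions = as.integer(n_true_fusions),
        n_false_calls = as.integer(n_false_calls), geometries = geometries,
        depth = depth, read_len = as.integer(read_len),
        insert_mean = insert_mean, insert_sd = insert_sd,
        base_error = base_error, seed = as.integer(seed))
}

setMethod("show", "SimSpec", function(object) {
    cat("SimSpec:", object@n_chroms, "x", object@chrom_len, "bp genome,",
        object@n_genes, "genes,", object@n_true_fusions, "true fusions,",
        object@n_false_calls, "false calls,", object@depth, "x depth, seed",
        object@seed, "\n")
})

#' Convert a SimSpec to a named list
#' @param spec a \code{SimSpec}
#' @return named list of fields
#' @export
simSpecAsList <- function(spec) {
    stopifnot(is(spec, "SimSpec"))
    sapply(slotNames(spec), function(s) slot(spec, s), simplify = FALSE)
}
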