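## Orchestration of the pipeline stages. These functions are the
## programmatic interface; inst/cli/fuseval.R wraps them in a thin
## command-line entry point.

.writeRunManifest <- function(path, inputs, params_list, seed = NULL) {
    inputs <- inputs[file.exists(unlist(inputs))]
    yaml::write_yaml(list(
        version = as.character(utils::packageVersion("fuseval")),
        seed = seed,
        parameters = params_list,
        input_checksums = as.list(tools::md5sum(unlist(inputs)))), path)
    invisible(path)
}

#' Run the synthetic-data generator stage
#'
#' Thin wrapper over \code{\link{simulateDataset}}: generates a complete
#' synthetic dataset directory (FASTA, GTF, BAM, caller tables, resource
#' fixtures, truth tables and manifest).
#'
#' @param out_dir output directory.
#' @param spec a \code{SimSpec} (default \code{simSpec()}).
#' @param seed overrides the spec's seed when non-NULL.
#' @return the list from \code{\link{simulateDataset}}.
#' @export
runSimulate <- function(out_dir, spec = simSpec(), seed = NULL) {
    if (!is.null(seed)) {
        sl <- simSpecAsList(spec)
        sl$seed <- as.integer(seed)
        spec <- do.call(simSpec, sl)
    }
    simulateDataset(spec, out_dir)
}

#' Run the validation and annotation stages
#'
#' Reads gene models and caller tables, applies the pre-validation
#' filters, validates every kept call against the WGS BAM, annotates the
#' results, collapses gene pairs, and writes the filter report,
#' validation table, annotated table, collapsed-group table, per-caller
#' validation summary and enrichment-test report, plus a run manifest
#' with input checksums and all parameters.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \code{gtf}, \code{bam}, \code{fasta}, \code{arriba} and/or
#'   \code{starfusion}, \code{cell_line}, optional resource paths
#'   (\code{kinases}, \code{mirnas}, \code{known_fusions},
#'   \code{cancer_genes}, \code{tissue_map}), optional \code{tissue},
#'   and \code{out_dir}.
#' @param params a \code{ValidationParams}.
#' @return a list with the output paths and the in-memory \code{results},
#'   \code{annotated}, \code{groups}, \code{summary} and
#'   \code{enrichment} objects.
#' @export
runValidateAnnotate <- function(config, params = validationParams()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    for (f in c("gtf", "bam", "fasta")) {
        if (is.null(config[[f]]))
            stop("config entry '", f, "' is required")
        if (!file.exists(config[[f]]))
            stop("input file for '", f, "' not found: ", config[[f]])
    }
    out_dir <- config$out_dir %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cell_line <- config$cell_line %||% "sample"

    genes <- readGeneModels(config$gtf)
    call_list <- list()
    if (!is.null(config$arriba))
        call_list$arriba <- as.data.frame(
            readArribaCalls(config$arriba, genes, cell_line))
    if (!is.null(config$starfusion))
        call_list$starfusion <- as.data.frame(
            readStarFusionCalls(config$starfusion, genes, cell_line))
    if (length(call_list) == 0L)
        stop("at least one of 'arriba'/'starfusion' is required")
    calls <- FusionCallSet(do.call(rbind, unname(call_list)))

    filt <- filterCalls(calls, genes)
    writeFilterReport(filt, file.path(out_dir, "filter_report.tsv"))

    results <- validateFusions(filt$kept, config$bam, genes, config$fasta,
                               params)
    writeValidationTsv(results, file.path(out_dir, "validation.tsv"),
                       params)

    resources <- readAnnotationResources(
        kinases = config$kinases, mirnas = config$mirnas,
        known_fusions = config$known_fusions,
        cancer_genes = config$cancer_genes, tissue_map = config$tissue_map)
    annotated <- annotateFusions(results, genes, resources,
                                 tissue = config$tissue)
    writeAnnotatedTsv(annotated, file.path(out_dir, "annotated.tsv"))

    groups <- collapseGenePairs(annotated)
    utils::write.table(groups, file.path(out_dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    summary <- validationSummary(results, "caller")
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    enrichment <- enrichmentTests(results)
    .writeEnrichmentReport(enrichment,
                           file.path(out_dir, "enrichment.tsv"))

    inputs <- config[intersect(names(config),
                               c("gtf", "bam", "fasta", "arriba",
                                 "starfusion", "kinases", "mirnas",
                                 "known_fusions", "cancer_genes",
                                 "tissue_map"))]
    .writeRunManifest(file.path(out_dir, "manifest.yaml"), inputs,
                      paramsAsList(params))

    list(out_dir = out_dir, results = results, annotated = annotated,
         groups = groups, summary = summary, enrichment = enrichment)
}

## machine-readable key-value report of every count used in each test
.writeEnrichmentReport <- function(enrichment, path) {
    lines <- character(0)
    for (cl in names(enrichment)) {
        for (kind in names(enrichment[[cl]])) {
            t <- enrichment[[cl]][[kind]]
            tab <- t$table
            for (r in rownames(tab)) for (cc in colnames(tab))
                lines <- c(lines, sprintf("%s.%s.%s.%s\t%d", cl, kind, r,
                                          cc, tab[r, cc]))
            lines <- c(lines, sprintf("%s.%s.odds_ratio\t%g", cl, kind,
                                      t$odds_ratio),
                       sprintf("%s.%s.p\t%g", cl, kind, t$p))
        }
    }
    writeLines(lines, path)
    invisible(path)
}

#' Run the drug-association stage
#'
#' Reads a drug-screen response table and a collapsed-group table and
#' writes the fusion-drug association results.
#'
#' @param config a named list (or YAML path) with \code{responses} (TSV),
#'   \code{groups} (TSV from \code{\link{runValidateAnnotate}} or a
#'   data.frame) and \code{out_dir}.
#' @param min_coverage,min_cell_lines see
#'   \code{\link{runFusionDrugAssociation}}.
#' @return the association data.frame (also written to
#'   \code{association.tsv}).
#' @export
runAssociate <- function(config, min_coverage = 0.8, min_cell_lines = 2) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    responses <- readDrugResponses(config$responses)
    groups <- if (is.data.frame(config$groups)) config$groups else
        utils::read.delim(config$groups, stringsAsFactors = FALSE)
    out_dir <- config$out_dir %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    assoc <- runFusionDrugAssociation(groups, responses, min_coverage,
                                      min_cell_lines)
    utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .writeRunManifest(file.path(out_dir, "association_manifest.yaml"),
                      config[intersect(names(config),
                                       c("responses", "groups"))],
                      list(min_coverage = min_coverage,
                           min_cell_lines = min_cell_lines))
    assoc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
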