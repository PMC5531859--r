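#' Default analysis thresholds
#'
#' The published filtering behaviour: nominal p < 0.05, CLES >= 0.65,
#' amplification at >= 8 copies across the coding sequence, mutation site
#' recurrence >= 3, a minimum panel of 10 cell lines, and at least 3 altered
#' (and 3 wild-type) lines per tested combination.
#'
#' @return Named list of threshold defaults.
#' @export
defaultThresholds <- function() {
    list(p_max = 0.05, cles_min = 0.65, amp_threshold = 8L,
         recurrence_threshold = 3L, min_altered = 3L, min_wildtype = 3L,
         min_cell_lines = 10L)
}

.readConfig <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    th <- utils::modifyList(defaultThresholds(),
                            config[names(config) %in%
                                       names(defaultThresholds())])
    config[names(th)] <- th
    if (is.null(config$normalize)) config$normalize <- "none"
    if (is.null(config$contexts)) config$contexts <- "auto"
    if (is.null(config$adjust)) config$adjust <- "none"
    config
}

#' Run the full dependency-detection pipeline
#'
#' Orchestrates genotype calling, per-screen scanning, multi-score
#' resolution, threshold filtering, cross-dataset flagging and annotation,
#' then writes a results table, per-dependency boxplot CSVs and a run
#' manifest (input checksums, thresholds, package version) sufficient to
#' reproduce the outputs.  Identical configuration and inputs yield
#' identical outputs.
#'
#' @param config path to a YAML configuration file, or an equivalent list.
#'   Recognised keys: \code{screens} (list of \code{path} /
#'   \code{dataset_id} / optional \code{rename_map} entries),
#'   \code{mutations}, \code{copy_number}, \code{drivers} (paths);
#'   optional \code{interactions}, \code{drug_gene}, \code{gene_index}
#'   (paths); thresholds as in [defaultThresholds()]; \code{normalize}
#'   (\code{"none"}, \code{"per_cell_line"}, \code{"per_target"});
#'   \code{contexts}; \code{adjust}; \code{output_dir}.
#' @param outputDir overrides the configured output directory.
#' @return Invisibly, the merged annotated record data.frame.
#' @export
runScan <- function(config, outputDir = NULL) {
    cfg <- .readConfig(config)
    outDir <- outputDir %||% cfg$output_dir %||% "."
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    drivers <- readDriverConfig(cfg$drivers)
    mutations <- readMutationTable(cfg$mutations)
    copyNumber <- readCopyNumberTable(cfg$copy_number)

    screens <- lapply(cfg$screens, function(s)
        parseScreen(s$path, s$dataset_id, renameMap = s$rename_map))
    if (cfg$normalize != "none")
        screens <- lapply(screens, zScoreNormalize, axis = cfg$normalize)
    for (sc in screens) {
        rep <- validateScreen(sc, minCellLines = cfg$min_cell_lines)
        if (!rep$ok)
            stop("screen '", datasetId(sc), "' failed validation: ",
                 paste(rep$issues$message[rep$issues$severity == "error"],
                       collapse = "; "))
    }

    allLines <- unique(unlist(lapply(screens, cellLineNames)))
    alterations <- suppressWarnings(buildAlterationMatrix(
        mutations, copyNumber, drivers, allLines,
        recurrenceThreshold = cfg$recurrence_threshold,
        ampThreshold = cfg$amp_threshold))

    perDataset <- lapply(screens, function(sc) {
        rec <- scanDependencies(sc, alterations, contexts = cfg$contexts,
                                minAltered = cfg$min_altered,
                                minWildtype = cfg$min_wildtype)
        rec <- resolveMultiscore(rec)
        filterCGDs(rec, pMax = cfg$p_max, clesMin = cfg$cles_min)
    })
    records <- flagMultipleHits(perDataset)
    records <- adjustPvalues(records, method = cfg$adjust)

    if (!is.null(cfg$interactions))
        records <- annotateString(records, loadInteractions(cfg$interactions))
    if (!is.null(cfg$drug_gene))
        records <- annotateInhibitors(records, loadInhibitors(cfg$drug_gene))

    writeResults(records, file.path(outDir, "results.tsv"))
    bpDir <- file.path(outDir, "boxplots")
    dir.create(bpDir, showWarnings = FALSE)
    byDs <- stats::setNames(screens, vapply(screens, datasetId,
                                            character(1)))
    for (i in seq_len(nrow(records))) {
        r <- records[i, ]
        bp <- boxplotData(byDs[[r$dataset]], alterations, r$driver_entrez,
                          r$target_entrez, r$suffix, r$context)
        utils::write.csv(bp, file.path(bpDir, sprintf(
            "%s_%s_%d_%s_%d_%s.csv", r$dataset, r$driver_symbol,
            r$driver_entrez, r$target_symbol, r$target_entrez, r$context)),
            row.names = FALSE)
    }

    inputs <- c(vapply(cfg$screens, `[[`, character(1), "path"),
                cfg$mutations, cfg$copy_number, cfg$drivers,
                cfg$interactions, cfg$drug_gene, cfg$gene_index)
    manifest <- list(
        package_version = as.character(utils::packageVersion("depscan")),
        thresholds = cfg[names(defaultThresholds())],
        normalize = cfg$normalize, contexts = cfg$contexts,
        adjust = cfg$adjust,
        inputs = as.list(tools::md5sum(unlist(inputs))),
        n_retained = nrow(records))
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    invisible(records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a complete demonstration workspace
#'
#' Generates two screens over the same panel and planted truth (so the
#' planted pair is a cross-dataset multiple hit), the matching mutation and
#' copy-number tables, a driver configuration, annotation fixtures, and a
#' ready-to-run YAML configuration.  Everything is reproducible from
#' \code{seed}.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param nCellLines,nTargets,nDrivers,nAltered,effectSize,noiseSd passed to
#'   [generateScreen()].
#' @return Invisibly, the path to the written \code{config.yaml}.
#' @export
writeFixtureWorkspace <- function(dir, seed = 1L, nCellLines = 30L,
                                  nTargets = 25L, nDrivers = 2L,
                                  nAltered = 10L, effectSize = -2,
                                  noiseSd = 1) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    g1 <- generateScreen(nCellLines, nTargets, seed = seed,
                         nAltered = nAltered, nDrivers = nDrivers,
                         effectSize = effectSize, noiseSd = noiseSd,
                         datasetId = "synth_screen_1")
    g2 <- generateScreen(nCellLines, nTargets, truth = g1$truth,
                         seed = seed + 1000L,
                         datasetId = "synth_screen_2")
    geno <- generateGenotype(g1$truth)
    tg <- targetInfo(g1$screen)
    genes <- unique(data.frame(
        symbol = c(g1$truth$drivers$gene_symbol, tg$symbol),
        entrez = c(g1$truth$drivers$entrez_id, tg$entrez),
        stringsAsFactors = FALSE))
    ann <- generateAnnotationFixtures(genes, seed)

    p <- function(f) file.path(dir, f)
    writeScreen(g1$screen, p("screen_1.txt"))
    writeScreen(g2$screen, p("screen_2.txt"))
    wt <- function(d, f) utils::write.table(d, p(f), sep = "\t",
                                            quote = FALSE,
                                            row.names = FALSE)
    wt(geno$mutations, "mutations.tsv")
    wt(geno$copyNumber, "copy_number.tsv")
    wt(g1$truth$drivers, "drivers.tsv")
    utils::write.table(ann$interactions, p("interactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    wt(ann$drugGene, "drug_gene.tsv")
    wt(ann$geneIndex, "gene_index.tsv")
    cfg <- c(list(
        screens = list(
            list(path = p("screen_1.txt"), dataset_id = "synth_screen_1"),
            list(path = p("screen_2.txt"), dataset_id = "synth_screen_2")),
        mutations = p("mutations.tsv"),
        copy_number = p("copy_number.tsv"),
        drivers = p("drivers.tsv"),
        interactions = p("interactions.tsv"),
        drug_gene = p("drug_gene.tsv"),
        gene_index = p("gene_index.tsv"),
        output_dir = p("results"),
        seed = seed), defaultThresholds())
    yaml::write_yaml(cfg, p("config.yaml"))
    invisible(p("config.yaml"))
}
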