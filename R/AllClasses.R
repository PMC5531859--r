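#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' ScreenMatrix: a loss-of-function screen as a SummarizedExperiment
#'
#' A \code{ScreenMatrix} stores one loss-of-function screen (siRNA, shRNA or
#' CRISPR) over a panel of tumor cell lines.  Following the Bioconductor
#' convention, rows are gene-targeting reagents ("targets") and columns are
#' cell lines; note that the on-disk submission format is the transpose
#' (rows = cell lines).  The single assay, \code{"score"}, holds quantitative
#' sensitivity scores in whatever units the screen's scoring scheme produces
#' (zGARP, ATARIS phenotype score, robust Z, CS score); increasingly negative
#' scores indicate greater inhibition of cell growth.
#'
#' Row metadata carries the parsed target label: \code{symbol}, \code{entrez}
#' (positive integer) and an optional \code{suffix} distinguishing multiple
#' score solutions for one gene (e.g. distinct ATARIS solutions).  Column
#' metadata carries the harmonized cell line \code{name} (digits and uppercase
#' letters only) and \code{tissue} (primary site, uppercase); column names are
#' the composite \code{NAME_TISSUE}.
#'
#' @seealso [parseScreen()], [writeScreen()], [validateScreen()],
#'   [zScoreNormalize()]
#' @export
setClass("ScreenMatrix", contains = "SummarizedExperiment")

.validScreenMatrix <- function(object) {
    msg <- character()
    if (!"score" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'score' is required")
    rd <- rowData(object)
    need <- c("symbol", "entrez", "suffix")
    if (!all(need %in% colnames(rd))) {
        msg <- c(msg, sprintf("rowData must have columns %s",
                              paste(need, collapse = ", ")))
    } else {
        if (any(is.na(rd$entrez)) || any(rd$entrez < 1))
            msg <- c(msg, "entrez ids must be positive integers")
        if (any(!nzchar(rd$symbol)))
            msg <- c(msg, "target symbols must be non-empty")
        if (any(!is.na(rd$suffix) & !nzchar(rd$suffix)))
            msg <- c(msg, "suffix must be absent (NA) or non-empty")
        key <- paste(rd$entrez, ifelse(is.na(rd$suffix), "", rd$suffix))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (entrez, suffix) target pairs")
    }
    cd <- colData(object)
    if (!all(c("name", "tissue") %in% colnames(cd))) {
        msg <- c(msg, "colData must have columns name, tissue")
    } else if (anyDuplicated(colnames(object))) {
        msg <- c(msg, "duplicate cell line names")
    }
    id <- metadata(object)$datasetId
    if (is.null(id) || !is.character(id) || length(id) != 1L || !nzchar(id))
        msg <- c(msg, "metadata datasetId must be a non-empty string")
    sc <- assay(object, "score")
    if (any(is.infinite(sc)))
        msg <- c(msg, "scores must be finite or missing (NA)")
    if (length(msg)) msg else TRUE
}
setValidity("ScreenMatrix", .validScreenMatrix)

#' Construct a ScreenMatrix
#'
#' @param scores numeric matrix, rows = targets, columns = cell lines.
#' @param targets data.frame (or DataFrame) with columns \code{symbol},
#'   \code{entrez}, \code{suffix} (NA for no suffix), one row per score row.
#' @param cellLines data.frame with columns \code{name} and \code{tissue},
#'   one row per score column.
#' @param datasetId single string naming the screen dataset.
#' @return A [ScreenMatrix-class] object.
#' @examples
#' sm <- ScreenMatrix(matrix(c(-1, 0, 1), 1,
#'                           dimnames = list(NULL, NULL)),
#'                    targets = data.frame(symbol = "KRAS", entrez = 3845L,
#'                                         suffix = NA_character_),
#'                    cellLines = data.frame(name = c("A1", "B2", "C3"),
#'                                           tissue = "LUNG"),
#'                    datasetId = "demo")
#' sm
#' @export
ScreenMatrix <- function(scores, targets, cellLines, datasetId) {
    scores <- as.matrix(scores)
    storage.mode(scores) <- "double"
    targets <- as.data.frame(targets)
    cellLines <- as.data.frame(cellLines)
    targets$entrez <- as.integer(targets$entrez)
    if (is.null(targets$suffix)) targets$suffix <- NA_character_
    targets$suffix <- as.character(targets$suffix)
    rownames(scores) <- targetLabels(targets)
    colnames(scores) <- paste(cellLines$name, cellLines$tissue, sep = "_")
    se <- SummarizedExperiment(
        assays = list(score = scores),
        rowData = DataFrame(targets, row.names = rownames(scores)),
        colData = DataFrame(cellLines, row.names = colnames(scores)),
        metadata = list(datasetId = as.character(datasetId)))
    new("ScreenMatrix", se)
}

#' AlterationMatrix: per-driver, per-cell-line functional alteration calls
#'
#' Boolean matrix of likely-functional alteration calls (rows = driver genes,
#' columns = cell lines) with per-call provenance recording which rule fired
#' (\code{"mutation"}, \code{"amplification"}, \code{"deletion"}; multiple
#' tokens comma-separated).  The \code{anyAlteration} slot records whether the
#' cell line carries \emph{any} recorded mutation event in the gene, including
#' events failing the functional rules; it supports optionally excluding such
#' lines from the wild-type group during scanning.
#'
#' @slot calls logical matrix, drivers x cell lines.
#' @slot provenance character matrix, same shape; "" where calls is FALSE.
#' @slot anyAlteration logical matrix, same shape.
#' @slot drivers data.frame of driver specifications (see [makeDrivers()]).
#' @seealso [buildAlterationMatrix()], [selectTestableDrivers()]
#' @export
setClass("AlterationMatrix", representation(
    calls = "matrix",
    provenance = "matrix",
    anyAlteration = "matrix",
    drivers = "data.frame"))

.validAlterationMatrix <- function(object) {
    msg <- character()
    cl <- object@calls
    pr <- object@provenance
    if (!is.logical(cl)) msg <- c(msg, "calls must be a logical matrix")
    if (!identical(dim(cl), dim(pr)) ||
        !identical(dim(cl), dim(object@anyAlteration)))
        msg <- c(msg, "calls, provenance and anyAlteration shapes differ")
    if (nrow(cl) != nrow(object@drivers))
        msg <- c(msg, "one calls row per driver required")
    if (is.logical(cl) && is.character(pr) && identical(dim(cl), dim(pr))) {
        if (any(cl & !nzchar(pr)))
            msg <- c(msg, "TRUE call without provenance")
        if (any(!cl & nzchar(pr)))
            msg <- c(msg, "provenance recorded for a FALSE call")
    }
    dmsg <- .checkDriverTable(object@drivers)
    msg <- c(msg, dmsg)
    if (length(msg)) msg else TRUE
}
setValidity("AlterationMatrix", .validAlterationMatrix)

#' InteractionTable: filtered functional-interaction edges
#'
#' Undirected functional-interaction edges (e.g. from a STRING-like combined
#' score file) kept only above the medium-confidence cut-off (score > 0.4 on
#' the unit scale) and labelled with a confidence tier.  Lookup is symmetric.
#'
#' @slot edges data.frame with columns id1, id2, score, tier.
#' @slot cutoffs named numeric: \code{high} and \code{highest} tier
#'   boundaries partitioning (0.4, 1].
#' @seealso [loadInteractions()], [annotateString()]
#' @export
setClass("InteractionTable", representation(
    edges = "data.frame", cutoffs = "numeric"))

.validInteractionTable <- function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("id1", "id2", "score", "tier") %in% colnames(e)))
        msg <- c(msg, "edges need columns id1, id2, score, tier")
    else {
        if (any(e$score <= 0.4))
            msg <- c(msg, "stored edges must have score > 0.4")
        if (!all(e$tier %in% c("medium", "high", "highest")))
            msg <- c(msg, "invalid tier label")
        if (any(e$id1 == e$id2))
            msg <- c(msg, "self-edges are not allowed")
    }
    ct <- object@cutoffs
    if (!all(c("high", "highest") %in% names(ct)) ||
        !(0.4 < ct["high"] && ct["high"] < ct["highest"] && ct["highest"] <= 1))
        msg <- c(msg, "cutoffs must satisfy 0.4 < high < highest <= 1")
    if (length(msg)) msg else TRUE
}
setValidity("InteractionTable", .validInteractionTable)

#' InhibitorMap: inhibitor drugs available per target gene
#'
#' Maps gene symbols to the drugs reported to inhibit them, after keeping
#' only interaction category "inhibitor" and dropping excluded sources.
#'
#' @slot table data.frame with columns gene, drug, source.
#' @slot excludedSources character vector of source names that were dropped.
#' @seealso [loadInhibitors()], [annotateInhibitors()]
#' @export
setClass("InhibitorMap", representation(
    table = "data.frame", excludedSources = "character"))

.validInhibitorMap <- function(object) {
    msg <- character()
    if (!all(c("gene", "drug", "source") %in% colnames(object@table)))
        msg <- c(msg, "table needs columns gene, drug, source")
    else if (any(object@table$source %in% object@excludedSources))
        msg <- c(msg, "table retains an excluded source")
    if (length(msg)) msg else TRUE
}
setValidity("InhibitorMap", .validInhibitorMap)
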