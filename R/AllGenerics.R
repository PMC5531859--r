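#' Accessors for screen and alteration objects
#'
#' \code{datasetId} returns the screen's dataset identifier;
#' \code{scoreMatrix} the targets x cell-lines score matrix;
#' \code{targetInfo} the parsed target labels (symbol, entrez, suffix);
#' \code{cellLineInfo} the cell line name/tissue table;
#' \code{cellLineNames} the composite \code{NAME_TISSUE} identifiers;
#' \code{altCalls}, \code{altProvenance}, \code{driverInfo} the calls matrix,
#' provenance matrix and driver table of an [AlterationMatrix-class].
#'
#' @param x a [ScreenMatrix-class] or [AlterationMatrix-class] object.
#' @return The requested component (see Description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("targetInfo", function(x) standardGeneric("targetInfo"))

#' @rdname accessors
#' @export
setGeneric("cellLineInfo", function(x) standardGeneric("cellLineInfo"))

#' @rdname accessors
#' @export
setGeneric("cellLineNames", function(x) standardGeneric("cellLineNames"))

#' @rdname accessors
#' @export
setGeneric("altCalls", function(x) standardGeneric("altCalls"))

#' @rdname accessors
#' @export
setGeneric("altProvenance", function(x) standardGeneric("altProvenance"))

#' @rdname accessors
#' @export
setGeneric("driverInfo", function(x) standardGeneric("driverInfo"))

#' @rdname accessors
#' @export
setMethod("datasetId", "ScreenMatrix", function(x) metadata(x)$datasetId)

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "ScreenMatrix", function(x) assay(x, "score"))

#' @rdname accessors
#' @export
setMethod("targetInfo", "ScreenMatrix",
          function(x) as.data.frame(rowData(x)))

#' @rdname accessors
#' @export
setMethod("cellLineInfo", "ScreenMatrix",
          function(x) as.data.frame(colData(x)))

#' @rdname accessors
#' @export
setMethod("cellLineNames", "ScreenMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("altCalls", "AlterationMatrix", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("altProvenance", "AlterationMatrix", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("driverInfo", "AlterationMatrix", function(x) x@drivers)

#' @rdname accessors
#' @export
setMethod("cellLineNames", "AlterationMatrix",
          function(x) colnames(x@calls))

setMethod("show", "ScreenMatrix", function(object) {
    cat(sprintf("ScreenMatrix '%s': %d targets x %d cell lines\n",
                datasetId(object), nrow(object), ncol(object)))
    tis <- table(colData(object)$tissue)
    cat("tissues:",
        paste(sprintf("%s(%d)", names(tis), tis), collapse = " "), "\n")
    nmiss <- sum(is.na(assay(object, "score")))
    cat(sprintf("missing scores: %d (%.1f%%)\n", nmiss,
                100 * nmiss / max(1, length(assay(object, "score")))))
})

setMethod("show", "AlterationMatrix", function(object) {
    cat(sprintf("AlterationMatrix: %d drivers x %d cell lines, %d calls\n",
                nrow(object@calls), ncol(object@calls), sum(object@calls)))
    alt <- rowSums(object@calls)
    for (i in seq_len(nrow(object@drivers))) {
        d <- object@drivers[i, ]
        cat(sprintf("  %s_%d [%s, %s]: %d altered\n", d$gene_symbol,
                    d$entrez_id, d$gene_class, d$alteration_mode, alt[i]))
    }
})

setMethod("show", "InteractionTable", function(object) {
    cat(sprintf("InteractionTable: %d edges (score > 0.4); tiers: %s\n",
                nrow(object@edges),
                paste(sprintf("%s=%d", names(table(object@edges$tier)),
                              table(object@edges$tier)), collapse = " ")))
})

setMethod("show", "InhibitorMap", function(object) {
    cat(sprintf("InhibitorMap: %d inhibitor relationships across %d genes\n",
                nrow(object@table), length(unique(object@table$gene))))
})
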