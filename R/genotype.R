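.MUT_EFFECTS <- c("missense", "inframe_indel", "nonsense", "frameshift",
                  "splice_site", "other")

.checkDriverTable <- function(drivers) {
    msg <- character()
    need <- c("gene_symbol", "entrez_id", "gene_class", "alteration_mode")
    if (!all(need %in% colnames(drivers)))
        return(sprintf("driver table needs columns %s",
                       paste(need, collapse = ", ")))
    if (!all(drivers$gene_class %in% c("oncogene", "tumor_suppressor")))
        msg <- c(msg, "gene_class must be oncogene or tumor_suppressor")
    if (!all(drivers$alteration_mode %in%
             c("both", "amplification_only", "mutation_only")))
        msg <- c(msg, "invalid alteration_mode")
    bad <- drivers$gene_class == "tumor_suppressor" &
        drivers$alteration_mode != "both"
    if (any(bad))
        msg <- c(msg, sprintf(
            "tumor suppressor %s must use alteration_mode 'both'",
            drivers$gene_symbol[bad][1]))
    if (anyDuplicated(drivers$entrez_id))
        msg <- c(msg, "duplicate driver entrez ids")
    msg
}

#' Build a driver-gene specification table
#'
#' Each driver gene carries a class (oncogene or tumor suppressor) and an
#' alteration mode governing which evidence counts as a likely functional
#' alteration: \code{"both"} combines mutation and copy-number rules;
#' \code{"amplification_only"} and \code{"mutation_only"} restrict oncogenes
#' to a single evidence type (tumor suppressors always use \code{"both"}).
#'
#' @param gene_symbol,entrez_id gene identifiers.
#' @param gene_class \code{"oncogene"} or \code{"tumor_suppressor"}.
#' @param alteration_mode \code{"both"}, \code{"amplification_only"} or
#'   \code{"mutation_only"}.
#' @return data.frame with one row per driver.
#' @export
makeDrivers <- function(gene_symbol, entrez_id, gene_class,
                        alteration_mode = "both") {
    d <- data.frame(gene_symbol = as.character(gene_symbol),
                    entrez_id = as.integer(entrez_id),
                    gene_class = as.character(gene_class),
                    alteration_mode = rep_len(as.character(alteration_mode),
                                              length(gene_symbol)),
                    stringsAsFactors = FALSE)
    msg <- .checkDriverTable(d)
    if (length(msg)) stop(paste(msg, collapse = "; "))
    d
}

#' Default driver configuration
#'
#' The built-in configuration covers only the driver genes whose alteration
#' mode is special-cased: ERBB2, MYC and MYCN are scored on amplification
#' only, and KRAS, BRAF, NRAS and HRAS on recurrent mutations/indels only.
#' All other drivers should be supplied through a user configuration table
#' with mode \code{"both"}.
#'
#' @return A driver table (see [makeDrivers()]).
#' @export
defaultDrivers <- function() {
    makeDrivers(
        gene_symbol = c("ERBB2", "MYC", "MYCN", "KRAS", "BRAF", "NRAS",
                        "HRAS"),
        entrez_id = c(2064L, 4609L, 4613L, 3845L, 673L, 4893L, 3265L),
        gene_class = "oncogene",
        alteration_mode = c(rep("amplification_only", 3),
                            rep("mutation_only", 4)))
}

#' Read a driver configuration file
#' @param file tab-delimited file with columns gene_symbol, entrez_id,
#'   gene_class, alteration_mode (alteration_mode defaults to "both" when the
#'   column is absent).
#' @return A validated driver table.
#' @export
readDriverConfig <- function(file) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (is.null(d$alteration_mode)) d$alteration_mode <- "both"
    makeDrivers(d$gene_symbol, d$entrez_id, d$gene_class, d$alteration_mode)
}

#' Read mutation and copy-number tables
#'
#' Mutation tables are tab-delimited with columns \code{cell_line},
#' \code{gene_symbol}, \code{entrez_id}, \code{effect} (one of missense,
#' inframe_indel, nonsense, frameshift, splice_site, other) and
#' \code{site_recurrence} (prior mutation count at the site in a COSMIC-like
#' catalogue).  Copy-number tables have columns \code{cell_line},
#' \code{gene_symbol}, \code{entrez_id}, \code{min_cn}, \code{max_cn}
#' (minimum/maximum segment copy number over the coding sequence).
#'
#' @param file path to the table.
#' @return data.frame.
#' @export
readMutationTable <- function(file) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("cell_line", "gene_symbol", "entrez_id", "effect",
              "site_recurrence")
    if (!all(need %in% colnames(d)))
        stop("mutation table needs columns ", paste(need, collapse = ", "))
    if (!all(d$effect %in% .MUT_EFFECTS))
        stop("unknown mutation effect class: ",
             d$effect[!d$effect %in% .MUT_EFFECTS][1])
    if (any(d$site_recurrence < 0)) stop("site_recurrence must be >= 0")
    d
}

#' @rdname readMutationTable
#' @export
readCopyNumberTable <- function(file) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("cell_line", "gene_symbol", "entrez_id", "min_cn", "max_cn")
    if (!all(need %in% colnames(d)))
        stop("copy-number table needs columns ", paste(need, collapse = ", "))
    if (any(d$min_cn < 0) || any(d$min_cn > d$max_cn))
        stop("copy numbers must satisfy 0 <= min_cn <= max_cn")
    d
}

#' Classify a mutation as a likely functional alteration
#'
#' Oncogenes: only recurrent missense or in-frame indel events qualify, where
#' recurrence means at least \code{recurrenceThreshold} (default 3) prior
#' mutations of the site in the COSMIC catalogue.  Tumor suppressors: all
#' nonsense, frameshift and splice-site mutations qualify unconditionally,
#' and recurrent missense/in-frame indel events qualify as well.  Effect
#' class \code{"other"} never qualifies.
#'
#' @param effect character vector of effect classes.
#' @param siteRecurrence integer vector of prior site mutation counts.
#' @param geneClass \code{"oncogene"} or \code{"tumor_suppressor"}.
#' @param recurrenceThreshold minimum prior site count (default 3).
#' @return logical vector.
#' @examples
#' classifyMutation("missense", 5, "oncogene")          # TRUE
#' classifyMutation("nonsense", 0, "tumor_suppressor")  # TRUE
#' classifyMutation("nonsense", 0, "oncogene")          # FALSE
#' @export
classifyMutation <- function(effect, siteRecurrence, geneClass,
                             recurrenceThreshold = 3L) {
    bad <- !effect %in% .MUT_EFFECTS
    if (any(bad)) stop("unknown mutation effect class: ", effect[bad][1])
    geneClass <- match.arg(geneClass, c("oncogene", "tumor_suppressor"))
    recurrent <- effect %in% c("missense", "inframe_indel") &
        siteRecurrence >= recurrenceThreshold
    if (geneClass == "oncogene") recurrent
    else recurrent | effect %in% c("nonsense", "frameshift", "splice_site")
}

#' Call an amplification from gene-level copy number
#'
#' An oncogene is considered amplified when the entire coding sequence has at
#' least \code{ampThreshold} copies (default 8), i.e. when the minimum
#' segment copy number over the coding sequence reaches the threshold.
#'
#' @param minCn integer vector of minimum segment copy numbers.
#' @param ampThreshold amplification threshold (default 8).
#' @return logical vector.
#' @export
callAmplification <- function(minCn, ampThreshold = 8L) {
    minCn >= ampThreshold
}

#' Call a deletion from gene-level copy number
#'
#' A tumor suppressor is considered deleted when any part of the coding
#' sequence has copy number zero, i.e. when the minimum segment copy number
#' is 0.
#'
#' @param minCn integer vector of minimum segment copy numbers.
#' @return logical vector.
#' @export
callDeletion <- function(minCn) {
    minCn == 0L
}

#' Build the driver x cell-line functional alteration matrix
#'
#' Combines mutation and copy-number evidence per driver according to its
#' class and alteration mode: oncogenes with mode \code{"both"} are altered
#' on amplification OR qualifying mutation; tumor suppressors on deletion OR
#' qualifying mutation; \code{"amplification_only"} / \code{"mutation_only"}
#' oncogenes use a single branch.  Records for cell lines or genes outside
#' the declared universe are dropped with a warning (tolerating superset
#' genotype files).  Provenance records which branch(es) fired for every
#' TRUE call.
#'
#' @param mutations mutation data.frame (see [readMutationTable()]).
#' @param copyNumber copy-number data.frame (see [readCopyNumberTable()]).
#' @param drivers driver table (see [makeDrivers()]).
#' @param cellLines character vector of cell line identifiers defining the
#'   column universe.
#' @param recurrenceThreshold,ampThreshold rule thresholds (defaults 3 and 8).
#' @return An [AlterationMatrix-class].
#' @export
buildAlterationMatrix <- function(mutations, copyNumber, drivers, cellLines,
                                  recurrenceThreshold = 3L,
                                  ampThreshold = 8L) {
    msg <- .checkDriverTable(drivers)
    if (length(msg)) stop(paste(msg, collapse = "; "))
    cellLines <- as.character(cellLines)
    mutations <- as.data.frame(mutations)
    copyNumber <- as.data.frame(copyNumber)
    bad <- !mutations$effect %in% .MUT_EFFECTS
    if (any(bad)) stop("unknown mutation effect class: ",
                       mutations$effect[bad][1])

    dropOutside <- function(d, what) {
        out <- !(d$cell_line %in% cellLines & d$entrez_id %in%
                     drivers$entrez_id)
        if (any(out))
            warning(sum(out), " ", what,
                    " record(s) for unknown cell lines or genes dropped",
                    call. = FALSE)
        d[!out, , drop = FALSE]
    }
    mutations <- dropOutside(mutations, "mutation")
    copyNumber <- dropOutside(copyNumber, "copy-number")

    nD <- nrow(drivers); nC <- length(cellLines)
    rlab <- paste(drivers$gene_symbol, drivers$entrez_id, sep = "_")
    calls <- matrix(FALSE, nD, nC, dimnames = list(rlab, cellLines))
    prov <- matrix("", nD, nC, dimnames = list(rlab, cellLines))
    anyAlt <- matrix(FALSE, nD, nC, dimnames = list(rlab, cellLines))

    for (i in seq_len(nD)) {
        drv <- drivers[i, ]
        mu <- mutations[mutations$entrez_id == drv$entrez_id, , drop = FALSE]
        cn <- copyNumber[copyNumber$entrez_id == drv$entrez_id, ,
                         drop = FALSE]
        mutHit <- rep(FALSE, nC); names(mutHit) <- cellLines
        if (nrow(mu)) {
            q <- classifyMutation(mu$effect, mu$site_recurrence,
                                  drv$gene_class, recurrenceThreshold)
            hitLines <- unique(mu$cell_line[q])
            mutHit[hitLines] <- TRUE
            anyAlt[i, unique(mu$cell_line)] <- TRUE
        }
        ampHit <- delHit <- rep(FALSE, nC); names(ampHit) <- cellLines
        names(delHit) <- cellLines
        if (nrow(cn)) {
            ampHit[unique(cn$cell_line[callAmplification(cn$min_cn,
                                                         ampThreshold)])] <-
                TRUE
            delHit[unique(cn$cell_line[callDeletion(cn$min_cn)])] <- TRUE
        }
        use <- switch(drv$alteration_mode,
            amplification_only = list(amplification = ampHit),
            mutation_only = list(mutation = mutHit),
            both = if (drv$gene_class == "oncogene")
                list(amplification = ampHit, mutation = mutHit)
            else
                list(deletion = delHit, mutation = mutHit))
        hit <- Reduce(`|`, use)
        calls[i, ] <- hit
        for (j in which(hit)) {
            fired <- sort(names(use)[vapply(use, `[`, logical(1), j)])
            prov[i, j] <- paste(fired, collapse = ",")
        }
        anyAlt[i, ] <- anyAlt[i, ] | calls[i, ]
    }
    new("AlterationMatrix", calls = calls, provenance = prov,
        anyAlteration = anyAlt, drivers = drivers)
}

#' Select drivers testable in a screened panel
#'
#' A driver is testable when it is altered in at least \code{minAltered}
#' (default 3) of the cell lines actually present in the screen.
#'
#' @param alterations an [AlterationMatrix-class].
#' @param screenCellLines character vector of screened cell line names.
#' @param minAltered minimum altered-line count (default 3).
#' @return The subset of the driver table meeting the requirement.
#' @export
selectTestableDrivers <- function(alterations, screenCellLines,
                                  minAltered = 3L) {
    stopifnot(is(alterations, "AlterationMatrix"))
    keep <- intersect(colnames(alterations@calls),
                      as.character(screenCellLines))
    n <- if (length(keep))
        rowSums(alterations@calls[, keep, drop = FALSE]) else
        rep(0L, nrow(alterations@calls))
    alterations@drivers[n >= minAltered, , drop = FALSE]
}
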