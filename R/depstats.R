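# Null distribution of the Mann-Whitney U statistic (no ties), via the
# standard count recursion N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
# Counts fit exactly in doubles for the sample sizes where the exact test is
# used (max C(30, 15) ~ 1.6e8).  Tail probabilities are cached per (m, n).
.uNullCache <- new.env(parent = emptyenv())

.uTailProbs <- function(m, n) {
    key <- paste(m, n, sep = ",")
    hit <- .uNullCache[[key]]
    if (!is.null(hit)) return(hit)
    tab <- vector("list", n + 1L)
    for (nn in 0:n) tab[[nn + 1L]] <- 1  # m' = 0: U always 0
    for (mm in 1:m) {
        prev <- tab
        tab[[1L]] <- 1                   # n' = 0: U always 0
        for (nn in 1:n) {
            a <- c(rep(0, nn), prev[[nn + 1L]])        # shift by n'
            b <- c(tab[[nn]], rep(0, mm * nn + 1L - length(tab[[nn]])))
            len <- mm * nn + 1L
            a <- c(a, rep(0, len - length(a)))
            tab[[nn + 1L]] <- a[seq_len(len)] + b[seq_len(len)]
        }
    }
    counts <- tab[[n + 1L]]
    tails <- rev(cumsum(rev(counts))) / sum(counts)  # P(U >= u), u = 0..mn
    .uNullCache[[key]] <- tails
    tails
}

.uStatistic <- function(altered, wildtype) {
    # pairs where the altered line is MORE sensitive (strictly lower score),
    # ties weighted 1/2; computed from tie-averaged ranks
    n1 <- length(altered); n2 <- length(wildtype)
    r <- rank(c(altered, wildtype))
    # sum of altered ranks - n1(n1+1)/2 counts pairs altered > wildtype
    n1 * n2 - (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2)
}

.checkGroups <- function(altered, wildtype) {
    if (!length(altered) || !length(wildtype))
        stop("both the altered and wild-type groups must be non-empty")
    if (any(!is.finite(altered)) || any(!is.finite(wildtype)))
        stop("scores must be finite")
}

#' Common-language effect size
#'
#' The probability that a randomly chosen altered cell line is more sensitive
#' (has a strictly lower score, under the negative-is-sensitive convention)
#' than a randomly chosen wild-type cell line, with tied pairs counted 1/2.
#' Equivalent to the area under the ROC curve and to U / (n1 * n2).
#'
#' @param altered,wildtype numeric score vectors for the two groups.
#' @return A probability in \[0, 1\].
#' @examples
#' cles(c(-3, -2), c(-1, 0, 1))  # 1: complete separation
#' cles(c(-2, 0), c(-1, 1))      # 0.75
#' @export
cles <- function(altered, wildtype) {
    .checkGroups(altered, wildtype)
    .uStatistic(altered, wildtype) / (length(altered) * length(wildtype))
}

#' One-sided Mann-Whitney U test for increased sensitivity
#'
#' Tests whether the altered group is stochastically smaller (more negative
#' scores, i.e. more sensitive to gene inhibition) than the wild-type group.
#' U counts altered-beats-wildtype pairs with ties weighted 1/2; the p-value
#' is P(U >= u) under the null.  For tie-free samples with
#' \code{n1 + n2 <= exactMax} the p-value is exact, from the enumerated null
#' distribution of U; otherwise a normal approximation with tie correction
#' and continuity correction is used.  When every score in both groups is
#' identical the data are degenerate: p = 1 is returned with a warning.
#'
#' @param altered,wildtype numeric score vectors.
#' @param exactMax largest combined sample size for the exact computation
#'   (default 30).
#' @return list with \code{U}, \code{p} and \code{method} ("exact" or
#'   "normal").
#' @examples
#' mannWhitneyOneSided(c(-3, -2, -1), c(1, 2, 3))  # U = 9, p = 0.05
#' @export
mannWhitneyOneSided <- function(altered, wildtype, exactMax = 30L) {
    .checkGroups(altered, wildtype)
    n1 <- length(altered); n2 <- length(wildtype)
    u <- .uStatistic(altered, wildtype)
    all <- c(altered, wildtype)
    ties <- anyDuplicated(all) > 0L
    if (!ties && n1 + n2 <= exactMax) {
        p <- .uTailProbs(n1, n2)[round(u) + 1L]
        return(list(U = u, p = p, method = "exact"))
    }
    N <- n1 + n2
    tieCounts <- table(all)
    sig2 <- n1 * n2 / 12 * ((N + 1) -
        sum(tieCounts^3 - tieCounts) / (N * (N - 1)))
    if (sig2 <= 0) {
        warning("degenerate data: all scores identical across both groups",
                call. = FALSE)
        return(list(U = u, p = 1, method = "normal"))
    }
    z <- (u - n1 * n2 / 2 - 0.5) / sqrt(sig2)
    p <- min(1, max(stats::pnorm(z, lower.tail = FALSE),
                    .Machine$double.xmin))
    list(U = u, p = p, method = "normal")
}

#' Difference in median sensitivity score
#'
#' \code{median(altered) - median(wildtype)}, in the screen's score units.
#' Negative values indicate the altered group is more sensitive.
#'
#' @param altered,wildtype numeric score vectors.
#' @return A single number.
#' @export
deltaMedian <- function(altered, wildtype) {
    .checkGroups(altered, wildtype)
    stats::median(altered) - stats::median(wildtype)
}

.CONTEXT_PANCAN <- "PANCAN"

.emptyRecords <- function() {
    data.frame(dataset = character(), context = character(),
               driver_symbol = character(), driver_entrez = integer(),
               target_symbol = character(), target_entrez = integer(),
               suffix = character(), n_altered = integer(),
               n_wildtype = integer(), U = numeric(), p = numeric(),
               cles = numeric(), delta_median = numeric(),
               p_method = character(), multiple_hit = logical(),
               string_tier = character(), inhibitors = character(),
               stringsAsFactors = FALSE)
}

#' Scan a screen for driver-associated dependencies
#'
#' For every context (pan-cancer plus each tissue), every driver testable in
#' that context (altered in at least \code{minAltered} of its screened cell
#' lines) and every target column: the context's cell lines with observed
#' scores are split into altered vs wild-type groups, the pair is skipped if
#' either group is below its minimum, and otherwise one dependency record is
#' emitted with U, one-sided p, CLES, and median difference.  Output order is
#' deterministic: context (pan-cancer first, then tissues alphabetically),
#' driver entrez, target entrez, suffix.
#'
#' @param screen a [ScreenMatrix-class].
#' @param alterations an [AlterationMatrix-class].
#' @param contexts contexts to scan: \code{"auto"} (default) scans
#'   \code{"PANCAN"} plus every tissue present in the shared panel, or give
#'   an explicit character vector of contexts.
#' @param minAltered minimum altered-group size (default 3).
#' @param minWildtype minimum wild-type-group size (default 3).
#' @param excludeNonFunctional when TRUE, cell lines carrying only
#'   non-functional alterations in the driver (events failing the functional
#'   rules) are excluded from the wild-type group instead of pooled into it.
#' @return data.frame of dependency records (one per tested combination).
#' @export
scanDependencies <- function(screen, alterations, contexts = "auto",
                             minAltered = 3L, minWildtype = 3L,
                             excludeNonFunctional = FALSE) {
    stopifnot(is(screen, "ScreenMatrix"), is(alterations, "AlterationMatrix"))
    shared <- intersect(cellLineNames(screen), cellLineNames(alterations))
    if (!length(shared))
        stop("screen and alteration matrix share no cell lines")
    tissues <- sort(unique(tissueOf(shared)))
    if (identical(contexts, "auto"))
        contexts <- c(.CONTEXT_PANCAN, tissues)
    else
        contexts <- unique(as.character(contexts))
    ord <- c(intersect(.CONTEXT_PANCAN, contexts),
             sort(setdiff(contexts, .CONTEXT_PANCAN)))
    m <- scoreMatrix(screen)
    tg <- targetInfo(screen)
    tOrd <- order(tg$entrez, ifelse(is.na(tg$suffix), "", tg$suffix))
    calls <- altCalls(alterations)
    anyAlt <- alterations@anyAlteration
    out <- vector("list", 0L)
    for (ctx in ord) {
        ctxLines <- if (ctx == .CONTEXT_PANCAN) shared
                    else shared[tissueOf(shared) == ctx]
        if (!length(ctxLines)) next
        drv <- selectTestableDrivers(alterations, ctxLines, minAltered)
        if (!nrow(drv)) next
        drv <- drv[order(drv$entrez_id), , drop = FALSE]
        for (i in seq_len(nrow(drv))) {
            dRow <- which(driverInfo(alterations)$entrez_id ==
                              drv$entrez_id[i])
            isAlt <- calls[dRow, ctxLines]
            wtPool <- !isAlt
            if (excludeNonFunctional)
                wtPool <- wtPool & !anyAlt[dRow, ctxLines]
            for (t in tOrd) {
                v <- m[t, ctxLines]
                okA <- isAlt & !is.na(v)
                okW <- wtPool & !is.na(v)
                if (sum(okA) < minAltered || sum(okW) < minWildtype) next
                a <- v[okA]; w <- v[okW]
                mw <- mannWhitneyOneSided(a, w)
                out[[length(out) + 1L]] <- data.frame(
                    dataset = datasetId(screen), context = ctx,
                    driver_symbol = drv$gene_symbol[i],
                    driver_entrez = drv$entrez_id[i],
                    target_symbol = tg$symbol[t],
                    target_entrez = tg$entrez[t],
                    suffix = ifelse(is.na(tg$suffix[t]), "", tg$suffix[t]),
                    n_altered = length(a), n_wildtype = length(w),
                    U = mw$U, p = mw$p,
                    cles = mw$U / (length(a) * length(w)),
                    delta_median = deltaMedian(a, w),
                    p_method = mw$method, multiple_hit = FALSE,
                    string_tier = "none", inhibitors = "",
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out)) return(.emptyRecords())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Filter dependencies at the published thresholds
#'
#' Retains records that are nominally significant (\code{p < pMax}, strict)
#' AND have a common-language effect size of at least \code{clesMin}.
#' Defaults are the published cut-offs p < 0.05 and CLES >= 0.65.  Order is
#' preserved and the input is not modified.
#'
#' @param records dependency record data.frame from [scanDependencies()].
#' @param pMax p-value threshold, applied strictly (default 0.05).
#' @param clesMin CLES threshold, applied inclusively (default 0.65).
#' @return The retained subset.
#' @export
filterCGDs <- function(records, pMax = 0.05, clesMin = 0.65) {
    keep <- records$p < pMax & records$cles >= clesMin
    records[keep, , drop = FALSE]
}

#' Resolve multiple score solutions per gene
#'
#' Screens scored with ATARiS may provide several score columns for one gene
#' (distinct suffixes on the same entrez id).  Within each (dataset, context,
#' driver, target entrez) group only the solution with the lowest p-value is
#' kept; ties are broken by higher CLES, then by the lexicographically
#' smallest suffix.
#'
#' @param records dependency record data.frame.
#' @return The de-duplicated records, in the original relative order.
#' @export
resolveMultiscore <- function(records) {
    if (!nrow(records)) return(records)
    key <- paste(records$dataset, records$context, records$driver_entrez,
                 records$target_entrez, sep = "\r")
    keepIdx <- unlist(lapply(split(seq_len(nrow(records)), key), function(ix) {
        sub <- records[ix, ]
        ix[order(sub$p, -sub$cles, sub$suffix)][1L]
    }), use.names = FALSE)
    records[sort(keepIdx), , drop = FALSE]
}

#' Optional multiple-testing adjustment
#'
#' The published resource stores nominal p-values only; Benjamini-Hochberg
#' q-values can be attached as an opt-in extension.  Adjustment is performed
#' within each (dataset, context) family; original p-values are untouched.
#'
#' @param records dependency record data.frame.
#' @param method \code{"none"} (default) or \code{"benjamini_hochberg"}.
#' @return The records, with a \code{q} column when adjustment is requested.
#' @export
adjustPvalues <- function(records,
                          method = c("none", "benjamini_hochberg")) {
    method <- match.arg(method)
    if (method == "none") return(records)
    if (!nrow(records)) { records$q <- numeric(0); return(records) }
    fam <- paste(records$dataset, records$context, sep = "\r")
    records$q <- NA_real_
    for (f in unique(fam)) {
        ix <- fam == f
        records$q[ix] <- stats::p.adjust(records$p[ix], method = "BH")
    }
    records
}

#' Write a results table
#' @param records dependency record data.frame.
#' @param file output path.
#' @return Invisibly, the path written.
#' @export
writeResults <- function(records, file) {
    utils::write.table(records, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Per-dependency boxplot data
#'
#' Exports the underlying data of one dependency as a (cell_line, tissue,
#' group, score) table, mirroring the downloadable per-boxplot CSV of the
#' published resource.
#'
#' @param screen a [ScreenMatrix-class].
#' @param alterations an [AlterationMatrix-class].
#' @param driverEntrez,targetEntrez entrez ids selecting the pair.
#' @param suffix optional target suffix ("" for none).
#' @param context \code{"PANCAN"} or a tissue token.
#' @return data.frame with one row per cell line with an observed score.
#' @export
boxplotData <- function(screen, alterations, driverEntrez, targetEntrez,
                        suffix = "", context = "PANCAN") {
    shared <- intersect(cellLineNames(screen), cellLineNames(alterations))
    lines <- if (context == .CONTEXT_PANCAN) shared
             else shared[tissueOf(shared) == context]
    tg <- targetInfo(screen)
    t <- which(tg$entrez == targetEntrez &
                   ifelse(is.na(tg$suffix), "", tg$suffix) == suffix)
    if (length(t) != 1L) stop("target not found (entrez ", targetEntrez,
                              ", suffix '", suffix, "')")
    dRow <- which(driverInfo(alterations)$entrez_id == driverEntrez)
    if (length(dRow) != 1L) stop("driver entrez ", driverEntrez,
                                 " not in alteration matrix")
    v <- scoreMatrix(screen)[t, lines]
    keep <- !is.na(v)
    data.frame(cell_line = lines[keep], tissue = tissueOf(lines[keep]),
               group = ifelse(altCalls(alterations)[dRow, lines[keep]],
                              "altered", "wildtype"),
               score = unname(v[keep]), stringsAsFactors = FALSE)
}
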