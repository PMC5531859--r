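#' Parse a gene-target column label
#'
#' Screen columns are labelled \code{SYMBOL_ENTREZID} (e.g. \code{KRAS_3846})
#' with an optional trailing numeric suffix distinguishing multiple score
#' solutions for one gene (e.g. \code{KRAS_3846_1}, \code{KRAS_3846_2}).  The
#' last underscore-separated segment is taken as the suffix only when the
#' second-to-last segment parses as an entrez id; a label whose trailing
#' segments cannot be resolved this way is rejected rather than guessed at.
#'
#' @param labels character vector of column labels.
#' @return data.frame with columns \code{symbol}, \code{entrez} (integer),
#'   \code{suffix} (character, NA when absent).
#' @examples
#' parseTargetLabel(c("KRAS_3846", "KRAS_3846_1"))
#' @export
parseTargetLabel <- function(labels) {
    labels <- as.character(labels)
    out <- data.frame(symbol = character(length(labels)),
                      entrez = integer(length(labels)),
                      suffix = NA_character_,
                      stringsAsFactors = FALSE)
    isInt <- function(s) grepl("^[0-9]+$", s)
    for (i in seq_along(labels)) {
        parts <- strsplit(labels[i], "_", fixed = TRUE)[[1]]
        n <- length(parts)
        if (n < 2L)
            stop("target label '", labels[i],
                 "' lacks an entrez id segment (expected SYMBOL_ENTREZID)")
        if (n >= 3L && isInt(parts[n]) && isInt(parts[n - 1L])) {
            ent <- parts[n - 1L]; suf <- parts[n]; symEnd <- n - 2L
        } else if (isInt(parts[n])) {
            ent <- parts[n]; suf <- NA_character_; symEnd <- n - 1L
        } else {
            stop("target label '", labels[i],
                 "' lacks a numeric entrez id segment")
        }
        entrez <- suppressWarnings(as.integer(ent))
        if (is.na(entrez) || entrez < 1L)
            stop("target label '", labels[i],
                 "': entrez id must be a positive integer")
        symbol <- paste(parts[seq_len(symEnd)], collapse = "_")
        if (!nzchar(symbol))
            stop("target label '", labels[i], "' has an empty gene symbol")
        out$symbol[i] <- symbol
        out$entrez[i] <- entrez
        out$suffix[i] <- suf
    }
    out
}

#' Reconstruct column labels from a parsed target table
#' @param targets data.frame with symbol, entrez, suffix columns.
#' @return character vector of \code{SYMBOL_ENTREZ[_SUFFIX]} labels.
#' @export
targetLabels <- function(targets) {
    lab <- paste(targets$symbol, targets$entrez, sep = "_")
    has <- !is.na(targets$suffix)
    lab[has] <- paste(lab[has], targets$suffix[has], sep = "_")
    lab
}

#' Harmonize a cell line name to the CCLE convention
#'
#' Cell line identifiers are standardized to \code{NAME_TISSUE}: the name part
#' keeps only digits and uppercase letters (punctuation and whitespace
#' stripped, letters uppercased) and the tissue/primary-site part is
#' uppercased, with runs of non-alphanumeric characters collapsed to single
#' underscores.  The operation is idempotent.
#'
#' @param raw character vector of raw cell line names (no tissue part).
#' @param tissue character vector of tissue/primary-site labels.
#' @return data.frame with columns \code{name}, \code{tissue}, \code{full}.
#' @examples
#' harmonizeCellLineName("MDA-MB-231", "BREAST")$full   # "MDAMB231_BREAST"
#' @export
harmonizeCellLineName <- function(raw, tissue) {
    raw <- as.character(raw); tissue <- as.character(tissue)
    if (any(!nzchar(raw)) || any(!nzchar(tissue)))
        stop("cell line name and tissue must be non-empty")
    name <- toupper(gsub("[^A-Za-z0-9]+", "", raw))
    if (any(!nzchar(name)))
        stop("cell line name '", raw[!nzchar(name)][1],
             "' is empty after removing punctuation")
    tis <- toupper(tissue)
    tis <- gsub("[^A-Z0-9]+", "_", tis)
    tis <- gsub("^_+|_+$", "", tis)
    if (any(!nzchar(tis)))
        stop("tissue label reduces to an empty string")
    data.frame(name = name, tissue = tis,
               full = paste(name, tis, sep = "_"),
               stringsAsFactors = FALSE)
}

#' Extract the tissue token from a full cell line name
#'
#' Splits at the FIRST underscore: harmonized names contain no underscore in
#' the name part, while tissue tokens may contain several (e.g.
#' \code{HAEMATOPOIETIC_AND_LYMPHOID_TISSUE}).
#'
#' @param fullName character vector of \code{NAME_TISSUE} identifiers.
#' @return character vector of tissue tokens.
#' @examples
#' tissueOf("NCIH1299_LUNG")
#' @export
tissueOf <- function(fullName) {
    fullName <- as.character(fullName)
    bad <- !grepl("_", fullName, fixed = TRUE)
    if (any(bad))
        stop("cell line name '", fullName[bad][1],
             "' has no underscore; expected NAME_TISSUE")
    sub("^[^_]*_", "", fullName)
}

.nameOf <- function(fullName) sub("_.*$", "", as.character(fullName))

#' Read a loss-of-function screen from the tab-delimited submission format
#'
#' The format is a UTF-8 tab-delimited table: row 1 is a header whose first
#' field is \code{cell_line} (or empty) followed by target labels
#' (\code{SYMBOL_ENTREZID} with optional suffix); each following row is a cell
#' line identifier then its sensitivity scores.  Blank cells, \code{NA} and
#' \code{NaN} are read as missing.  Cell line identifiers are CCLE-style
#' \code{NAME_TISSUE} tokens, or arbitrary identifiers (e.g. COSMIC ids)
#' resolvable through \code{renameMap}; the rename map is applied before
#' harmonization, mirroring manual renames such as
#' \code{H1299_LUNG -> NCIH1299_LUNG}.
#'
#' @param file path or connection to the screen file.
#' @param datasetId single string naming the dataset.
#' @param renameMap optional two-column table (\code{raw_name},
#'   \code{harmonized_full_name}) or path to a tab-delimited file of the same.
#' @return A [ScreenMatrix-class].
#' @export
parseScreen <- function(file, datasetId, renameMap = NULL) {
    lines <- readLines(file, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) < 1L) stop("empty screen file")
    # sentinel keeps trailing empty (missing-score) fields alive
    rows <- lapply(strsplit(paste0(lines, "\tEOL"), "\t", fixed = TRUE),
                   function(f) f[-length(f)])
    header <- rows[[1L]]
    if (length(header) >= 1L &&
        (tolower(header[1L]) %in% c("cell_line", "cell.line", "cellline", "")))
        header <- header[-1L]
    else
        stop("header must start with 'cell_line' or an empty field")
    targets <- parseTargetLabel(header)
    key <- paste(targets$entrez, ifelse(is.na(targets$suffix), "",
                                        targets$suffix))
    if (anyDuplicated(key)) {
        dup <- header[duplicated(key)][1]
        stop("duplicate target column (same entrez id and suffix): '",
             dup, "'")
    }
    if (!is.null(renameMap)) {
        if (is.character(renameMap) && length(renameMap) == 1L)
            renameMap <- utils::read.delim(renameMap, header = FALSE,
                                           colClasses = "character")
        renameMap <- as.data.frame(renameMap)
        rmap <- stats::setNames(as.character(renameMap[[2L]]),
                                as.character(renameMap[[1L]]))
    } else rmap <- character()

    body <- rows[-1L]
    nT <- nrow(targets)
    scores <- matrix(NA_real_, nrow = length(body), ncol = nT)
    rawNames <- character(length(body))
    for (r in seq_along(body)) {
        f <- body[[r]]
        if (length(f) != nT + 1L)
            stop(sprintf("row %d has %d fields; expected %d",
                         r + 1L, length(f), nT + 1L))
        rawNames[r] <- f[1L]
        vals <- f[-1L]
        miss <- vals %in% c("", "NA", "NaN")
        num <- suppressWarnings(as.numeric(vals))
        bad <- which(!miss & is.na(num))
        if (length(bad))
            stop(sprintf("non-numeric score '%s' at row %d, column '%s'",
                         vals[bad[1L]], r + 1L, header[bad[1L]]))
        num[miss] <- NA_real_
        scores[r, ] <- num
    }
    mapped <- ifelse(rawNames %in% names(rmap), rmap[rawNames], rawNames)
    if (any(!grepl("_", mapped, fixed = TRUE)))
        stop("cell line identifier '",
             mapped[!grepl("_", mapped, fixed = TRUE)][1],
             "' has no tissue part; supply a rename map entry for it")
    cl <- harmonizeCellLineName(.nameOf(mapped), tissueOf(mapped))
    if (anyDuplicated(cl$full))
        stop("duplicate cell line row: '", cl$full[duplicated(cl$full)][1],
             "'")
    ScreenMatrix(t(scores), targets,
                 cl[, c("name", "tissue")], datasetId)
}

#' Write a screen in the tab-delimited submission format
#'
#' Inverse of [parseScreen()]: emits the cell-lines-in-rows layout.  Scores
#' are printed with \code{\%.17g} so that reading the file back reproduces the
#' doubles exactly; missing values are written as empty cells.
#'
#' @param screen a [ScreenMatrix-class].
#' @param file path or connection to write to.
#' @return Invisibly, the path written.
#' @export
writeScreen <- function(screen, file) {
    stopifnot(is(screen, "ScreenMatrix"))
    m <- t(scoreMatrix(screen))
    fmt <- ifelse(is.na(m), "", sprintf("%.17g", m))
    dim(fmt) <- dim(m)
    header <- paste(c("cell_line", rownames(scoreMatrix(screen))),
                    collapse = "\t")
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(colnames(scoreMatrix(screen))[i], fmt[i, ]), collapse = "\t"),
        character(1))
    writeLines(c(header, body), file)
    invisible(file)
}

#' Validate a parsed screen
#'
#' Checks the panel-size requirement (screens must cover a minimum number of
#' cell lines; the published threshold is ten) and reports data-quality
#' warnings: columns that are entirely missing, columns with constant scores,
#' and cell line names that do not follow the harmonized convention.
#' Warnings do not block; \code{ok} is \code{TRUE} iff no error-level issue
#' was found.
#'
#' @param screen a [ScreenMatrix-class].
#' @param minCellLines minimum panel size (default 10).
#' @return A \code{ValidationReport}: list with \code{ok} and an
#'   \code{issues} data.frame (severity, code, message).
#' @export
validateScreen <- function(screen, minCellLines = 10L) {
    stopifnot(is(screen, "ScreenMatrix"))
    issues <- data.frame(severity = character(), code = character(),
                         message = character(), stringsAsFactors = FALSE)
    add <- function(sev, code, msg)
        rbind(issues, data.frame(severity = sev, code = code, message = msg,
                                 stringsAsFactors = FALSE))
    if (ncol(screen) < minCellLines)
        issues <- add("error", "panel_size",
                      sprintf("screen has %d cell lines; minimum is %d",
                              ncol(screen), minCellLines))
    m <- scoreMatrix(screen)
    allMiss <- rownames(m)[rowSums(!is.na(m)) == 0L]
    for (t in allMiss)
        issues <- add("warning", "all_missing",
                      sprintf("target '%s' has no scores", t))
    const <- rownames(m)[apply(m, 1L, function(v) {
        v <- v[!is.na(v)]
        length(v) >= 2L && stats::sd(v) == 0
    })]
    for (t in const)
        issues <- add("warning", "constant_scores",
                      sprintf("target '%s' has constant scores", t))
    cd <- cellLineInfo(screen)
    bad <- !grepl("^[0-9A-Z]+$", cd$name) |
        colnames(screen) != paste(cd$name, cd$tissue, sep = "_")
    for (n in colnames(screen)[bad])
        issues <- add("warning", "non_harmonized",
                      sprintf("cell line '%s' is not harmonized", n))
    structure(list(ok = !any(issues$severity == "error"), issues = issues),
              class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
    cat(sprintf("ValidationReport: %s (%d issue%s)\n",
                if (x$ok) "OK" else "FAILED", nrow(x$issues),
                if (nrow(x$issues) == 1L) "" else "s"))
    for (i in seq_len(nrow(x$issues)))
        cat(sprintf("  [%s] %s: %s\n", x$issues$severity[i],
                    x$issues$code[i], x$issues$message[i]))
    invisible(x)
}

#' Z-score normalize a screen
#'
#' Standardizes score vectors to mean 0 and sample standard deviation 1
#' (n - 1 denominator), as applied to zGARP scores to make them comparable
#' across cell lines.  The axis is configurable: \code{"per_cell_line"}
#' (default) standardizes each cell line's score vector across targets;
#' \code{"per_target"} standardizes each target across cell lines.  Missing
#' entries are preserved.
#'
#' @param screen a [ScreenMatrix-class].
#' @param axis \code{"per_cell_line"} or \code{"per_target"}.
#' @return A [ScreenMatrix-class] of the same shape.
#' @export
zScoreNormalize <- function(screen, axis = c("per_cell_line", "per_target")) {
    stopifnot(is(screen, "ScreenMatrix"))
    axis <- match.arg(axis)
    m <- scoreMatrix(screen)
    zfun <- function(v, label) {
        obs <- v[!is.na(v)]
        if (length(obs) < 2L)
            stop("cannot z-normalize '", label,
                 "': fewer than 2 observed scores")
        s <- stats::sd(obs)
        if (s == 0)
            stop("cannot z-normalize '", label, "': zero variance")
        (v - mean(obs)) / s
    }
    if (axis == "per_cell_line") {
        for (j in seq_len(ncol(m))) m[, j] <- zfun(m[, j], colnames(m)[j])
    } else {
        for (i in seq_len(nrow(m))) m[i, ] <- zfun(m[i, ], rownames(m)[i])
    }
    out <- screen
    SummarizedExperiment::assay(out, "score") <- m
    out
}
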