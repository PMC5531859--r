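.edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Load functional interactions from an edge list
#'
#' Reads a STRING-like whitespace- or tab-delimited edge list
#' (\code{id1 id2 combined_score}).  Scores on the milli scale (0-999
#' integers, the convention of distributed STRING files) are detected when
#' any score exceeds 1 and converted to the unit scale by dividing by 1000;
#' declaring \code{scoreScale = "milli"} when every score is already <= 1 is
#' treated as an error rather than silently double-scaled.  Only edges with
#' unit-scale score strictly above 0.4 (medium confidence) are stored;
#' self-edges are dropped.  Retained edges are tiered: medium
#' (0.4, highCut], high (highCut, highestCut], highest above highestCut;
#' the default cut-offs 0.7 and 0.9 follow the conventional STRING
#' confidence levels and are configurable.
#'
#' @param file path to the edge list.
#' @param scoreScale \code{"auto"} (default), \code{"unit"} or
#'   \code{"milli"}.
#' @param highCut,highestCut tier boundaries (defaults 0.7 and 0.9).
#' @param mapping optional two-column data.frame (or path) mapping the file's
#'   identifiers (e.g. Ensembl protein ids) to gene identifiers; applied
#'   before self-edge removal.
#' @return An [InteractionTable-class].
#' @export
loadInteractions <- function(file, scoreScale = c("auto", "unit", "milli"),
                             highCut = 0.7, highestCut = 0.9,
                             mapping = NULL) {
    scoreScale <- match.arg(scoreScale)
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(#|protein1|id1)", lines)]
    parts <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(parts)
    if (any(nf != 3L))
        stop("malformed interaction row at line ", which(nf != 3L)[1],
             ": expected 'id1 id2 combined_score'")
    id1 <- vapply(parts, `[`, character(1), 1L)
    id2 <- vapply(parts, `[`, character(1), 2L)
    score <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1),
                                                3L)))
    if (any(is.na(score)))
        stop("malformed interaction row at line ", which(is.na(score))[1],
             ": non-numeric score")
    if (scoreScale == "auto")
        scoreScale <- if (any(score > 1)) "milli" else "unit"
    if (scoreScale == "milli") {
        if (all(score <= 1))
            stop("scores all <= 1 but scale declared 'milli'; ",
                 "ambiguous scale")
        score <- score / 1000
    }
    if (any(score < 0 | score > 1))
        stop("combined scores must lie in [0, 1] after scaling")
    if (!is.null(mapping)) {
        if (is.character(mapping) && length(mapping) == 1L)
            mapping <- utils::read.delim(mapping, header = FALSE,
                                         colClasses = "character")
        mapping <- as.data.frame(mapping)
        mp <- stats::setNames(as.character(mapping[[2L]]),
                              as.character(mapping[[1L]]))
        id1 <- ifelse(id1 %in% names(mp), mp[id1], id1)
        id2 <- ifelse(id2 %in% names(mp), mp[id2], id2)
    }
    keep <- score > 0.4 & id1 != id2
    e <- data.frame(id1 = id1[keep], id2 = id2[keep], score = score[keep],
                    stringsAsFactors = FALSE)
    # one edge per unordered pair; keep the highest-confidence record
    k <- .edgeKey(e$id1, e$id2)
    e <- e[order(k, -e$score), ]
    e <- e[!duplicated(.edgeKey(e$id1, e$id2)), , drop = FALSE]
    e$tier <- ifelse(e$score > highestCut, "highest",
                     ifelse(e$score > highCut, "high", "medium"))
    rownames(e) <- NULL
    new("InteractionTable", edges = e,
        cutoffs = c(high = highCut, highest = highestCut))
}

#' Look up the interaction tier of gene pairs
#'
#' Symmetric lookup: \code{interactionTier(x, a, b)} equals
#' \code{interactionTier(x, b, a)}.  Pairs without a stored edge (including
#' all self-pairs) return \code{"none"}.
#'
#' @param interactions an [InteractionTable-class].
#' @param a,b character vectors of gene identifiers (recycled).
#' @return character vector of tiers.
#' @export
interactionTier <- function(interactions, a, b) {
    stopifnot(is(interactions, "InteractionTable"))
    e <- interactions@edges
    tiers <- stats::setNames(e$tier, .edgeKey(e$id1, e$id2))
    res <- tiers[.edgeKey(as.character(a), as.character(b))]
    res[is.na(res)] <- "none"
    unname(res)
}

#' Annotate dependency records with functional-interaction tiers
#'
#' Sets each record's \code{string_tier} to the confidence tier of the
#' driver-target edge, or \code{"none"} when no edge is stored.  Lookup
#' tries gene symbols first, then entrez ids (as character), so the loader's
#' identifier space can be either.  Records are otherwise unchanged.
#'
#' @param records dependency record data.frame.
#' @param interactions an [InteractionTable-class].
#' @return The annotated records.
#' @export
annotateString <- function(records, interactions) {
    if (!nrow(records)) return(records)
    bySym <- interactionTier(interactions, records$driver_symbol,
                             records$target_symbol)
    byEnt <- interactionTier(interactions,
                             as.character(records$driver_entrez),
                             as.character(records$target_entrez))
    records$string_tier <- ifelse(bySym != "none", bySym, byEnt)
    records
}

#' Load inhibitor relationships from a drug-gene interaction table
#'
#' Reads a DGIdb-like tab-delimited table (\code{gene}, \code{drug},
#' \code{interaction_category}, \code{source}).  Only rows whose category is
#' \code{inhibitor} are kept, and rows from the excluded sources (by default
#' MyCancerGenome and MyCancerGenomeClinicalTrial, which report
#' mutation-efficacy rather than direct inhibition relationships) are
#' dropped.  Drug names are de-duplicated per gene case-insensitively,
#' keeping the first spelling seen.
#'
#' @param file path to the table (a header row is detected and skipped).
#' @param excludedSources sources to drop.
#' @return An [InhibitorMap-class].
#' @export
loadInhibitors <- function(file,
                           excludedSources = c("MyCancerGenome",
                                               "MyCancerGenomeClinicalTrial")) {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && grepl("^gene\t", lines[1L], ignore.case = TRUE))
        lines <- lines[-1L]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 4L))
        stop("malformed drug-gene row at line ", which(nf != 4L)[1],
             ": expected 'gene<TAB>drug<TAB>interaction_category<TAB>source'")
    d <- data.frame(gene = vapply(parts, `[`, character(1), 1L),
                    drug = vapply(parts, `[`, character(1), 2L),
                    category = vapply(parts, `[`, character(1), 3L),
                    source = vapply(parts, `[`, character(1), 4L),
                    stringsAsFactors = FALSE)
    d <- d[tolower(d$category) == "inhibitor" &
               !d$source %in% excludedSources, , drop = FALSE]
    d <- d[!duplicated(paste(d$gene, tolower(d$drug), sep = "\r")), ,
           drop = FALSE]
    rownames(d) <- NULL
    new("InhibitorMap", table = d[, c("gene", "drug", "source")],
        excludedSources = as.character(excludedSources))
}

#' Drugs inhibiting a gene
#' @param map an [InhibitorMap-class].
#' @param gene gene symbol.
#' @return character vector of drug names (possibly empty).
#' @export
inhibitorsOf <- function(map, gene) {
    stopifnot(is(map, "InhibitorMap"))
    map@table$drug[map@table$gene == gene]
}

#' Annotate dependency records with available inhibitors
#'
#' Fills the \code{inhibitors} column with a comma-separated list of drugs
#' known to inhibit the target gene.
#'
#' @param records dependency record data.frame.
#' @param map an [InhibitorMap-class].
#' @return The annotated records.
#' @export
annotateInhibitors <- function(records, map) {
    if (!nrow(records)) return(records)
    records$inhibitors <- vapply(records$target_symbol, function(g)
        paste(inhibitorsOf(map, g), collapse = ","), character(1),
        USE.NAMES = FALSE)
    records
}

#' Flag dependencies observed in multiple datasets
#'
#' Merges per-dataset retained record lists and sets \code{multiple_hit} on
#' every record whose (driver entrez, target entrez) pair is retained in at
#' least two distinct datasets.  Matching ignores context and reagent
#' suffix, and the flag is symmetric across all datasets where the pair
#' appears.  Statistics (p, CLES, median difference) are never modified.
#'
#' @param recordSets list of retained (post-filter) record data.frames, one
#'   per dataset.
#' @return A single merged record data.frame.
#' @export
flagMultipleHits <- function(recordSets) {
    stopifnot(is.list(recordSets), length(recordSets) >= 1L)
    ids <- vapply(recordSets, function(r)
        if (nrow(r)) r$dataset[1L] else NA_character_, character(1))
    if (anyDuplicated(stats::na.omit(ids)))
        stop("duplicate dataset_id across record sets: '",
             ids[duplicated(ids) & !is.na(ids)][1], "'")
    merged <- do.call(rbind, recordSets)
    if (is.null(merged) || !nrow(merged)) return(.emptyRecords())
    rownames(merged) <- NULL
    pair <- paste(merged$driver_entrez, merged$target_entrez, sep = "\r")
    nDatasets <- vapply(split(merged$dataset, pair),
                        function(d) length(unique(d)), integer(1))
    merged$multiple_hit <- unname(nDatasets[pair] >= 2L)
    merged
}

#' Read a gene identifier index
#'
#' Tab-delimited HGNC-like extract with columns \code{symbol},
#' \code{entrez}, \code{ensembl_gene}, \code{ensembl_protein},
#' \code{synonyms} (pipe-separated alternative symbols, may be empty).
#'
#' @param file path to the table.
#' @return data.frame of class \code{geneIndex}.
#' @export
readGeneIndex <- function(file) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("symbol", "entrez", "ensembl_gene", "ensembl_protein",
              "synonyms")
    if (!all(need %in% colnames(d)))
        stop("gene index needs columns ", paste(need, collapse = ", "))
    if (anyDuplicated(d$entrez)) stop("gene index entrez ids must be unique")
    class(d) <- c("geneIndex", class(d))
    d
}

#' Resolve a gene query against the identifier index
#'
#' Case-insensitive lookup: primary symbols are checked first, then
#' synonyms, so a synonym colliding with a distinct primary symbol resolves
#' to the primary symbol (e.g. searching \code{HER2} finds ERBB2).  A query
#' whose synonyms match two or more distinct genes is an ambiguity error; a
#' query matching nothing returns \code{NULL}.
#'
#' @param query gene symbol or synonym.
#' @param index a gene index from [readGeneIndex()].
#' @return One row of the index, or \code{NULL} when not found.
#' @export
resolveGene <- function(query, index) {
    q <- toupper(as.character(query))
    hit <- which(toupper(index$symbol) == q)
    if (length(hit) == 1L) return(index[hit, , drop = FALSE])
    synHit <- which(vapply(strsplit(index$synonyms, "|", fixed = TRUE),
                           function(s) q %in% toupper(s), logical(1)))
    if (length(synHit) > 1L)
        stop("ambiguous gene query '", query, "': matches ",
             paste(index$symbol[synHit], collapse = ", "))
    if (length(synHit) == 1L) return(index[synHit, , drop = FALSE])
    NULL
}

#' Export the dependency network of one driver
#'
#' Writes the driver's retained targets and the functional interactions
#' among them (the induced subgraph, plus any driver-target edges) as a
#' two-section tab-delimited file: a \code{[nodes]} section
#' (\code{symbol entrez}) and an \code{[edges]} section
#' (\code{id1 id2 score tier}).  An empty record list yields a valid file
#' with headers only.
#'
#' @param records dependency records sharing one driver.
#' @param interactions an [InteractionTable-class].
#' @param file output path.
#' @return Invisibly, the path written.
#' @export
exportNetwork <- function(records, interactions, file) {
    if (nrow(records) && length(unique(records$driver_entrez)) != 1L)
        stop("records must share a single driver")
    nodes <- unique(records[, c("target_symbol", "target_entrez"),
                            drop = FALSE])
    ids <- c(nodes$target_symbol,
             if (nrow(records)) records$driver_symbol[1L])
    e <- interactions@edges
    keep <- e$id1 %in% ids & e$id2 %in% ids
    e <- e[keep, , drop = FALSE]
    con <- file(file, "w")
    on.exit(close(con))
    writeLines("[nodes]", con)
    writeLines("symbol\tentrez", con)
    if (nrow(nodes))
        writeLines(paste(nodes$target_symbol, nodes$target_entrez,
                         sep = "\t"), con)
    writeLines("[edges]", con)
    writeLines("id1\tid2\tscore\ttier", con)
    if (nrow(e))
        writeLines(paste(e$id1, e$id2, e$score, e$tier, sep = "\t"), con)
    invisible(file)
}
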