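# Run expr with a private RNG stream so generators never disturb the
# caller's random state.
.withSeed <- function(seed, expr) {
    hasSeed <- exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)
    if (hasSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

.synthDrivers <- function(nDrivers) {
    cls <- rep(c("oncogene", "tumor_suppressor", "oncogene", "oncogene"),
               length.out = nDrivers)
    mode <- rep(c("both", "both", "amplification_only", "mutation_only"),
                length.out = nDrivers)
    makeDrivers(sprintf("DRV%d", seq_len(nDrivers)),
                9000L + seq_len(nDrivers), cls, mode)
}

#' Generate a screen with planted dependencies
#'
#' Draws background sensitivity scores from a standard normal (scaled by
#' \code{noiseSd}; a heavy-tailed t with 3 df, rescaled to the same standard
#' deviation, is available to exercise rank-test robustness) and shifts the
#' scores of altered cell lines by \code{effectSize} at each planted
#' (driver, target) pair.  Defaults encode the reference simulation
#' conditions used throughout the package's calibration: a 30-cell-line
#' panel with 10 altered lines per driver, 100 targets, a planted mean
#' shift of -2 score units at noise sd 1.  Tissues are assigned round-robin.
#' Fully reproducible from \code{seed}; the caller's RNG state is untouched.
#'
#' When \code{truth} is supplied (from a previous call) its driver set,
#' alteration assignments and planted pairs are reused and only the noise is
#' redrawn, which simulates a second dataset screening the same panel.
#'
#' @param nCellLines,nTargets panel dimensions (defaults 30 and 100).
#' @param truth optional planted-truth list to reuse.
#' @param seed integer seed.
#' @param nAltered altered lines per driver (default 10).
#' @param nDrivers number of drivers; classes/modes cycle through the four
#'   rule combinations (default 1, an oncogene with mode "both").
#' @param effectSize planted mean shift, score units; must be <= 0 for a
#'   true sensitivity dependency (default -2).
#' @param noiseSd noise standard deviation (default 1).
#' @param tissues tissue labels assigned round-robin.
#' @param noiseModel \code{"normal"} or \code{"t3"}.
#' @param suffixedTargets number of leading targets emitted as two suffixed
#'   score solutions (simulating multiple ATARiS solutions; default 0).
#' @param datasetId dataset name for the generated screen.
#' @param minAltered planted drivers must be altered in at least this many
#'   lines, or generation fails (default 3).
#' @return list with elements \code{screen} (a [ScreenMatrix-class]) and
#'   \code{truth} (drivers, assignments matrix, planted pair table,
#'   noiseSd, seed).
#' @export
generateScreen <- function(nCellLines = 30L, nTargets = 100L, truth = NULL,
                           seed = 1L, nAltered = 10L, nDrivers = 1L,
                           effectSize = -2, noiseSd = 1,
                           tissues = c("BREAST", "LUNG", "SKIN"),
                           noiseModel = c("normal", "t3"),
                           suffixedTargets = 0L,
                           datasetId = "synth_screen_1", minAltered = 3L) {
    noiseModel <- match.arg(noiseModel)
    stopifnot(nCellLines >= 1L, nTargets >= 1L)
    .withSeed(seed, {
        cl <- data.frame(
            name = sprintf("CL%03d", seq_len(nCellLines)),
            tissue = rep_len(tissues, nCellLines),
            stringsAsFactors = FALSE)
        full <- paste(cl$name, cl$tissue, sep = "_")
        if (is.null(truth)) {
            drivers <- .synthDrivers(nDrivers)
            assign <- matrix(FALSE, nDrivers, nCellLines,
                             dimnames = list(paste(drivers$gene_symbol,
                                                   drivers$entrez_id,
                                                   sep = "_"), full))
            for (i in seq_len(nDrivers))
                assign[i, sample(nCellLines, nAltered)] <- TRUE
            planted <- data.frame(
                driver_entrez = drivers$entrez_id,
                target_entrez = 1000L + seq_len(nDrivers),
                effect = effectSize, context = "PANCAN",
                stringsAsFactors = FALSE)
            truth <- list(drivers = drivers, assignments = assign,
                          planted = planted, noiseSd = noiseSd, seed = seed)
        }
        if (any(rowSums(truth$assignments) < minAltered))
            stop("a planted driver is altered in fewer than ", minAltered,
                 " cell lines")
        base <- data.frame(symbol = sprintf("TGT%03d", seq_len(nTargets)),
                           entrez = 1000L + seq_len(nTargets),
                           suffix = NA_character_, stringsAsFactors = FALSE)
        if (suffixedTargets > 0L) {
            sufIdx <- seq_len(min(suffixedTargets, nTargets))
            dup <- base[sufIdx, ]
            base$suffix[sufIdx] <- "1"
            dup$suffix <- "2"
            base <- rbind(base, dup)
            base <- base[order(base$entrez, base$suffix,
                               na.last = FALSE), ]
        }
        nT <- nrow(base)
        draw <- function(n) switch(noiseModel,
            normal = stats::rnorm(n, sd = truth$noiseSd),
            t3 = stats::rt(n, df = 3) / sqrt(3) * truth$noiseSd)
        scores <- matrix(draw(nT * nCellLines), nrow = nT)
        for (k in seq_len(nrow(truth$planted))) {
            pl <- truth$planted[k, ]
            tIdx <- which(base$entrez == pl$target_entrez)
            dIdx <- which(truth$drivers$entrez_id == pl$driver_entrez)
            altIdx <- which(truth$assignments[dIdx, ])
            ctxOk <- if (pl$context == "PANCAN") altIdx
                     else altIdx[cl$tissue[altIdx] == pl$context]
            scores[tIdx, ctxOk] <- scores[tIdx, ctxOk] + pl$effect
        }
        screen <- ScreenMatrix(scores, base, cl, datasetId)
        list(screen = screen, truth = truth)
    })
}

#' Generate genotype tables that invert to a planted alteration matrix
#'
#' For every altered (cell line, driver) assignment in \code{truth} this
#' emits mutation and/or copy-number records that the alteration-calling
#' rules will call functional, respecting each driver's alteration mode
#' (amplification-only drivers get min_cn = 9 amplifications and never a
#' qualifying mutation; mutation-only drivers get recurrent missense events
#' with site recurrence 5; mode-"both" oncogenes alternate amplification and
#' mutation evidence; tumor suppressors alternate homozygous deletions and
#' nonsense mutations).  Wild-type lines additionally receive decoy records
#' sitting just below each rule boundary (site recurrence 2; min_cn 7;
#' min_cn 1) so that threshold regressions change call counts.
#'
#' @param truth planted-truth list from [generateScreen()].
#' @param seed integer seed (decoy placement only).
#' @return list with data.frames \code{mutations} and \code{copyNumber}.
#' @export
generateGenotype <- function(truth, seed = truth$seed) {
    drivers <- truth$drivers
    assign <- truth$assignments
    lines <- colnames(assign)
    mut <- list(); cn <- list()
    addMut <- function(line, drv, effect, rec)
        mut[[length(mut) + 1L]] <<- data.frame(
            cell_line = line, gene_symbol = drv$gene_symbol,
            entrez_id = drv$entrez_id, effect = effect,
            site_recurrence = rec, stringsAsFactors = FALSE)
    addCn <- function(line, drv, lo, hi)
        cn[[length(cn) + 1L]] <<- data.frame(
            cell_line = line, gene_symbol = drv$gene_symbol,
            entrez_id = drv$entrez_id, min_cn = lo, max_cn = hi,
            stringsAsFactors = FALSE)
    .withSeed(seed, {
        for (i in seq_len(nrow(drivers))) {
            drv <- drivers[i, ]
            alt <- which(assign[i, ])
            wt <- which(!assign[i, ])
            for (k in seq_along(alt)) {
                line <- lines[alt[k]]
                switch(drv$alteration_mode,
                    amplification_only = addCn(line, drv, 9L, 12L),
                    mutation_only = addMut(line, drv, "missense", 5L),
                    both = if (drv$gene_class == "oncogene") {
                        if (k %% 2L) addCn(line, drv, 9L, 12L)
                        else addMut(line, drv, "missense", 5L)
                    } else {
                        if (k %% 2L) addCn(line, drv, 0L, 2L)
                        else addMut(line, drv, "nonsense", 0L)
                    })
            }
            # decoys on up to three wild-type lines, one per rule boundary
            for (k in seq_len(min(3L, length(wt)))) {
                line <- lines[wt[k]]
                if (k == 1L) addMut(line, drv, "missense", 2L)
                if (k == 2L) addCn(line, drv, 7L, 20L)
                if (k == 3L) addCn(line, drv, 1L, 2L)
            }
        }
    })
    list(mutations = if (length(mut)) do.call(rbind, mut) else
             data.frame(cell_line = character(), gene_symbol = character(),
                        entrez_id = integer(), effect = character(),
                        site_recurrence = integer()),
         copyNumber = if (length(cn)) do.call(rbind, cn) else
             data.frame(cell_line = character(), gene_symbol = character(),
                        entrez_id = integer(), min_cn = integer(),
                        max_cn = integer()))
}

#' Generate annotation fixtures
#'
#' Produces an interaction edge list whose scores straddle every tier
#' boundary (0.35, 0.45, 0.75, 0.95 over consecutive gene pairs), a
#' drug-gene table covering kept and excluded categories and sources, and a
#' gene index in which the first gene carries a synthetic synonym (and
#' ERBB2, when present, its HER2/NEU aliases).
#'
#' @param genes data.frame with columns \code{symbol} and \code{entrez}.
#' @param seed integer seed (unused randomness reserved for future noise;
#'   kept for interface uniformity).
#' @return list of data.frames: \code{interactions} (id1, id2, score),
#'   \code{drugGene} (gene, drug, interaction_category, source),
#'   \code{geneIndex}.
#' @export
generateAnnotationFixtures <- function(genes, seed = 1L) {
    stopifnot(nrow(genes) >= 1L)
    sym <- as.character(genes$symbol)
    scores <- c(0.35, 0.45, 0.75, 0.95)
    inter <- if (nrow(genes) >= 2L) {
        i <- seq_len(nrow(genes) - 1L)
        data.frame(id1 = sym[i], id2 = sym[i + 1L],
                   score = rep_len(scores, length(i)),
                   stringsAsFactors = FALSE)
    } else data.frame(id1 = character(), id2 = character(),
                      score = numeric())
    g1 <- sym[1L]
    drug <- data.frame(
        gene = c(g1, g1, g1, g1, sym),
        drug = c(paste0(g1, "ib"), paste0(g1, "IB"), "excluded_drug",
                 "trial_drug", paste0(tolower(sym), "_mab")),
        interaction_category = c("inhibitor", "inhibitor", "inhibitor",
                                 "inhibitor", rep("agonist", length(sym))),
        source = c("TALC", "TEND", "MyCancerGenome",
                   "MyCancerGenomeClinicalTrial", rep("TALC", length(sym))),
        stringsAsFactors = FALSE)
    syn <- rep("", nrow(genes))
    syn[1L] <- paste0("ALT", sym[1L])
    isE <- sym == "ERBB2"
    syn[isE] <- ifelse(nzchar(syn[isE]), paste0(syn[isE], "|HER2|NEU"),
                       "HER2|NEU")
    idx <- data.frame(
        symbol = sym, entrez = as.character(genes$entrez),
        ensembl_gene = sprintf("ENSG%08d", as.integer(genes$entrez)),
        ensembl_protein = sprintf("ENSP%08d", as.integer(genes$entrez)),
        synonyms = syn, stringsAsFactors = FALSE)
    list(interactions = inter, drugGene = drug, geneIndex = idx)
}
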