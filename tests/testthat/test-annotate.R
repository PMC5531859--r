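.writeLinesTmp <- function(lines) withr::local_tempfile(
    lines = lines, .local_envir = parent.frame())

test_that("interaction loading keeps only score > 0.4 and tiers the rest", {
    f <- .writeLinesTmp(c("A B 0.35", "B C 0.40", "C D 0.45", "D E 0.75",
                          "E F 0.95", "F F 0.99"))
    it <- loadInteractions(f)
    expect_equal(nrow(it@edges), 3L)               # 0.45, 0.75, 0.95 kept
    expect_equal(interactionTier(it, "C", "D"), "medium")
    expect_equal(interactionTier(it, "D", "E"), "high")
    expect_equal(interactionTier(it, "E", "F"), "highest")
    expect_equal(interactionTier(it, "F", "F"), "none")  # self-edge dropped
    # symmetric lookup
    expect_equal(interactionTier(it, "D", "C"),
                 interactionTier(it, "C", "D"))
    # tier boundaries partition (0.4, 1]: boundary values land uniquely
    fb <- .writeLinesTmp(c("A B 0.7", "C D 0.700001", "E F 0.9",
                           "G H 0.900001"))
    itb <- loadInteractions(fb)
    expect_equal(interactionTier(itb, "A", "B"), "medium")
    expect_equal(interactionTier(itb, "C", "D"), "high")
    expect_equal(interactionTier(itb, "E", "F"), "high")
    expect_equal(interactionTier(itb, "G", "H"), "highest")
})

test_that("milli-scale scores are detected and converted; ambiguity fails", {
    f <- .writeLinesTmp(c("A B 700", "B C 950", "C D 350"))
    it <- loadInteractions(f)
    expect_equal(sort(it@edges$score), c(0.7, 0.95))
    expect_equal(interactionTier(it, "A", "B"), "medium")   # 0.700 <= 0.7
    expect_equal(interactionTier(it, "B", "C"), "highest")
    funit <- .writeLinesTmp(c("A B 0.7"))
    expect_error(loadInteractions(funit, scoreScale = "milli"),
                 "ambiguous")
    fbad <- .writeLinesTmp(c("A B 0.7", "B C"))
    expect_error(loadInteractions(fbad), "line 2")
})

test_that("protein-id mapping applies before self-edge removal", {
    f <- .writeLinesTmp(c("9606.ENSP1 9606.ENSP2 900",
                          "9606.ENSP1 9606.ENSP3 800"))
    mp <- data.frame(p = c("9606.ENSP1", "9606.ENSP2", "9606.ENSP3"),
                     g = c("ERBB2", "ERBB2", "PIK3CA"))
    it <- loadInteractions(f, mapping = mp)
    # first row maps to ERBB2-ERBB2: a self-edge, dropped
    expect_equal(nrow(it@edges), 1L)
    expect_equal(interactionTier(it, "ERBB2", "PIK3CA"), "high")
})

test_that("string annotation sets tiers without touching statistics", {
    f <- .writeLinesTmp(c("DRV TGT1 0.95", "DRV TGT2 0.5"))
    it <- loadInteractions(f)
    rec <- data.frame(dataset = "d", context = "PANCAN",
                      driver_symbol = "DRV", driver_entrez = 1L,
                      target_symbol = c("TGT1", "TGT2", "TGT3", "DRV"),
                      target_entrez = 2:5, suffix = "", n_altered = 3L,
                      n_wildtype = 5L, U = 10, p = 0.01, cles = 0.8,
                      delta_median = -1, p_method = "exact",
                      multiple_hit = FALSE, string_tier = "none",
                      inhibitors = "", stringsAsFactors = FALSE)
    ann <- annotateString(rec, it)
    expect_equal(ann$string_tier, c("highest", "medium", "none", "none"))
    expect_identical(ann[, c("p", "cles", "delta_median")],
                     rec[, c("p", "cles", "delta_median")])
})

test_that("inhibitor loading filters category and excluded sources", {
    f <- .writeLinesTmp(c(
        "EGFR\terlotinib\tinhibitor\tTALC",
        "EGFR\tdrugX\tinhibitor\tMyCancerGenome",
        "EGFR\tdrugZ\tinhibitor\tMyCancerGenomeClinicalTrial",
        "EGFR\tdrugY\tagonist\tTALC",
        "EGFR\tErlotinib\tinhibitor\tTEND",
        "BRAF\tvemurafenib\tinhibitor\tTALC"))
    im <- loadInhibitors(f)
    expect_equal(inhibitorsOf(im, "EGFR"), "erlotinib")  # case-insens dedup
    expect_equal(inhibitorsOf(im, "BRAF"), "vemurafenib")
    # re-scan the loaded map: no excluded source, inhibitors only
    expect_false(any(im@table$source %in% im@excludedSources))
    fbad <- .writeLinesTmp(c("EGFR\terlotinib\tinhibitor"))
    expect_error(loadInhibitors(fbad), "line 1")

    rec <- data.frame(target_symbol = c("EGFR", "KRAS"),
                      inhibitors = "", stringsAsFactors = FALSE)
    ann <- annotateInhibitors(rec, im)
    expect_equal(ann$inhibitors, c("erlotinib", ""))
})

test_that("multiple-hit flags require the pair in two distinct datasets", {
    mk <- function(ds, ctx, drv, tgt)
        data.frame(dataset = ds, context = ctx, driver_symbol = "D",
                   driver_entrez = drv, target_symbol = "T",
                   target_entrez = tgt, suffix = "", n_altered = 3L,
                   n_wildtype = 5L, U = 10, p = 0.01, cles = 0.8,
                   delta_median = -1, p_method = "exact",
                   multiple_hit = FALSE, string_tier = "none",
                   inhibitors = "", stringsAsFactors = FALSE)
    a <- rbind(mk("A", "PANCAN", 1L, 10L), mk("A", "PANCAN", 1L, 11L))
    b <- rbind(mk("B", "BREAST", 1L, 10L), mk("B", "PANCAN", 2L, 12L))
    m <- flagMultipleHits(list(a, b))
    # shared pair flagged in both datasets despite different contexts
    expect_equal(m$multiple_hit[m$target_entrez == 10L], c(TRUE, TRUE))
    expect_false(any(m$multiple_hit[m$target_entrez %in% c(11L, 12L)]))
    # annotation-only contract
    expect_identical(m[, c("p", "cles", "delta_median")],
                     rbind(a, b)[, c("p", "cles", "delta_median")])
    expect_error(flagMultipleHits(list(a, a)), "duplicate dataset_id")
})

test_that("gene resolution prefers primary symbols, then synonyms", {
    f <- .writeLinesTmp(c(
        "symbol\tentrez\tensembl_gene\tensembl_protein\tsynonyms",
        "ERBB2\t2064\tENSG1\tENSP1\tHER2|NEU",
        "MIEN1\t84299\tENSG2\tENSP2\tHER2-shared",
        "KRAS\t3845\tENSG3\tENSP3\t",
        "NRAS\t4893\tENSG4\tENSP4\tSHARED",
        "HRAS\t3265\tENSG5\tENSP5\tSHARED|KRAS"))
    idx <- readGeneIndex(f)
    expect_equal(resolveGene("HER2", idx)$symbol, "ERBB2")
    expect_equal(resolveGene("ERBB2", idx)$symbol, "ERBB2")
    expect_equal(resolveGene("her2", idx)$symbol, "ERBB2")
    # synonym colliding with a primary symbol resolves to the primary
    expect_equal(resolveGene("KRAS", idx)$symbol, "KRAS")
    expect_error(resolveGene("SHARED", idx), "ambiguous.*NRAS.*HRAS")
    expect_null(resolveGene("NOPE", idx))
    # synonym and primary-symbol lookup agree
    expect_identical(resolveGene("NEU", idx), resolveGene("ErbB2", idx))
})

test_that("network export writes nodes and the induced edge set", {
    f <- .writeLinesTmp(c("T1 T2 0.95", "T1 T9 0.8", "DRV T3 0.7"))
    it <- loadInteractions(f)
    rec <- data.frame(dataset = "d", context = "PANCAN",
                      driver_symbol = "DRV", driver_entrez = 1L,
                      target_symbol = c("T1", "T2", "T3"),
                      target_entrez = 2:4, suffix = "",
                      stringsAsFactors = FALSE)
    out <- withr::local_tempfile()
    exportNetwork(rec, it, out)
    lines <- readLines(out)
    nodeSec <- lines[(which(lines == "[nodes]") + 2):(which(
        lines == "[edges]") - 1)]
    edgeSec <- lines[(which(lines == "[edges]") + 2):length(lines)]
    expect_equal(length(nodeSec), 3L)
    # induced edges: T1-T2 and the driver-target edge DRV-T3; T1-T9 outside
    expect_setequal(edgeSec, c("T1\tT2\t0.95\thighest",
                               "DRV\tT3\t0.7\tmedium"))
    # empty record list: valid headers only
    out2 <- withr::local_tempfile()
    exportNetwork(rec[0, ], it, out2)
    expect_equal(readLines(out2),
                 c("[nodes]", "symbol\tentrez", "[edges]",
                   "id1\tid2\tscore\ttier"))
    expect_error(exportNetwork(transform(rec, driver_entrez = 1:3), it,
                               out2), "single driver")
})
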