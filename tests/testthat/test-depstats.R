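test_that("CLES matches hand-enumerated pair probabilities", {
    expect_equal(cles(c(-3, -2), c(-1, 0, 1)), 1)
    expect_equal(cles(c(-2, 0), c(-1, 1)), 0.75)
    expect_equal(cles(0, 0), 0.5)
    expect_error(cles(numeric(0), 1), "non-empty")
})

test_that("CLES is complementary, rank-invariant and equal to U/(n1 n2)", {
    set.seed(101)
    for (i in 1:30) {
        n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
        a <- round(rnorm(n1), 1)   # rounding induces ties
        w <- round(rnorm(n2), 1)
        expect_equal(cles(a, w) + cles(w, a), 1)
        mono <- function(x) exp(2 * x) - 5
        expect_equal(cles(mono(a), mono(w)), cles(a, w))
        expect_equal(cles(a, w),
                     mannWhitneyOneSided(a, w)$U / (n1 * n2))
        expect_equal(cles(a, w), oracleCles(a, w))
    }
})

test_that("one-sided Mann-Whitney matches exact enumeration and wilcox.test", {
    r <- mannWhitneyOneSided(c(-3, -2, -1), c(1, 2, 3))
    expect_equal(r$U, 9)
    expect_equal(r$p, 0.05)            # 1/20 assignments as extreme
    expect_equal(r$method, "exact")
    expect_equal(mannWhitneyOneSided(c(1, 2, 3), c(-3, -2, -1))$p, 1)
    expect_warning(rd <- mannWhitneyOneSided(5, 5), "degenerate")
    expect_equal(rd$p, 1)

    set.seed(202)
    for (i in 1:20) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        a <- rnorm(n1); w <- rnorm(n2)    # continuous: tie-free
        r <- mannWhitneyOneSided(a, w)
        expect_equal(r$method, "exact")
        expect_equal(r$p, oracleExactP(a, w), tolerance = 1e-12)
        # independent library cross-check ("less": altered shifted down)
        wt <- wilcox.test(a, w, alternative = "less", exact = TRUE)
        expect_equal(r$p, wt$p.value, tolerance = 1e-12)
    }
})

test_that("normal approximation tracks the exact p for small samples", {
    set.seed(303)
    for (i in 1:20) {
        n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
        if (n1 + n2 > 12) next
        a <- rnorm(n1); w <- rnorm(n2)
        pe <- mannWhitneyOneSided(a, w)$p
        pn <- mannWhitneyOneSided(a, w, exactMax = 0)$p
        expect_lt(abs(pe - pn), 0.02)
    }
    # ties force the corrected normal path
    r <- mannWhitneyOneSided(c(-1, 0, 0, -2), c(0, 1, 1, 2))
    expect_equal(r$method, "normal")
    wt <- suppressWarnings(wilcox.test(c(-1, 0, 0, -2), c(0, 1, 1, 2),
                                       alternative = "less", exact = FALSE,
                                       correct = TRUE))
    expect_equal(r$p, wt$p.value, tolerance = 1e-10)
})

test_that("median differences are in score units with sensitivity negative", {
    expect_equal(deltaMedian(c(-4, -2), c(0, 2)), -4)
    expect_equal(deltaMedian(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(deltaMedian(1, 0), 1)
})

.scanFixture <- function() {
    # 10 cell lines over two tissues; driver altered in CL1-3 (all BREAST);
    # target G1 completely separates the groups
    lines <- data.frame(name = sprintf("CL%d", 1:10),
                        tissue = rep(c("BREAST", "LUNG"), each = 5))
    scores <- cbind(c(-5, -4, -3, seq(0.5, 4, length.out = 7)),
                    rnorm(10),
                    c(NA, NA, NA, rnorm(7)))
    screen <- tinyScreen(scores, tinyTargets(3), lines, "ds1")
    drivers <- makeDrivers("DRV", 900L, "oncogene", "both")
    full <- paste(lines$name, lines$tissue, sep = "_")
    cn <- data.frame(cell_line = full[1:3], gene_symbol = "DRV",
                     entrez_id = 900L, min_cn = 9L, max_cn = 12L)
    mut <- data.frame(cell_line = character(), gene_symbol = character(),
                      entrez_id = integer(), effect = character(),
                      site_recurrence = integer())
    am <- buildAlterationMatrix(mut, cn, drivers, full)
    list(screen = screen, am = am)
}

test_that("scan emits records per context with group-size gating", {
    set.seed(404)
    fx <- .scanFixture()
    rec <- scanDependencies(fx$screen, fx$am)
    # PANCAN: all 3 targets tested except G3 (all altered scores missing)
    pan <- rec[rec$context == "PANCAN", ]
    expect_equal(pan$target_symbol, c("G1", "G2"))
    expect_equal(pan$cles[pan$target_symbol == "G1"], 1)
    expect_equal(pan$n_altered, c(3L, 3L))
    # BREAST: driver altered in 3 breast lines, but only 2 wild-type there
    expect_false(any(rec$context == "BREAST"))
    # LUNG: only 0 altered lines -> no records
    expect_false(any(rec$context == "LUNG"))
    # deterministic output
    expect_identical(rec, scanDependencies(fx$screen, fx$am))
    # empty intersection is an error
    other <- tinyScreen(matrix(rnorm(4), 2), tinyTargets(2),
                        data.frame(name = c("X1", "X2"), tissue = "SKIN"))
    expect_error(scanDependencies(other, fx$am), "no cell lines")
})

test_that("filtering applies strict p and inclusive CLES thresholds", {
    rec <- scanDependencies(.scanFixture()$screen, .scanFixture()$am)[0, ]
    mk <- function(p, cl) {
        r <- rec[0, ]
        r[1, c("p", "cles")] <- list(p, cl)
        r$dataset <- "d"; r
    }
    expect_equal(nrow(filterCGDs(mk(0.049, 0.65))), 1L)
    expect_equal(nrow(filterCGDs(mk(0.05, 0.90))), 0L)
    expect_equal(nrow(filterCGDs(mk(0.001, 0.64))), 0L)
    # subset, threshold satisfaction, idempotence
    set.seed(11)
    g <- generateScreen(seed = 5)
    geno <- generateGenotype(g$truth)
    am <- buildAlterationMatrix(geno$mutations, geno$copyNumber,
                                g$truth$drivers,
                                colnames(g$truth$assignments))
    all <- scanDependencies(g$screen, am)
    kept <- filterCGDs(all)
    expect_true(all(kept$p < 0.05 & kept$cles >= 0.65))
    expect_true(nrow(kept) <= nrow(all))
    expect_identical(filterCGDs(kept), kept)
})

test_that("multi-score resolution keeps the lowest-p solution", {
    base <- scanDependencies(.scanFixture()$screen, .scanFixture()$am)[0, ]
    mk <- function(suffix, p, cl, entrez = 7L) {
        r <- base[0, ]
        r[1, ] <- list("ds", "PANCAN", "DRV", 900L, "TGT", entrez, suffix,
                       3L, 5L, 10, p, cl, -1, "exact", FALSE, "none", "")
        r
    }
    recs <- rbind(mk("1", 0.01, 0.8), mk("2", 0.03, 0.9))
    expect_equal(resolveMultiscore(recs)$suffix, "1")
    # equal p: higher CLES wins; equal both: smallest suffix
    recs2 <- rbind(mk("1", 0.02, 0.7), mk("2", 0.02, 0.8))
    expect_equal(resolveMultiscore(recs2)$suffix, "2")
    recs3 <- rbind(mk("2", 0.02, 0.8), mk("1", 0.02, 0.8))
    expect_equal(resolveMultiscore(recs3)$suffix, "1")
    # unsuffixed single record unchanged; distinct entrez kept apart
    single <- mk("", 0.2, 0.5)
    expect_identical(resolveMultiscore(single), single)
    two <- rbind(mk("", 0.01, 0.8, entrez = 7L),
                 mk("", 0.04, 0.7, entrez = 8L))
    expect_equal(nrow(resolveMultiscore(two)), 2L)
})

test_that("BH adjustment is opt-in, per family, and leaves p untouched", {
    base <- scanDependencies(.scanFixture()$screen, .scanFixture()$am)
    expect_identical(adjustPvalues(base, "none"), base)
    r <- base[rep(1, 3), ]
    r$p <- c(0.01, 0.02, 0.03)
    r$target_entrez <- 1:3
    adj <- adjustPvalues(r, "benjamini_hochberg")
    expect_equal(adj$q, c(0.03, 0.03, 0.03))
    expect_equal(adj$p, r$p)
    one <- adjustPvalues(r[1, ], "benjamini_hochberg")
    expect_equal(one$q, one$p)
})

test_that("boxplot data mirrors the groups behind one dependency", {
    fx <- .scanFixture()
    bp <- boxplotData(fx$screen, fx$am, 900L, 101L)
    expect_equal(nrow(bp), 10L)
    expect_equal(sum(bp$group == "altered"), 3L)
    expect_equal(bp$score[bp$group == "altered"], c(-5, -4, -3))
    expect_setequal(unique(bp$tissue), c("BREAST", "LUNG"))
})
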