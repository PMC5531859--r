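# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the implementation's code paths: CLES by explicit
# double loop over pairs, the exact one-sided p by enumerating every
# C(n1+n2, n1) assignment of the pooled scores to the altered group.

oracleCles <- function(a, w) {
    s <- 0
    for (x in a) for (y in w)
        s <- s + if (x < y) 1 else if (x == y) 0.5 else 0
    s / (length(a) * length(w))
}

oracleU <- function(a, w) oracleCles(a, w) * length(a) * length(w)

oracleExactP <- function(a, w) {
    pooled <- c(a, w)
    n1 <- length(a)
    uObs <- oracleU(a, w)
    idx <- utils::combn(length(pooled), n1)
    hits <- 0
    for (j in seq_len(ncol(idx))) {
        aa <- pooled[idx[, j]]
        ww <- pooled[-idx[, j]]
        if (oracleU(aa, ww) >= uObs - 1e-9) hits <- hits + 1
    }
    hits / ncol(idx)
}

# A tiny hand-built screen: scores given cell-lines-in-rows (as in the file
# format), transposed into the ScreenMatrix convention.
tinyScreen <- function(scores, targets, cellLines, datasetId = "tiny") {
    ScreenMatrix(t(as.matrix(scores)), targets, cellLines, datasetId)
}

tinyTargets <- function(n) {
    data.frame(symbol = sprintf("G%d", seq_len(n)),
               entrez = 100L + seq_len(n), suffix = NA_character_,
               stringsAsFactors = FALSE)
}

tinyCellLines <- function(n, tissue = "LUNG") {
    data.frame(name = sprintf("CL%d", seq_len(n)),
               tissue = rep_len(tissue, n), stringsAsFactors = FALSE)
}
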