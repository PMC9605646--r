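# Independent oracles kept deliberately naive: they re-derive each statistic
# from its definition and never call the implementation they check.

# OLS by the normal equations
olsOracle <- function(x, y) {
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# two-sample KS D: brute-force sup over every ECDF step point
ksOracle <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t),
                   numeric(1))))
}

# Benjamini-Hochberg step-up from its definition
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in rev(seq_len(m - 1L))) adj[i] <- min(adj[i], adj[i + 1L])
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
}

# all permutations of a vector (n! rows)
allPermutations <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in allPermutations(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

# tiny expression fixture: named counts with two groups
tinyMatrix <- function(values = NULL, nGenes = 3L, nCells = 4L,
                       groups = NULL, layer = "raw-count") {
    if (is.null(values))
        values <- matrix(seq_len(nGenes * nCells), nGenes, nCells)
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
    colnames(values) <- sprintf("c%d", seq_len(ncol(values)))
    if (is.null(groups))
        groups <- rep(c("naive", "primed"), length.out = ncol(values))
    ExpressionMatrix(values, groups = groups, layer = layer)
}

writeTsvFixture <- function(values, path) {
    df <- data.frame(gene_id = rownames(values), values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))
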