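#' Two-tailed pooled-variance Student's t-test
#'
#' Unpaired two-sample t with pooled variance and `|x| + |y| - 2` degrees of
#' freedom. A degenerate comparison (zero pooled variance) returns p = 1
#' with a warning instead of failing, so screens over many gene sets keep
#' running.
#'
#' @param x,y numeric samples with at least 2 values each (NAs dropped).
#' @return A list with elements `t` and `p`.
#' @export
studentTTwoSample <- function(x, y) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L)
        stop("both samples need >= 2 finite values")
    pooled <- ((length(x) - 1) * stats::var(x) +
               (length(y) - 1) * stats::var(y)) /
              (length(x) + length(y) - 2)
    if (pooled == 0) {
        warning("zero pooled variance; degenerate comparison, p set to 1")
        return(list(t = 0, p = 1))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    list(t = unname(tt$statistic), p = unname(tt$p.value))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validates that p-values lie in (0, 1] and applies the step-up
#' adjustment: `adj_i = min over ranks j >= rank(i) of p_(j) * m / j`,
#' capped at 1, returned in the original order.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
benjaminiHochberg <- function(pvalues) {
    if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Per-miRNA comparison of target mean expression and noise between groups
#'
#' For each differentially expressed miRNA, compares its expressed target
#' genes between the two cell groups, separately for each metric: the log10
#' mean expression and the RCV, on every supplied layer. The test is the
#' unpaired pooled-variance t-test; Benjamini-Hochberg adjustment is applied
#' per metric across miRNAs. miRNAs with fewer than `minTargets` usable
#' targets for a metric are skipped with a warning.
#'
#' @param deSet data.frame with columns `mirna_id` and `direction` (the
#'   group each miRNA is more highly expressed in); differential calls are
#'   pipeline inputs, produced externally.
#' @param targetMap a [TargetMap-class].
#' @param noiseTables named list of layers (e.g. `rpkm`, `denoised`), each
#'   itself a named list of exactly two noise tables (one per cell group)
#'   computed on the same genes.
#' @param minTargets minimum usable targets per test (default 3).
#' @return data.frame with columns `mirna_id`, `direction`, `metric`,
#'   `t_statistic`, `p_value`, `fdr`, `n_targets`; metrics are named
#'   `mean_<layer>` and `rcv_<layer>`.
#' @export
perMiRNAComparison <- function(deSet, targetMap, noiseTables,
                               minTargets = 3L) {
    stopifnot(is.data.frame(deSet),
              all(c("mirna_id", "direction") %in% names(deSet)))
    if (anyDuplicated(deSet$mirna_id))
        stop("each DE miRNA must have exactly one direction")
    rows <- list()
    skipped <- character()
    for (layerName in names(noiseTables)) {
        pair <- noiseTables[[layerName]]
        if (length(pair) != 2L)
            stop("layer '", layerName, "' must hold exactly 2 group tables")
        tabA <- pair[[1L]]; tabB <- pair[[2L]]
        shared <- intersect(tabA$gene_id, tabB$gene_id)
        a <- tabA[match(shared, tabA$gene_id), ]
        b <- tabB[match(shared, tabB$gene_id), ]
        for (i in seq_len(nrow(deSet))) {
            mir <- deSet$mirna_id[i]
            targets <- intersect(targetsOf(targetMap, mir), shared)
            idx <- match(targets, shared)
            for (stat in c("mean", "rcv")) {
                if (stat == "mean") {
                    ok <- a$mean[idx] > 0 & b$mean[idx] > 0
                    xa <- log10(a$mean[idx][ok])
                    xb <- log10(b$mean[idx][ok])
                } else {
                    ok <- is.finite(a$rcv[idx]) & is.finite(b$rcv[idx])
                    xa <- a$rcv[idx][ok]
                    xb <- b$rcv[idx][ok]
                }
                metric <- paste(stat, layerName, sep = "_")
                if (sum(ok) < minTargets) {
                    skipped <- c(skipped, paste0(mir, "/", metric))
                    next
                }
                tt <- studentTTwoSample(xa, xb)
                rows[[length(rows) + 1L]] <- data.frame(
                    mirna_id = mir, direction = deSet$direction[i],
                    metric = metric, t_statistic = tt$t, p_value = tt$p,
                    n_targets = sum(ok), stringsAsFactors = FALSE)
            }
        }
    }
    if (length(skipped))
        warning(length(skipped), " miRNA/metric comparison(s) skipped ",
                "(fewer than ", minTargets, " usable targets)")
    if (!length(rows))
        return(data.frame(mirna_id = character(), direction = character(),
                          metric = character(), t_statistic = numeric(),
                          p_value = numeric(), fdr = numeric(),
                          n_targets = integer()))
    out <- do.call(rbind, rows)
    out$fdr <- NA_real_
    for (m in unique(out$metric)) {
        sel <- out$metric == m
        out$fdr[sel] <- benjaminiHochberg(out$p_value[sel])
    }
    out
}

#' Combinatorial targeting frequency
#'
#' For each expressed gene, counts how many miRNAs of the given set target
#' it. Genes targeted by none are absent (implicit zero). The identity
#' `sum(frequencies) == sum over miRNAs of |expressed targets|` holds by
#' construction.
#'
#' @param mirnas character vector of miRNA ids (e.g. all DE miRNAs of one
#'   direction).
#' @param targetMap a [TargetMap-class].
#' @param expressedGenes gene universe to restrict to.
#' @return Named integer vector, gene id -> count.
#' @export
targetingFrequency <- function(mirnas, targetMap, expressedGenes) {
    stopifnot(methods::is(targetMap, "TargetMap"))
    hits <- lapply(intersect(mirnas, mirnaIds(targetMap)), function(m)
        intersect(targetsOf(targetMap, m), expressedGenes))
    counts <- table(unlist(hits, use.names = FALSE))
    stats::setNames(as.integer(counts), names(counts))
}

#' Select the most commonly targeted genes
#'
#' Ranks genes by targeting frequency and returns the top `k` ("commonest
#' targets"). Ties are broken deterministically: descending mean expression
#' (when supplied), then lexicographic gene id.
#'
#' @param freq named integer vector from [targetingFrequency()].
#' @param k number of genes to select (default 100); if fewer genes are
#'   targeted, all are returned with a warning.
#' @param meanExpr optional named numeric of mean expression for
#'   tie-breaking.
#' @param direction label recorded in the report.
#' @return data.frame with columns `direction`, `gene_id`,
#'   `targeting_frequency`, `rank`.
#' @export
topCommonTargets <- function(freq, k = 100L, meanExpr = NULL,
                             direction = NA_character_) {
    genes <- names(freq)
    me <- if (is.null(meanExpr)) rep(0, length(genes)) else {
        v <- meanExpr[genes]
        v[is.na(v)] <- 0
        as.numeric(v)
    }
    ord <- order(-as.integer(freq), -me, genes)
    if (length(ord) < k) {
        warning("only ", length(ord), " targeted gene(s); returning all")
        k <- length(ord)
    }
    sel <- ord[seq_len(k)]
    data.frame(direction = direction, gene_id = genes[sel],
               targeting_frequency = as.integer(freq[sel]),
               rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Hierarchical-clustering mixing of two gene sets
#'
#' Clusters genes (rows) of a log-transformed expression matrix and scores
#' how well two labelled gene sets interleave along the dendrogram's leaf
#' order: `mixing = fraction of adjacent leaf pairs with different labels`.
#' Under perfect mixing of label proportion p the expectation is about
#' `2 p (1 - p)`; well-separated sets give scores near `1/(n-1)`.
#'
#' @param counts gene x cell matrix of raw counts for the labelled genes.
#' @param labels named character/factor, gene id -> set label (2 or more
#'   genes per label required).
#' @param transform apply `log(count + 1)` (natural log) before clustering
#'   (default `TRUE`; set `FALSE` if `counts` is already transformed).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`); distance is Euclidean.
#' @return A list with `leafOrder` (gene ids in dendrogram order),
#'   `mixingScore`, and `expectedMixing` (the perfect-mixing reference
#'   `2 p (1 - p)`).
#' @export
clusterMixing <- function(counts, labels, transform = TRUE,
                          linkage = "average") {
    counts <- as.matrix(counts)
    labels <- labels[rownames(counts)]
    if (anyNA(labels)) stop("every gene row needs a label")
    tabl <- table(labels)
    if (length(tabl) < 2L || any(tabl < 2L))
        stop("need >= 2 genes per label in >= 2 labels")
    m <- if (transform) log(counts + 1) else counts
    hc <- stats::hclust(stats::dist(m), method = linkage)
    ord <- hc$order
    lab <- as.character(labels)[ord]
    mixing <- mean(lab[-1L] != lab[-length(lab)])
    p <- tabl[1L] / sum(tabl)
    list(leafOrder = rownames(counts)[ord],
         mixingScore = mixing,
         expectedMixing = unname(2 * p * (1 - p)))
}

#' Group-level comparison of the commonest targets
#'
#' For each direction's commonest-target report and each metric (log10 mean
#' and RCV per layer), tests whether the selected genes differ between the
#' two cell groups (unpaired pooled-variance t), and emits a long-format
#' table of the underlying values (violin-plot ready).
#'
#' @param reports named list of commonest-target reports (one per
#'   direction) from [topCommonTargets()].
#' @param noiseTables as in [perMiRNAComparison()].
#' @return A list with `tests` (direction, metric, t_statistic, p_value)
#'   and `values` (direction, metric, group, gene_id, value).
#' @export
groupLevelComparison <- function(reports, noiseTables) {
    tests <- list(); values <- list()
    for (dir in names(reports)) {
        genes <- reports[[dir]]$gene_id
        for (layerName in names(noiseTables)) {
            pair <- noiseTables[[layerName]]
            grpNames <- if (!is.null(names(pair))) names(pair) else
                c("groupA", "groupB")
            tabA <- pair[[1L]]; tabB <- pair[[2L]]
            ia <- match(genes, tabA$gene_id)
            ib <- match(genes, tabB$gene_id)
            for (stat in c("mean", "rcv")) {
                if (stat == "mean") {
                    va <- log10(ifelse(tabA$mean[ia] > 0, tabA$mean[ia], NA))
                    vb <- log10(ifelse(tabB$mean[ib] > 0, tabB$mean[ib], NA))
                } else {
                    va <- tabA$rcv[ia]; vb <- tabB$rcv[ib]
                }
                metric <- paste(stat, layerName, sep = "_")
                tt <- studentTTwoSample(va[is.finite(va)],
                                        vb[is.finite(vb)])
                tests[[length(tests) + 1L]] <- data.frame(
                    direction = dir, metric = metric,
                    t_statistic = tt$t, p_value = tt$p,
                    stringsAsFactors = FALSE)
                values[[length(values) + 1L]] <- data.frame(
                    direction = dir, metric = metric,
                    group = rep(grpNames, each = length(genes)),
                    gene_id = rep(genes, 2L),
                    value = c(va, vb), stringsAsFactors = FALSE)
            }
        }
    }
    list(tests = do.call(rbind, tests), values = do.call(rbind, values))
}

#' Log-fold-change summary of mean expression and noise between groups
#'
#' Per gene shared by the two noise tables: `lfc_mean = log2(mean_B /
#' mean_A)` (genes with a zero mean in either group carry NA) and
#' `noise_change = rcv_B - rcv_A`. RCV is already on the log10 scale, so
#' the difference is itself a log fold change of CV at matched mean.
#' Commonest-target genes can be flagged for overlay; the centroid of the
#' flagged genes (with its standard errors) quantifies whether they deviate
#' from the origin.
#'
#' @param noiseA,noiseB noise tables with `rcv` for the two groups.
#' @param flaggedGenes character vector of genes to flag (e.g. commonest
#'   targets).
#' @return data.frame with columns `gene_id`, `lfc_mean`, `noise_change`,
#'   `flagged`; the flagged-gene centroid (means, SEs, n) is attached as
#'   attribute `centroid`.
#' @export
logFoldChangeSummary <- function(noiseA, noiseB,
                                 flaggedGenes = character()) {
    shared <- intersect(noiseA$gene_id, noiseB$gene_id)
    if (!length(shared)) stop("no genes shared between the two tables")
    a <- noiseA[match(shared, noiseA$gene_id), ]
    b <- noiseB[match(shared, noiseB$gene_id), ]
    lfc <- ifelse(a$mean > 0 & b$mean > 0, log2(b$mean / a$mean), NA_real_)
    dn <- b$rcv - a$rcv
    out <- data.frame(gene_id = shared, lfc_mean = lfc, noise_change = dn,
                      flagged = shared %in% flaggedGenes,
                      stringsAsFactors = FALSE)
    fl <- out[out$flagged & is.finite(out$lfc_mean) &
              is.finite(out$noise_change), ]
    centroid <- if (nrow(fl) >= 2L) {
        list(lfc_mean = mean(fl$lfc_mean),
             noise_change = mean(fl$noise_change),
             se_lfc_mean = stats::sd(fl$lfc_mean) / sqrt(nrow(fl)),
             se_noise_change = stats::sd(fl$noise_change) / sqrt(nrow(fl)),
             n = nrow(fl))
    } else NULL
    attr(out, "centroid") <- centroid
    out
}
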