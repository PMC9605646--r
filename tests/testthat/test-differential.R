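test_that("pooled-variance t matches the closed form and is antisymmetric", {
    same <- studentTTwoSample(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    tt <- studentTTwoSample(c(1, 2, 3), c(4, 5, 6))
    # pooled sd = 1, se = sqrt(2/3), diff = -3
    expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
    expect_equal(tt$t, -3.674235, tolerance = 1e-6)
    expect_equal(tt$p, 2 * pt(tt$t, df = 4), tolerance = 1e-12)
    swapped <- studentTTwoSample(c(4, 5, 6), c(1, 2, 3))
    expect_equal(swapped$t, -tt$t)
    expect_equal(swapped$p, tt$p)
    expect_warning(deg <- studentTTwoSample(c(2, 2), c(2, 2)),
                   "pooled variance")
    expect_equal(deg$p, 1)
    expect_error(studentTTwoSample(1, c(1, 2)), ">= 2")
})

test_that("BH adjustment: worked example, edge cases, oracle on permutations", {
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
                 rep(0.04, 4))
    expect_equal(benjaminiHochberg(0.123), 0.123)
    expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
    expect_error(benjaminiHochberg(c(0.5, 0)), "\\(0, 1\\]")
    expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\(0, 1\\]")
    base <- c(0.003, 0.04, 0.19, 0.41, 0.62)
    for (k in 2:5)
        for (perm in allPermutations(base[seq_len(k)]))
            expect_equal(benjaminiHochberg(perm), bhOracle(perm),
                         tolerance = 1e-12)
})

test_that("targeting frequency counts DE miRNAs per gene; identity holds", {
    tm <- TargetMap(c("m1", "m1", "m2", "m2", "m3"),
                    c("ga", "gb", "ga", "gc", "ga"))
    freq <- targetingFrequency(c("m1", "m2", "m3"), tm,
                               c("ga", "gb", "gc", "gd"))
    expect_equal(freq[["ga"]], 3L)
    expect_equal(freq[["gb"]], 1L)
    expect_false("gd" %in% names(freq))  # implicit zero
    # double-counting identity on random fixtures
    set.seed(8)
    for (i in 1:5) {
        genes <- sprintf("g%02d", 1:30)
        mirnas <- sprintf("m%02d", 1:6)
        tmR <- generateTargetMap(30, 6, sample(3:20, 1), seed = i,
                                 geneIds = genes, mirnaIds = mirnas)
        expressed <- sample(genes, 20)
        fr <- targetingFrequency(mirnas, tmR, expressed)
        perMiRNA <- vapply(mirnas, function(m)
            length(intersect(targetsOf(tmR, m), expressed)), integer(1))
        expect_identical(sum(fr), sum(perMiRNA))
    }
})

test_that("top-k commonest targets: deterministic ranking and tie-breaks", {
    freq <- c(a = 3L, b = 2L, c = 2L, d = 1L)
    top <- topCommonTargets(freq, k = 2)
    expect_identical(top$gene_id, c("a", "b"))  # lexicographic tie-break
    expect_identical(top$rank, 1:2)
    # mean expression outranks the lexicographic rule
    top2 <- topCommonTargets(freq, k = 2, meanExpr = c(c = 10, b = 1))
    expect_identical(top2$gene_id, c("a", "c"))
    expect_warning(all4 <- topCommonTargets(freq, k = 10), "returning all")
    expect_identical(nrow(all4), 4L)
    expect_true(all(diff(all4$targeting_frequency) <= 0))
})

test_that("per-miRNA comparison: identical tables give p = 1, planted shift is found", {
    set.seed(55)
    genes <- sprintf("g%03d", 1:200)
    mkTab <- function(mean, rcv) data.frame(
        gene_id = genes, mean = mean, sd = NA, cv = NA,
        log10_mean = log10(mean), log10_cv = NA, eligible = TRUE,
        rcv = rcv)
    mean1 <- rlnorm(200, log(50), 1); rcv1 <- rnorm(200, 0, 0.1)
    mirnas <- sprintf("m%02d", 1:10)
    tm <- TargetMap(rep(mirnas, each = 25),
                    unlist(lapply(1:10, function(i) sample(genes, 25))))
    de <- data.frame(mirna_id = mirnas,
                     direction = rep(c("naive", "primed"), 5))
    identical <- perMiRNAComparison(de, tm,
        list(rpkm = list(naive = mkTab(mean1, rcv1),
                         primed = mkTab(mean1, rcv1))))
    expect_true(all(identical$p_value == 1))
    expect_true(all(identical$fdr == 1))
    expect_true(all(identical$fdr >= identical$p_value))
    expect_setequal(unique(identical$metric), c("mean_rpkm", "rcv_rpkm"))
    # plant a strong mean shift (x4) on m01's targets in group 2
    mean2 <- mean1
    mean2[genes %in% targetsOf(tm, "m01")] <-
        mean2[genes %in% targetsOf(tm, "m01")] / 4
    shifted <- perMiRNAComparison(de, tm,
        list(rpkm = list(naive = mkTab(mean1, rcv1),
                         primed = mkTab(mean2, rnorm(200, 0, 0.1)))))
    hit <- shifted[shifted$mirna_id == "m01" &
                   shifted$metric == "mean_rpkm", ]
    expect_lt(hit$fdr, 0.05)
    expect_error(perMiRNAComparison(
        data.frame(mirna_id = c("a", "a"), direction = c("x", "y")),
        tm, list()), "exactly one direction")
})

test_that("separable gene blocks barely mix; shuffled labels mix fully", {
    set.seed(66)
    blockA <- matrix(rep(c(100, 100, 0, 0), each = 10), 10, 4) +
        matrix(rnorm(40, 0, 0.5), 10, 4)
    blockB <- matrix(rep(c(0, 0, 100, 100), each = 10), 10, 4) +
        matrix(rnorm(40, 0, 0.5), 10, 4)
    counts <- pmax(rbind(blockA, blockB), 0)
    rownames(counts) <- sprintf("g%02d", 1:20)
    colnames(counts) <- sprintf("c%d", 1:4)
    labels <- setNames(rep(c("naive", "primed"), each = 10),
                       rownames(counts))
    sep <- clusterMixing(counts, labels)
    expect_equal(sep$mixingScore, 1 / 19)  # one discordant junction
    expect_equal(sep$expectedMixing, 0.5)
    expect_setequal(sep$leafOrder, rownames(counts))
    # identical rows + shuffled labels: mixing near 2p(1-p) on average
    flat <- matrix(rep(rlnorm(4, log(50), 0.1), each = 20), 20, 4,
                   dimnames = dimnames(counts))
    flat <- flat + matrix(rnorm(80, 0, 1e-3), 20, 4)
    scores <- vapply(1:30, function(i) {
        lab <- setNames(sample(labels), names(labels))
        clusterMixing(flat, lab)$mixingScore
    }, numeric(1))
    expect_gt(mean(scores), 0.35)
    expect_lt(abs(mean(scores) - 0.5), 0.12)
    expect_error(clusterMixing(counts, setNames(rep("one", 20),
                                                rownames(counts))),
                 "2 labels")
})

test_that("group-level comparison of commonest targets is null on identical data", {
    genes <- sprintf("g%02d", 1:30)
    tab <- data.frame(gene_id = genes, mean = rlnorm(30, log(20), 1),
                      sd = NA, cv = NA, log10_mean = NA, log10_cv = NA,
                      eligible = TRUE, rcv = rnorm(30, 0, 0.1))
    reports <- list(naive = data.frame(direction = "naive",
                                       gene_id = genes[1:10],
                                       targeting_frequency = 10:1,
                                       rank = 1:10),
                    primed = data.frame(direction = "primed",
                                        gene_id = genes[11:20],
                                        targeting_frequency = 10:1,
                                        rank = 1:10))
    out <- groupLevelComparison(reports,
        list(rpkm = list(naive = tab, primed = tab)))
    expect_true(all(out$tests$p_value == 1))
    expect_identical(nrow(out$tests), 4L)   # 2 directions x 2 metrics
    expect_identical(
        sort(unique(out$values$metric)), c("mean_rpkm", "rcv_rpkm"))
    expect_identical(nrow(out$values), 4L * 2L * 10L)
})

test_that("log-fold-change summary: zeros on identical tables, log2 on doubling", {
    genes <- c("ga", "gb", "gc")
    tab <- data.frame(gene_id = genes, mean = c(10, 20, 30), sd = NA,
                      cv = NA, log10_mean = NA, log10_cv = NA,
                      eligible = TRUE, rcv = c(0.1, -0.2, 0))
    same <- logFoldChangeSummary(tab, tab, flaggedGenes = genes)
    expect_equal(same$lfc_mean, rep(0, 3))
    expect_equal(same$noise_change, rep(0, 3))
    cent <- attr(same, "centroid")
    expect_equal(cent$lfc_mean, 0)
    expect_equal(cent$n, 3L)
    tab2 <- tab; tab2$mean[1] <- 20
    doubled <- logFoldChangeSummary(tab, tab2)
    expect_equal(doubled$lfc_mean[doubled$gene_id == "ga"], 1)
    expect_false(any(doubled$flagged))
    tabZ <- tab; tabZ$mean[2] <- 0
    withZero <- logFoldChangeSummary(tab, tabZ)
    expect_true(is.na(withZero$lfc_mean[2]))
    expect_error(logFoldChangeSummary(tab,
        data.frame(gene_id = "other", mean = 1, rcv = 0, eligible = TRUE)),
        "shared")
})
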