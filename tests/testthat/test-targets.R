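profileWithFractions <- function(fractions) {
    ids <- sprintf("miR-%02d", seq_along(fractions))
    lf <- matrix(log2(fractions), length(fractions), 1,
                 dimnames = list(ids, "c1"))
    new("MiRNAProfile", log2Fractions = lf,
        meanFraction = setNames(fractions, ids), floor = 1e-4)
}

test_that("target tables parse and de-duplicate across dialects", {
    two <- tempfile(); writeLines(c("miR-1\tGENE_A", "miR-1\tGENE_A",
                                    "miR-1\tGENE_B", "miR-2\tGENE_B"), two)
    tm <- readTargetMap(two, "two-column")
    expect_identical(sort(targetsOf(tm, "miR-1")), c("GENE_A", "GENE_B"))
    expect_identical(targetsOf(tm, "miR-2"), "GENE_B")

    ts <- tempfile()
    writeLines(c("miR Family\tGene Symbol\tSite Type",
                 "miR-17-5p/20/93\tCCND1\t8mer",
                 "miR-17-5p/20/93\tE2F1\t7mer",
                 "let-7/98\tHMGA2\t8mer",
                 "unknown-fam\tFOO\t8mer"), ts)
    fam <- list("miR-17-5p/20/93" = c("hsa-miR-17-5p", "hsa-miR-20a-5p"),
                "let-7/98" = "hsa-let-7a-5p")
    expect_message(tmTs <- readTargetMap(ts, "targetscan",
                                         familyMap = fam), "unmapped")
    expect_identical(sort(targetsOf(tmTs, "hsa-miR-20a-5p")),
                     c("CCND1", "E2F1"))
    expect_identical(targetsOf(tmTs, "hsa-let-7a-5p"), "HMGA2")
    expect_identical(targetSource(tmTs), "targetscan")

    db <- tempfile(); writeLines(c("hsa-miR-1\tNM_0001\t95.2",
                                   "hsa-miR-1\tNM_0002\t40.0"), db)
    expect_identical(targetsOf(readTargetMap(db, "mirdb",
                                             scoreThreshold = 60),
                               "hsa-miR-1"), "NM_0001")
    expect_identical(sort(targetsOf(readTargetMap(db, "mirdb"),
                                    "hsa-miR-1")),
                     c("NM_0001", "NM_0002"))

    mtb <- tempfile()
    writeLines(c("miRTarBase ID,miRNA,Target Gene",
                 "MIRT000001,hsa-miR-21-5p,PTEN"), mtb)
    expect_identical(targetsOf(readTargetMap(mtb, "mirtarbase"),
                               "hsa-miR-21-5p"), "PTEN")

    empty <- tempfile(); file.create(empty)
    expect_error(readTargetMap(empty, "two-column"))
})

test_that("expression grouping: equal-width log10 bins, low edge in, max on top", {
    p <- profileWithFractions(c(1e-4, 1e-3, 1e-2, 1e-1))
    part <- groupMiRNAsByExpression(p, 4)
    expect_identical(unname(groupAssignment(part)), 1:4)
    expect_equal(groupBoundaries(part),
                 seq(-4, -1, length.out = 5))
    # one group swallows everything
    expect_true(all(groupAssignment(
        groupMiRNAsByExpression(p, 1)) == 1L))
    # a value strictly inside a bin, and one exactly at the max
    p2 <- profileWithFractions(c(1e-4, 3e-4, 1e-3, 1e-2, 1e-1))
    a <- groupAssignment(groupMiRNAsByExpression(p2, 4))
    expect_identical(unname(a), c(1L, 1L, 2L, 3L, 4L))
    expect_error(groupMiRNAsByExpression(
        profileWithFractions(rep(0.01, 5))), "distinct")
    expect_error(groupMiRNAsByExpression(p, 4, boundaries = c(-3, -2, -1)),
                 "length")
    # explicit boundaries override the equal-width default
    part2 <- groupMiRNAsByExpression(p, 2, boundaries = c(-4, -3.5, -1))
    expect_identical(unname(groupAssignment(part2)), c(1L, 2L, 2L, 2L))
})

test_that("union target sets intersect the expressed universe", {
    tm <- TargetMap(c("miR-A", "miR-A", "miR-B", "miR-B"),
                    c("g1", "g2", "g2", "g3"))
    expect_setequal(unionTargets(c("miR-A", "miR-B"), tm,
                                 c("g1", "g2", "g3", "g4")),
                    c("g1", "g2", "g3"))
    expect_setequal(unionTargets(c("miR-A", "miR-B"), tm, c("g1", "g3")),
                    c("g1", "g3"))
    expect_warning(out <- unionTargets("miR-absent", tm, c("g1")),
                   "empty")
    expect_length(out, 0)
})

test_that("KS statistic equals the ECDF sup; asymptotic p in (0, 1]", {
    expect_equal(ksTwoSample(c(1, 2, 3), c(1, 2, 3))$d, 0)
    expect_equal(ksTwoSample(c(1, 2, 3), c(1, 2, 3))$p, 1)
    expect_equal(ksTwoSample(c(1, 2), c(10, 20))$d, 1)
    expect_equal(ksTwoSample(c(1, 3), c(2, 4))$d, 0.5)
    expect_equal(ksTwoSample(c(1, 3), c(2, 4))$d,
                 ksOracle(c(1, 3), c(2, 4)))
    expect_error(ksTwoSample(numeric(0), 1), "non-empty")
    set.seed(21)
    for (i in 1:25) {
        x <- round(runif(sample(1:8, 1), 0, 4), 1)
        y <- round(runif(sample(1:8, 1), 0, 4), 1)
        expect_equal(ksTwoSample(x, y)$d, ksOracle(x, y),
                     tolerance = 1e-12)
    }
})

test_that("pairwise group-noise comparison emits C(k,2) rows, symmetric by construction", {
    set.seed(33)
    genes <- sprintf("g%03d", 1:300)
    noise <- data.frame(gene_id = genes, mean = rlnorm(300),
                        sd = NA, cv = NA, log10_mean = NA, log10_cv = NA,
                        eligible = TRUE, rcv = rnorm(300, 0, 0.1))
    mirnas <- sprintf("miR-%02d", 1:20)
    tm <- TargetMap(rep(mirnas, each = 40),
                    unlist(lapply(1:20, function(i) sample(genes, 40))))
    part <- new("GroupPartition", nGroups = 4L,
                boundaries = c(-4, -3, -2, -1, 0),
                assignment = setNames(rep(1:4, each = 5L), mirnas))
    cmp <- compareGroupNoise(part, tm, noise)
    expect_identical(nrow(cmp), 6L)
    expect_true(all(cmp$d >= 0 & cmp$d <= 1))
    expect_true(all(cmp$p > 0 & cmp$p <= 1))
    expect_equal(cmp$neglog10p, -log10(cmp$p))
    samples <- attr(cmp, "samples")
    expect_length(samples, 4)
    expect_identical(lengths(samples)[c("group1", "group4")],
                     c(group1 = cmp$n_i[1], group4 = cmp$n_j[3]))
})

test_that("identical target sets give D = 0, p = 1; small groups are skipped", {
    genes <- sprintf("g%03d", 1:100)
    noise <- data.frame(gene_id = genes, mean = 1, sd = 1, cv = 1,
                        log10_mean = 0, log10_cv = 0, eligible = TRUE,
                        rcv = seq(-1, 1, length.out = 100))
    # both miRNAs target the same 50 genes; one tiny third group
    tm <- TargetMap(c(rep("miR-a", 50), rep("miR-b", 50), "miR-c"),
                    c(genes[1:50], genes[1:50], genes[60]))
    part <- new("GroupPartition", nGroups = 3L,
                boundaries = c(-3, -2, -1, 0),
                assignment = c("miR-a" = 1L, "miR-b" = 2L, "miR-c" = 3L))
    expect_warning(cmp <- compareGroupNoise(part, tm, noise), "skipped")
    expect_identical(nrow(cmp), 1L)      # only pair (1,2) survives
    expect_equal(cmp$d, 0)
    expect_equal(cmp$p, 1)
})

test_that("degree-preserving permutation of target labels destroys signal", {
    # planted effect: targets of miR-hi have shifted rcv; permuting the
    # gene labels of the map removes the association
    set.seed(44)
    genes <- sprintf("g%03d", 1:400)
    rcv <- rnorm(400, 0, 0.1)
    hiTargets <- sample(genes, 80)
    rcv[genes %in% hiTargets] <- rcv[genes %in% hiTargets] - 0.12
    noise <- data.frame(gene_id = genes, mean = 1, sd = 1, cv = 1,
                        log10_mean = 0, log10_cv = 0, eligible = TRUE,
                        rcv = rcv)
    loTargets <- sample(genes, 80)
    tm <- TargetMap(c(rep("miR-lo", 80), rep("miR-hi", 80)),
                    c(loTargets, hiTargets))
    part <- new("GroupPartition", nGroups = 2L,
                boundaries = c(-4, -2, 0),
                assignment = c("miR-lo" = 1L, "miR-hi" = 2L))
    planted <- compareGroupNoise(part, tm, noise)
    expect_lt(planted$p, 0.01)
    permPs <- vapply(1:20, function(i) {
        perm <- sample(genes)
        names(perm) <- genes
        tmP <- TargetMap(c(rep("miR-lo", 80), rep("miR-hi", 80)),
                         unname(perm[c(loTargets, hiTargets)]))
        compareGroupNoise(part, tmP, noise)$p
    }, numeric(1))
    expect_lte(mean(permPs < 0.05), 0.25)
})
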