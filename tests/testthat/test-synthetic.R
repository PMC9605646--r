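test_that("generators are pure functions of their seed", {
    a <- generateTargetMap(10, 2, 3, seed = 123)
    b <- generateTargetMap(10, 2, 3, seed = 123)
    expect_identical(a@entries, b@entries)
    expect_false(identical(a@entries,
                           generateTargetMap(10, 2, 3, seed = 124)@entries))
    p1 <- generateMiRNAProfiles(5, 4, seed = 9)
    p2 <- generateMiRNAProfiles(5, 4, seed = 9)
    expect_identical(p1, p2)
    b1 <- simulateNoiseExperiment(nGenes = 100, nCells = 10, nMiRNAs = 10,
                                  seed = 77)
    b2 <- simulateNoiseExperiment(nGenes = 100, nCells = 10, nMiRNAs = 10,
                                  seed = 77)
    expect_identical(exprValues(b1$mrna), exprValues(b2$mrna))
    expect_identical(b1$truth, b2$truth)
    g1 <- generateTwoGroupExperiment(nGenes = 100, nCellsPerGroup = 8,
                                     nMiRNAs = 10, nDE = 4, seed = 5)
    g2 <- generateTwoGroupExperiment(nGenes = 100, nCellsPerGroup = 8,
                                     nMiRNAs = 10, nDE = 4, seed = 5)
    expect_identical(exprValues(g1$mrna), exprValues(g2$mrna))
    expect_identical(g1$deSet, g2$deSet)
    # the generators leave the caller's RNG stream untouched
    set.seed(1); before <- runif(1)
    set.seed(1); invisible(simulateNoiseExperiment(nGenes = 50,
        nCells = 5, nMiRNAs = 5, seed = 3)); after <- runif(1)
    expect_identical(before, after)
})

test_that("target map edge cases: saturation and frequency balance", {
    full <- generateTargetMap(5, 3, 5, seed = 1)
    expect_true(all(lengths(full@entries) == 5))
    expect_identical(sort(targetsOf(full, "miR-001")),
                     sprintf("G%04d", 1:5))
    expect_error(generateTargetMap(5, 3, 6, seed = 1), "exceed")
    # expected per-gene frequency = nMiRNAs * targetsPerMiRNA / nGenes
    freqs <- rowMeans(vapply(1:40, function(s) {
        tm <- generateTargetMap(50, 10, 10, seed = s)
        tab <- table(factor(unlist(tm@entries),
                            levels = sprintf("G%04d", 1:50)))
        as.numeric(tab)
    }, numeric(50)))
    expect_equal(mean(freqs), 2, tolerance = 1e-12)  # exact in expectation
    expect_lt(max(abs(freqs - 2)), 0.75)
})

test_that("miRNA profiles span the planted gradient and are recoverable", {
    p <- generateMiRNAProfiles(50, 30, seed = 13)
    expect_equal(sum(p$trueFractions), 1, tolerance = 1e-12)
    expect_identical(colSums(p$counts),
                     setNames(rep(1e5, 30), colnames(p$counts)))
    prof <- normalizeMiRNA(p$counts)
    expect_gt(cor(meanFraction(prof), p$trueFractions,
                  method = "spearman"), 0.95)
    single <- generateMiRNAProfiles(1, 3, seed = 2)
    expect_true(all(single$counts == 1e5))
    expect_equal(unname(single$trueFractions), 1)
})

test_that("simulated counts are valid pipeline input and Poisson-limit correct", {
    b <- simulateNoiseExperiment(nGenes = 300, nCells = 15, nMiRNAs = 20,
                                 seed = 19)
    v <- exprValues(b$mrna)
    expect_true(all(v >= 0))
    expect_true(all(v == round(v)))      # integer counts, no RSEM warning
    expect_identical(expressionLayer(b$mrna), "raw-count")
    expect_identical(expressionLayer(b$denoisedTruth), "denoised")
    expect_identical(denoiseProvenance(b$denoisedTruth), "synthetic")
    expect_true(all(unlist(b$targetMap@entries) %in% rownames(b$mrna)))
    # no heterogeneity, no overdispersion, no dropout -> Poisson sampling:
    # realized CV approaches 1/sqrt(mu)
    pois <- simulateNoiseExperiment(nGenes = 400, nCells = 200,
                                    nMiRNAs = 10, seed = 23,
                                    noiseMultipliers = rep(1, 4),
                                    meanRepression = rep(1, 4),
                                    cvBio = 0, techDispersion = 0,
                                    dropout = FALSE, librarySdLog = 0)
    mu <- pois$truth$geneBaseMean
    cv <- apply(exprValues(pois$mrna), 1, sd) /
        rowMeans(exprValues(pois$mrna))
    big <- mu > 20 & mu < 2000
    expect_equal(median(cv[big] * sqrt(mu[big])), 1, tolerance = 0.1)
})

test_that("planted noise reduction is recovered from the denoised truth", {
    b <- simulateNoiseExperiment(nGenes = 1500, nCells = 30,
                                 nMiRNAs = 60, seed = 29,
                                 noiseMultipliers = c(1, 0.9, 0.8, 0.7))
    den <- rpkmNormalize(b$denoisedTruth, b$geneLengths)
    tab <- quietly(noiseTable(den, "cells"))
    rcv <- setNames(tab$rcv, tab$gene_id)
    stratum <- b$truth$geneStratum[tab$gene_id]
    hi <- rcv[stratum == 4]; none <- rcv[stratum == 0]
    mid <- rcv[stratum == 2]
    expect_lt(mean(hi, na.rm = TRUE), mean(none, na.rm = TRUE))
    expect_lt(mean(hi, na.rm = TRUE), mean(mid, na.rm = TRUE))
    expect_lt(mean(mid, na.rm = TRUE), mean(none, na.rm = TRUE))
})

test_that("two-group design: DE labels, fraction shifts, null downstream", {
    g <- generateTwoGroupExperiment(nGenes = 200, nCellsPerGroup = 10,
                                    nMiRNAs = 20, nDE = 8,
                                    deLog2Shift = 1.5, seed = 37)
    expect_identical(nrow(g$deSet), 8L)
    expect_setequal(unique(g$deSet$direction), c("naive", "primed"))
    expect_identical(sort(unique(cellGroups(g$mrna))),
                     c("naive", "primed"))
    expect_identical(ncol(g$mrna), 20L)
    # planted fraction shift: DE miRNAs are higher in their direction
    fr <- g$truth$mirnaTrueFractions
    for (i in seq_len(nrow(g$deSet))) {
        m <- g$deSet$mirna_id[i]; d <- g$deSet$direction[i]
        other <- setdiff(c("naive", "primed"), d)
        expect_gt(fr[[d]][m], fr[[other]][m])
    }
    expect_error(generateTwoGroupExperiment(nGenes = 50,
        nCellsPerGroup = 5, nMiRNAs = 5, nDE = 2, seed = 1,
        targetMeanFold = c("not-a-de-mirna" = 4)), "DE miRNA")
})

test_that("bundles round-trip through the flat-file dialects", {
    b <- generateTwoGroupExperiment(nGenes = 80, nCellsPerGroup = 6,
                                    nMiRNAs = 8, nDE = 4, seed = 41)
    dir <- tempfile(); writeSyntheticBundle(b, dir)
    back <- quietly(readExpressionMatrix(
        file.path(dir, "mrna_counts.tsv"), "tsv",
        groups = file.path(dir, "cell_groups.tsv")))
    expect_equal(exprValues(back), exprValues(b$mrna))
    expect_identical(unname(cellGroups(back)),
                     unname(cellGroups(b$mrna)))
    tm <- readTargetMap(file.path(dir, "target_map.tsv"), "two-column")
    expect_identical(lapply(tm@entries, sort),
                     lapply(b$targetMap@entries, sort))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"))
    expect_equal(truth$seed, 41)
})
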