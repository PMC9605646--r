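## All generators are pure functions of their parameters and seed: the
## global RNG state is saved and restored around every draw.
.withSeed <- function(seed, expr) {
    env <- globalenv()
    if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        old <- get(".Random.seed", envir = env, inherits = FALSE)
        on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = env)),
                add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

#' Simulate a sparse miRNA-target map
#'
#' Each miRNA receives `targetsPerMiRNA` target genes sampled uniformly
#' without replacement from the gene universe, independently across miRNAs.
#'
#' @param nGenes,nMiRNAs universe sizes.
#' @param targetsPerMiRNA targets per miRNA (at most `nGenes`).
#' @param seed RNG seed.
#' @param geneIds,mirnaIds optional id vectors (defaults `G0001...`,
#'   `miR-001...`).
#' @return A [TargetMap-class] with source `"synthetic"`.
#' @export
generateTargetMap <- function(nGenes, nMiRNAs, targetsPerMiRNA, seed,
                              geneIds = sprintf("G%04d", seq_len(nGenes)),
                              mirnaIds = sprintf("miR-%03d",
                                                 seq_len(nMiRNAs))) {
    if (targetsPerMiRNA > nGenes)
        stop("targetsPerMiRNA cannot exceed nGenes")
    if (targetsPerMiRNA < 1L) stop("targetsPerMiRNA must be >= 1")
    .withSeed(seed, {
        entries <- lapply(seq_len(nMiRNAs), function(i)
            sort(sample(geneIds, targetsPerMiRNA)))
        names(entries) <- mirnaIds
        methods::new("TargetMap", entries = entries, source = "synthetic")
    })
}

#' Simulate single-cell miRNA counts with a planted expression gradient
#'
#' Each miRNA gets a true expression fraction drawn log-uniformly over
#' `fractionRange` (spanning several orders of magnitude, as observed in
#' single-cell small-RNA data); fractions are renormalized to sum to 1.
#' Per cell, counts are multinomial over miRNAs with a fixed total.
#'
#' @param nMiRNAs,nCells dimensions.
#' @param fractionRange range of the log-uniform fraction draw.
#' @param totalCount total miRNA reads per cell (default 1e5).
#' @param seed RNG seed.
#' @param mirnaIds,cellIds optional id vectors.
#' @return A list with `counts` (miRNA x cell integer matrix) and
#'   `trueFractions` (named numeric summing to 1).
#' @export
generateMiRNAProfiles <- function(nMiRNAs, nCells,
                                  fractionRange = c(1e-4, 1e-1),
                                  totalCount = 1e5, seed,
                                  mirnaIds = sprintf("miR-%03d",
                                                     seq_len(nMiRNAs)),
                                  cellIds = sprintf("cell%02d",
                                                    seq_len(nCells))) {
    if (any(fractionRange <= 0) || any(fractionRange >= 1) ||
        diff(fractionRange) < 0)
        stop("fractionRange must be ascending within (0, 1)")
    .withSeed(seed, {
        raw <- 10^stats::runif(nMiRNAs, log10(fractionRange[1L]),
                               log10(fractionRange[2L]))
        frac <- stats::setNames(raw / sum(raw), mirnaIds)
        counts <- stats::rmultinom(nCells, size = totalCount, prob = frac)
        dimnames(counts) <- list(mirnaIds, cellIds)
        list(counts = counts, trueFractions = frac)
    })
}

.assignMiRNAGroups <- function(fractions, nGroups) {
    lf <- log10(fractions)
    b <- seq(min(lf), max(lf), length.out = nGroups + 1L)
    findInterval(lf, b, rightmost.closed = TRUE)
}

#' Simulate a single-group single-cell mRNA experiment with planted
#' miRNA noise effects
#'
#' Generates a gene x cell raw-count matrix with the statistical structure
#' of read-based scRNA-seq: log-normal gene base means, per-cell library
#' size factors, per-gene-per-cell log-normal biological heterogeneity,
#' negative-binomial technical overdispersion, and logistic dropout (the
#' probability of a false zero decreases with log expression). miRNA
#' regulation is planted through the target map: each gene's biological CV
#' is multiplied by the `noiseMultipliers` entry of the highest-expression
#' miRNA group targeting it (1 = no effect), and its mean optionally scaled
#' by `meanRepression` of the same group. The pre-dropout, pre-sampling
#' expression surface (the negative-binomial means) is returned as the
#' ground-truth "denoised" layer.
#'
#' @param nGenes,nCells,nMiRNAs,targetsPerMiRNA scenario dimensions
#'   (defaults: 2000 genes, 30 cells, 100 miRNAs, 30 targets each).
#' @param seed RNG seed.
#' @param nMiRNAGroups expression strata used for planting (default 4).
#' @param noiseMultipliers per-stratum biological-CV multipliers in (0, 1],
#'   lowest stratum first (default `c(1, 0.9, 0.8, 0.7)`: targets of more
#'   abundant miRNAs are quieter).
#' @param meanRepression per-stratum mean fold (default
#'   `c(1, 1, 1, 0.8)`: modest repression of top-stratum targets).
#' @param cvBio baseline biological coefficient of variation (default
#'   0.55).
#' @param cvBioSdLog log-normal sd of the gene-intrinsic biological CV
#'   around `cvBio` (default 0.15): genes differ persistently in how noisy
#'   they are.
#' @param techDispersion negative-binomial technical dispersion (default
#'   0.2; 0 = Poisson sampling).
#' @param dropout enable logistic dropout (default `TRUE`).
#' @param dropoutMidpoint,dropoutSlope dropout curve on the natural-log
#'   mean scale: `P(false zero) = plogis(dropoutSlope * (dropoutMidpoint -
#'   log(mu)))` (defaults 0 and 1: ~50% dropout at mean 1).
#' @param baseMeanLog,baseMeanSdLog log-normal parameters of gene base
#'   means (defaults `log(20)` and 1.5).
#' @param librarySdLog log-normal sd of cell library-size factors (default
#'   0.2).
#' @param fractionRange,totalMiRNACount passed to
#'   [generateMiRNAProfiles()].
#' @param group cell-group label (default `"cells"`).
#'
#' @return A list (synthetic bundle) with elements `mrna` (raw-count
#'   [ExpressionMatrix-class]), `denoisedTruth` (the NB means, layer
#'   `"denoised"`, provenance `"synthetic"`), `mirnaCounts`,
#'   `targetMap`, `geneLengths` (named, base pairs), and `truth` (all
#'   planted parameters, per-gene multipliers, true miRNA fractions and
#'   strata, and the seed).
#' @export
simulateNoiseExperiment <- function(nGenes = 2000L, nCells = 30L,
                                    nMiRNAs = 100L, targetsPerMiRNA = 30L,
                                    seed = 1L, nMiRNAGroups = 4L,
                                    noiseMultipliers = c(1, 0.9, 0.8, 0.7),
                                    meanRepression = c(1, 1, 1, 0.8),
                                    cvBio = 0.55, cvBioSdLog = 0.15,
                                    techDispersion = 0.2,
                                    dropout = TRUE, dropoutMidpoint = 0,
                                    dropoutSlope = 1,
                                    baseMeanLog = log(20),
                                    baseMeanSdLog = 1.5,
                                    librarySdLog = 0.2,
                                    fractionRange = c(1e-4, 1e-1),
                                    totalMiRNACount = 1e5,
                                    group = "cells") {
    stopifnot(length(noiseMultipliers) == nMiRNAGroups,
              length(meanRepression) == nMiRNAGroups,
              all(noiseMultipliers > 0), all(noiseMultipliers <= 1))
    geneIds <- sprintf("G%04d", seq_len(nGenes))
    cellIds <- sprintf("cell%02d", seq_len(nCells))
    tm <- generateTargetMap(nGenes, nMiRNAs, targetsPerMiRNA,
                            seed = seed + 1L, geneIds = geneIds)
    mir <- generateMiRNAProfiles(nMiRNAs, nCells,
                                 fractionRange = fractionRange,
                                 totalCount = totalMiRNACount,
                                 seed = seed + 2L, cellIds = cellIds)
    mirGroups <- .assignMiRNAGroups(mir$trueFractions, nMiRNAGroups)
    geneStratum <- .geneStratum(tm, geneIds, mirGroups)
    mult <- ifelse(geneStratum > 0, noiseMultipliers[pmax(geneStratum, 1L)],
                   1)
    repr <- ifelse(geneStratum > 0, meanRepression[pmax(geneStratum, 1L)],
                   1)
    sim <- .simulateCounts(geneIds, cellIds, mult, repr, seed + 3L,
                           cvBio, cvBioSdLog, techDispersion, dropout,
                           dropoutMidpoint, dropoutSlope,
                           baseMeanLog, baseMeanSdLog, librarySdLog,
                           group = group)
    truth <- list(seed = seed, nGenes = nGenes, nCells = nCells,
                  nMiRNAs = nMiRNAs, targetsPerMiRNA = targetsPerMiRNA,
                  noiseMultipliers = noiseMultipliers,
                  meanRepression = meanRepression,
                  cvBio = cvBio, cvBioSdLog = cvBioSdLog,
                  techDispersion = techDispersion,
                  dropout = dropout, dropoutMidpoint = dropoutMidpoint,
                  dropoutSlope = dropoutSlope,
                  baseMeanLog = baseMeanLog, baseMeanSdLog = baseMeanSdLog,
                  librarySdLog = librarySdLog,
                  geneBaseMean = sim$baseMean,
                  geneBaseCV = sim$baseCV,
                  libraryFactor = sim$libFactor,
                  geneNoiseMultiplier = stats::setNames(mult, geneIds),
                  geneMeanRepression = stats::setNames(repr, geneIds),
                  geneStratum = stats::setNames(geneStratum, geneIds),
                  mirnaTrueFractions = mir$trueFractions,
                  mirnaStratum = stats::setNames(mirGroups,
                                                 names(mir$trueFractions)))
    list(mrna = sim$raw, denoisedTruth = sim$denoised,
         mirnaCounts = mir$counts, targetMap = tm,
         geneLengths = sim$lengths, truth = truth)
}

## stratum 0 = untargeted; otherwise the highest-expression miRNA stratum
## among the gene's regulators
.geneStratum <- function(tm, geneIds, mirGroups) {
    stratum <- stats::setNames(integer(length(geneIds)), geneIds)
    entries <- tm@entries
    for (i in seq_along(entries)) {
        g <- entries[[i]]
        stratum[g] <- pmax(stratum[g], mirGroups[i])
    }
    unname(stratum[geneIds])
}

.simulateCounts <- function(geneIds, cellIds, mult, repr, seed,
                            cvBio, cvBioSdLog, techDispersion, dropout,
                            dropoutMidpoint, dropoutSlope,
                            baseMeanLog, baseMeanSdLog, librarySdLog,
                            group, baseMean = NULL, lengths = NULL,
                            baseCV = NULL) {
    nGenes <- length(geneIds); nCells <- length(cellIds)
    .withSeed(seed, {
        if (is.null(baseMean))
            baseMean <- stats::setNames(
                stats::rlnorm(nGenes, baseMeanLog, baseMeanSdLog), geneIds)
        if (is.null(lengths))
            lengths <- stats::setNames(
                as.integer(round(stats::runif(nGenes, 500, 5000))), geneIds)
        # gene-intrinsic noise level: genes differ persistently in their
        # biological CV (log-normal around cvBio)
        if (is.null(baseCV))
            baseCV <- stats::setNames(
                cvBio * stats::rlnorm(nGenes, 0, cvBioSdLog), geneIds)
        libFactor <- stats::setNames(stats::rlnorm(nCells, 0, librarySdLog),
                                     cellIds)
        # biological heterogeneity: per gene-cell log-normal with CV
        # = gene's intrinsic CV * planted multiplier, mean 1
        cvG <- unname(baseCV) * mult
        sdlog <- sqrt(log1p(cvG^2))
        eps <- matrix(stats::rlnorm(nGenes * nCells,
                                    meanlog = rep(-sdlog^2 / 2, nCells),
                                    sdlog = rep(sdlog, nCells)),
                      nGenes, nCells)
        mu <- (baseMean * repr) %o% libFactor * eps
        counts <- if (techDispersion > 0) {
            matrix(stats::rnbinom(nGenes * nCells, mu = mu,
                                  size = 1 / techDispersion),
                   nGenes, nCells)
        } else {
            matrix(stats::rpois(nGenes * nCells, lambda = mu),
                   nGenes, nCells)
        }
        if (dropout) {
            pDrop <- stats::plogis(dropoutSlope * (dropoutMidpoint -
                                                   log(mu)))
            counts[stats::runif(nGenes * nCells) < pDrop] <- 0L
        }
        dimnames(counts) <- list(geneIds, cellIds)
        dimnames(mu) <- list(geneIds, cellIds)
        grp <- stats::setNames(rep(group, nCells), cellIds)
        list(raw = ExpressionMatrix(counts, groups = grp,
                                    layer = "raw-count"),
             denoised = ExpressionMatrix(mu, groups = grp,
                                         layer = "denoised",
                                         provenance = "synthetic"),
             baseMean = baseMean, libFactor = libFactor,
             lengths = lengths, baseCV = baseCV)
    })
}

#' Simulate a two-cell-group experiment with differentially expressed
#' miRNAs
#'
#' Emulates a naive/primed-style design: two cell groups share the same
#' genes, target map and gene base means; a chosen subset of miRNAs is
#' differentially expressed (their fractions shifted by `deLog2Shift` in
#' their higher-expression group), yielding a labelled DE set. By default
#' the DE miRNAs have no planted downstream effect on their target mRNAs
#' (the null that the differential pathway should report as such);
#' `targetMeanFold` plants a mean fold change on selected miRNAs' targets
#' in that miRNA's higher group.
#'
#' @param nGenes,nCellsPerGroup,nMiRNAs,targetsPerMiRNA scenario
#'   dimensions (defaults 2000, 30, 100, 30).
#' @param nDE number of differentially expressed miRNAs (default 40),
#'   split evenly between directions.
#' @param deLog2Shift log2 shift of DE miRNA fractions (default 1).
#' @param targetMeanFold named numeric, miRNA id -> fold applied to its
#'   targets' base means in the miRNA's higher-expression group (default
#'   none: null experiment).
#' @param groups the two group labels (default `c("naive", "primed")`).
#' @param seed RNG seed.
#' @inheritParams simulateNoiseExperiment
#' @return A bundle as in [simulateNoiseExperiment()] but with `mrna` and
#'   `denoisedTruth` spanning both groups, `mirnaCounts` a list per group,
#'   and additional elements `deSet` (data.frame `mirna_id`, `direction`)
#'   and per-group true fractions in `truth`.
#' @export
generateTwoGroupExperiment <- function(nGenes = 2000L,
                                       nCellsPerGroup = 30L,
                                       nMiRNAs = 100L,
                                       targetsPerMiRNA = 30L,
                                       nDE = 40L, deLog2Shift = 1,
                                       targetMeanFold = numeric(),
                                       groups = c("naive", "primed"),
                                       seed = 1L,
                                       cvBio = 0.55, cvBioSdLog = 0.15,
                                       techDispersion = 0.2,
                                       dropout = TRUE,
                                       dropoutMidpoint = 0,
                                       dropoutSlope = 1,
                                       baseMeanLog = log(20),
                                       baseMeanSdLog = 1.5,
                                       librarySdLog = 0.2,
                                       fractionRange = c(1e-4, 1e-1),
                                       totalMiRNACount = 1e5) {
    stopifnot(length(groups) == 2L, nDE <= nMiRNAs)
    geneIds <- sprintf("G%04d", seq_len(nGenes))
    mirnaIds <- sprintf("miR-%03d", seq_len(nMiRNAs))
    tm <- generateTargetMap(nGenes, nMiRNAs, targetsPerMiRNA,
                            seed = seed + 1L, geneIds = geneIds,
                            mirnaIds = mirnaIds)
    shared <- .withSeed(seed + 2L, {
        raw <- 10^stats::runif(nMiRNAs, log10(fractionRange[1L]),
                               log10(fractionRange[2L]))
        baseFrac <- stats::setNames(raw / sum(raw), mirnaIds)
        de <- sample(mirnaIds, nDE)
        direction <- stats::setNames(
            rep(groups, length.out = nDE)[sample.int(nDE)], de)
        baseMean <- stats::setNames(
            stats::rlnorm(nGenes, baseMeanLog, baseMeanSdLog), geneIds)
        lengths <- stats::setNames(
            as.integer(round(stats::runif(nGenes, 500, 5000))), geneIds)
        baseCV <- stats::setNames(
            cvBio * stats::rlnorm(nGenes, 0, cvBioSdLog), geneIds)
        list(baseFrac = baseFrac, de = de, direction = direction,
             baseMean = baseMean, lengths = lengths, baseCV = baseCV)
    })
    if (length(targetMeanFold) &&
        !all(names(targetMeanFold) %in% shared$de))
        stop("targetMeanFold names must be DE miRNA ids")
    mult <- rep(1, nGenes)  # no planted noise effect in this design
    fracByGroup <- list(); rawList <- list(); denList <- list()
    mirnaCounts <- list(); trueFracs <- list()
    for (gi in 1:2) {
        g <- groups[gi]
        frac <- shared$baseFrac
        up <- names(shared$direction)[shared$direction == g]
        frac[up] <- frac[up] * 2^deLog2Shift
        frac <- frac / sum(frac)
        trueFracs[[g]] <- frac
        mirnaCounts[[g]] <- .withSeed(seed + 10L + gi, {
            cnt <- stats::rmultinom(nCellsPerGroup,
                                    size = totalMiRNACount, prob = frac)
            dimnames(cnt) <- list(mirnaIds,
                                  sprintf("%s_cell%02d", g,
                                          seq_len(nCellsPerGroup)))
            cnt
        })
        repr <- stats::setNames(rep(1, nGenes), geneIds)
        for (m in names(targetMeanFold)) {
            if (shared$direction[[m]] == g)
                repr[targetsOf(tm, m)] <- repr[targetsOf(tm, m)] *
                    targetMeanFold[[m]]
        }
        cellIds <- sprintf("%s_cell%02d", g, seq_len(nCellsPerGroup))
        sim <- .simulateCounts(geneIds, cellIds, mult, unname(repr),
                               seed + 20L + gi, cvBio, cvBioSdLog,
                               techDispersion,
                               dropout, dropoutMidpoint, dropoutSlope,
                               baseMeanLog, baseMeanSdLog, librarySdLog,
                               group = g, baseMean = shared$baseMean,
                               lengths = shared$lengths,
                               baseCV = shared$baseCV)
        rawList[[g]] <- sim$raw; denList[[g]] <- sim$denoised
    }
    combine <- function(a, b, layer, provenance = NULL) {
        v <- cbind(exprValues(a), exprValues(b))
        ExpressionMatrix(v, groups = c(cellGroups(a), cellGroups(b)),
                         layer = layer, provenance = provenance)
    }
    deSet <- data.frame(mirna_id = shared$de,
                        direction = unname(shared$direction[shared$de]),
                        stringsAsFactors = FALSE)
    truth <- list(seed = seed, nGenes = nGenes,
                  nCellsPerGroup = nCellsPerGroup, nMiRNAs = nMiRNAs,
                  targetsPerMiRNA = targetsPerMiRNA, nDE = nDE,
                  deLog2Shift = deLog2Shift,
                  targetMeanFold = targetMeanFold,
                  geneBaseMean = shared$baseMean,
                  geneBaseCV = shared$baseCV,
                  mirnaTrueFractions = trueFracs,
                  groups = groups)
    list(mrna = combine(rawList[[1L]], rawList[[2L]], "raw-count"),
         denoisedTruth = combine(denList[[1L]], denList[[2L]], "denoised",
                                 provenance = "synthetic"),
         mirnaCounts = mirnaCounts, targetMap = tm,
         geneLengths = shared$lengths, deSet = deSet, truth = truth)
}

#' Write a synthetic bundle to disk in the pipeline's input dialects
#'
#' Serializes a bundle from [simulateNoiseExperiment()] or
#' [generateTwoGroupExperiment()] as the flat files the ingest functions
#' read: TSV matrices, a two-column target table, a two-column group
#' assignment, a gene-length table, a DE-miRNA table when present, and the
#' ground truth as JSON.
#'
#' @param bundle a synthetic bundle.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSyntheticBundle <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeMat <- function(m, path) {
        df <- data.frame(id = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    writeMat(exprValues(bundle$mrna), file.path(dir, "mrna_counts.tsv"))
    writeMat(exprValues(bundle$denoisedTruth),
             file.path(dir, "denoised.tsv"))
    mc <- bundle$mirnaCounts
    if (is.list(mc)) mc <- do.call(cbind, mc)
    writeMat(mc, file.path(dir, "mirna_counts.tsv"))
    grp <- cellGroups(bundle$mrna)
    utils::write.table(data.frame(cell_id = names(grp), group = grp),
                       file.path(dir, "cell_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    entries <- bundle$targetMap@entries
    utils::write.table(
        data.frame(mirna = rep(names(entries), lengths(entries)),
                   gene = unlist(entries, use.names = FALSE)),
        file.path(dir, "target_map.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    utils::write.table(
        data.frame(gene_id = names(bundle$geneLengths),
                   effective_length = unname(bundle$geneLengths)),
        file.path(dir, "gene_lengths.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (!is.null(bundle$deSet))
        utils::write.table(bundle$deSet, file.path(dir, "de_mirnas.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
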