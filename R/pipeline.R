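.CONFIG_KEYS <- c(
    "simulate", "two_group",
    "mrna_path", "mrna_dialect", "groups", "groups_path",
    "mirna_path", "lengths_path", "target_path", "target_source",
    "de_path",
    "mirna_floor", "min_library_size", "min_cells_expressed",
    "per_group", "n_groups", "k_common_targets",
    "denoise_provenance", "denoise_path",
    "seed", "out")

#' Validate a pipeline run configuration
#'
#' Accepts a named list or the path to a YAML file and checks it against
#' the known configuration keys (unknown keys are rejected) before any
#' computation. Either `simulate` (a list of simulator arguments;
#' `two_group: yes` selects the two-group design) or the input paths
#' (`mrna_path`, `mirna_path`, `lengths_path`, `target_path`, plus
#' `groups`/`groups_path`) must be supplied.
#'
#' @param config named list or YAML path.
#' @return The validated config with defaults filled in.
#' @export
runConfig <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a list or a YAML path")
    unknown <- setdiff(names(config), .CONFIG_KEYS)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    defaults <- list(mirna_floor = 1e-4, min_library_size = 1e5,
                     min_cells_expressed = 5L, per_group = TRUE,
                     n_groups = 4L, k_common_targets = 100L,
                     denoise_provenance = "passthrough",
                     two_group = FALSE, seed = 1L, out = NULL,
                     mrna_dialect = "tsv", target_source = "two-column")
    for (k in names(defaults))
        if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
    if (is.null(config$simulate) && is.null(config$mrna_path))
        stop("config needs either 'simulate' or input paths")
    config
}

.configHash <- function(config) {
    config <- config[setdiff(names(config), "out")]  # hash the science only
    s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                          digits = NA, force = TRUE)
    sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %%
                .Machine$integer.max)
}

.writeArtifact <- function(df, path, config) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# miRNoise %s | config %s",
                       as.character(utils::packageVersion("miRNoise")),
                       .configHash(config)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.acquireInputs <- function(config) {
    if (!is.null(config$simulate)) {
        args <- config$simulate
        if (isTRUE(config$two_group)) {
            args$seed <- config$seed
            bundle <- do.call(generateTwoGroupExperiment, args)
        } else {
            args$seed <- config$seed
            bundle <- do.call(simulateNoiseExperiment, args)
        }
        return(bundle)
    }
    groups <- if (!is.null(config$groups_path))
        readGroupAssignment(config$groups_path) else config$groups
    raw <- readExpressionMatrix(config$mrna_path,
                                dialect = config$mrna_dialect,
                                groups = groups)
    lengths <- utils::read.delim(config$lengths_path,
                                 stringsAsFactors = FALSE)
    mirna <- as.matrix(utils::read.delim(config$mirna_path, row.names = 1L,
                                         check.names = FALSE))
    tm <- readTargetMap(config$target_path, source = config$target_source)
    deSet <- if (!is.null(config$de_path))
        utils::read.delim(config$de_path, stringsAsFactors = FALSE)
    list(mrna = raw,
         geneLengths = stats::setNames(lengths$effective_length,
                                       lengths$gene_id),
         mirnaCounts = mirna, targetMap = tm, deSet = deSet,
         denoisedTruth = NULL)
}

.denoisedLayer <- function(config, raw, bundle) {
    prov <- config$denoise_provenance
    if (prov == "passthrough") return(passthroughDenoise(raw))
    if (prov == "synthetic") {
        if (is.null(bundle$denoisedTruth))
            stop("denoise_provenance 'synthetic' needs a simulated bundle")
        den <- bundle$denoisedTruth
        return(den[rownames(raw), colnames(raw)])
    }
    if (is.null(config$denoise_path))
        stop("denoise_provenance '", prov, "' needs denoise_path")
    loadDenoised(config$denoise_path, raw, provenance = prov)
}

#' Run the expression-noise pathway
#'
#' End-to-end orchestration of the miRNA expression-stratification
#' analysis: ingest (or simulate) the matrices, filter cells by library
#' size and genes by prevalence, normalize to RPKM, bring in the denoised
#' layer and normalize it identically, compute per-group noise tables with
#' RCV on both layers, stratify miRNAs by mean expression fraction, and
#' compare the RCV distributions of union target sets between every pair
#' of strata with KS tests. When `out` is set, all artifacts (noise
#' tables, fits, KS matrices, CDF samples, run log) are written there.
#'
#' @param config a config list or YAML path (see [runConfig()]).
#' @return Invisibly, a list with `noiseTables` (layer -> group -> table),
#'   `fits`, `ksMatrices` (layer -> group -> data.frame with attached CDF
#'   samples), `partition`, `profile`, and the filtered matrices.
#' @export
runNoisePathway <- function(config) {
    config <- runConfig(config)
    bundle <- .acquireInputs(config)
    rawCells <- filterCellsByLibrarySize(bundle$mrna,
                                         config$min_library_size)
    raw <- filterGenesByPrevalence(rawCells, config$min_cells_expressed,
                                   perGroup = config$per_group)
    # library size (the RPKM denominator) is the column total over all
    # genes present before the prevalence filter; normalize first, then
    # subset to the retained genes
    denoised <- .denoisedLayer(config, rawCells, bundle)
    rpkm <- rpkmNormalize(rawCells, bundle$geneLengths)[rownames(raw), ]
    denNorm <- rpkmNormalize(denoised, bundle$geneLengths)
    denNorm <- denNorm[intersect(rownames(raw), rownames(denNorm)), ]
    mirnaCounts <- bundle$mirnaCounts
    if (is.list(mirnaCounts)) mirnaCounts <- do.call(cbind, mirnaCounts)
    profile <- normalizeMiRNA(mirnaCounts, floor = config$mirna_floor)
    partition <- groupMiRNAsByExpression(profile,
                                         nGroups = config$n_groups)
    layers <- list(rpkm = rpkm, denoised = denNorm)
    groupsPresent <- unique(cellGroups(raw))
    noiseTables <- list(); fits <- list(); ksMatrices <- list()
    for (ln in names(layers)) {
        noiseTables[[ln]] <- list(); ksMatrices[[ln]] <- list()
        for (g in groupsPresent) {
            tab <- noiseTable(layers[[ln]], g)
            noiseTables[[ln]][[g]] <- tab
            fits[[paste(ln, g, sep = ".")]] <- attr(tab, "fit")
            ksMatrices[[ln]][[g]] <- compareGroupNoise(
                partition, bundle$targetMap, tab)
        }
    }
    res <- list(noiseTables = noiseTables, fits = fits,
                ksMatrices = ksMatrices, partition = partition,
                profile = profile, raw = raw, rpkm = rpkm,
                denoisedNormalized = denNorm, bundle = bundle,
                config = config)
    if (!is.null(config$out)) .writeNoiseArtifacts(res, config)
    invisible(res)
}

.writeNoiseArtifacts <- function(res, config) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    logLines <- c(sprintf("miRNoise %s",
                          as.character(utils::packageVersion("miRNoise"))),
                  sprintf("seed: %s", config$seed),
                  sprintf("config hash: %s", .configHash(config)),
                  sprintf("genes x cells after filters: %d x %d",
                          nrow(res$raw), ncol(res$raw)))
    ksAll <- list(); cdfAll <- list()
    for (ln in names(res$noiseTables)) {
        for (g in names(res$noiseTables[[ln]])) {
            tab <- res$noiseTables[[ln]][[g]]
            writeNoiseTable(tab, file.path(config$out,
                sprintf("noise_%s_%s.tsv", ln, g)))
            km <- res$ksMatrices[[ln]][[g]]
            if (nrow(km)) {
                km$layer <- ln; km$group <- g
                ksAll[[length(ksAll) + 1L]] <- km
            }
            samples <- attr(km, "samples")
            for (sg in names(samples)) {
                v <- samples[[sg]]
                if (length(v))
                    cdfAll[[length(cdfAll) + 1L]] <- data.frame(
                        layer = ln, group = g, mirna_group = sg, rcv = v)
            }
            fit <- attr(tab, "fit")
            logLines <- c(logLines, sprintf(
                "fit %s/%s: slope %.4f intercept %.4f n %d R2 %.3f",
                ln, g, fit@slope, fit@intercept, fit@nGenesUsed,
                fit@rSquared))
        }
    }
    fitJson <- lapply(res$fits, function(f)
        list(slope = f@slope, intercept = f@intercept,
             n_genes_used = f@nGenesUsed, r_squared = f@rSquared))
    jsonlite::write_json(fitJson, file.path(config$out, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    if (length(ksAll))
        .writeArtifact(do.call(rbind, ksAll),
                       file.path(config$out, "ks_matrix.tsv"), config)
    if (length(cdfAll))
        .writeArtifact(do.call(rbind, cdfAll),
                       file.path(config$out, "cdf_samples.tsv"), config)
    writeLines(logLines, file.path(config$out, "run_log.txt"))
}

#' Run the differential-miRNA pathway
#'
#' Orchestrates the two-cell-group analysis of differentially expressed
#' miRNAs: per-miRNA t-tests of target mean expression and noise with
#' per-metric Benjamini-Hochberg correction, combinatorial targeting
#' frequencies and commonest-target selection per direction,
#' hierarchical-clustering mixing of the two commonest-target sets,
#' group-level comparisons, and the log-fold-change summary with the
#' commonest targets flagged.
#'
#' @param config a config list or YAML path (see [runConfig()]); the input
#'   must contain exactly two cell groups and a DE miRNA table (from
#'   `de_path`, or the simulated DE set of the two-group design selected
#'   with `two_group: yes`).
#' @return Invisibly, a list with `differential` (per-miRNA results),
#'   `commonTargets`, `mixing`, `groupComparison`, `lfc` (per layer), and
#'   the underlying noise pathway results.
#' @export
runDifferentialPathway <- function(config) {
    config <- runConfig(config)
    noise <- runNoisePathway(config)
    raw <- noise$raw
    groupsPresent <- unique(cellGroups(raw))
    if (length(groupsPresent) != 2L)
        stop("differential pathway needs exactly 2 cell groups; have ",
             length(groupsPresent))
    deSet <- noise$bundle$deSet
    if (is.null(deSet)) stop("no DE miRNA table available")
    tm <- noise$bundle$targetMap
    noiseTables <- lapply(noise$noiseTables, function(byGroup)
        byGroup[groupsPresent])
    differential <- perMiRNAComparison(deSet, tm, noiseTables)
    expressed <- rownames(raw)
    # overall mean expression (both groups) for deterministic tie-breaks
    tabA <- noise$noiseTables$rpkm[[1L]]
    tabB <- noise$noiseTables$rpkm[[2L]]
    meanExpr <- stats::setNames(
        (tabA$mean + tabB$mean[match(tabA$gene_id, tabB$gene_id)]) / 2,
        tabA$gene_id)
    reports <- list()
    for (dir in groupsPresent) {
        mirs <- deSet$mirna_id[deSet$direction == dir]
        freq <- targetingFrequency(mirs, tm, expressed)
        reports[[dir]] <- topCommonTargets(freq,
                                           k = config$k_common_targets,
                                           meanExpr = meanExpr,
                                           direction = dir)
    }
    commonTargets <- do.call(rbind, reports)
    labels <- stats::setNames(commonTargets$direction,
                              commonTargets$gene_id)
    labels <- labels[!duplicated(names(labels))]
    # genes in both directions' top sets keep their first label
    mixing <- clusterMixing(exprValues(raw)[names(labels), , drop = FALSE],
                            labels)
    groupComparison <- groupLevelComparison(reports, noiseTables)
    lfc <- lapply(noiseTables, function(pair)
        logFoldChangeSummary(pair[[1L]], pair[[2L]],
                             flaggedGenes = unique(commonTargets$gene_id)))
    res <- list(differential = differential,
                commonTargets = commonTargets, mixing = mixing,
                groupComparison = groupComparison, lfc = lfc,
                noise = noise, config = config)
    if (!is.null(config$out)) {
        dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
        .writeArtifact(differential,
                       file.path(config$out, "differential_results.tsv"),
                       config)
        .writeArtifact(commonTargets,
                       file.path(config$out, "common_targets.tsv"), config)
        .writeArtifact(groupComparison$tests,
                       file.path(config$out, "group_comparison.tsv"),
                       config)
        lfcLong <- do.call(rbind, lapply(names(lfc), function(ln) {
            d <- lfc[[ln]]; d$layer <- ln; d
        }))
        .writeArtifact(lfcLong, file.path(config$out, "lfc_summary.tsv"),
                       config)
        jsonlite::write_json(
            list(mixing_score = mixing$mixingScore,
                 expected_mixing = mixing$expectedMixing,
                 leaf_order = mixing$leafOrder),
            file.path(config$out, "mixing_report.json"),
            auto_unbox = TRUE, digits = NA)
    }
    invisible(res)
}
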