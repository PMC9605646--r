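#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats lm coef var sd p.adjust ks.test t.test rlnorm rnbinom
#'   rpois rmultinom runif rbinom plogis hclust dist as.dendrogram
#'   order.dendrogram setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

.LAYERS <- c("raw-count", "rpkm", "denoised", "denoised-normalized")
.TARGET_SOURCES <- c("targetscan", "mirdb", "mirtarbase", "synthetic",
                     "two-column")

#' Gene-by-cell expression matrix with layer tag and cell groups
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single gene x cell assay (`"values"`), a per-cell group label in
#' `colData(x)$group`, and a layer tag in `metadata(x)$layer` recording what
#' the values are: `"raw-count"` (read counts, possibly fractional when they
#' are expected counts from an EM quantifier), `"rpkm"` (length- and
#' depth-normalized), `"denoised"` (output of an external denoiser), or
#' `"denoised-normalized"` (denoised counts normalized like RPKM).
#'
#' @slot .  Inherits all slots from `SummarizedExperiment`.
#'
#' @seealso [ExpressionMatrix()] for construction,
#'   [filterCellsByLibrarySize()], [filterGenesByPrevalence()],
#'   [rpkmNormalize()].
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    md <- S4Vectors::metadata(object)
    if (is.null(md$layer) || length(md$layer) != 1L ||
        !md$layer %in% .LAYERS) {
        msg <- c(msg, sprintf("metadata()$layer must be one of %s",
                              paste(.LAYERS, collapse = ", ")))
    }
    if (!"values" %in% SummarizedExperiment::assayNames(object)) {
        msg <- c(msg, "assay 'values' is required")
    } else {
        v <- SummarizedExperiment::assay(object, "values")
        if (anyNA(v)) msg <- c(msg, "values contain NA")
        else if (any(v < 0)) msg <- c(msg, "values contain negatives")
    }
    rn <- rownames(object); cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "cell ids must be present and unique")
    grp <- SummarizedExperiment::colData(object)$group
    if (is.null(grp) || anyNA(grp) || any(!nzchar(grp)))
        msg <- c(msg, "every cell needs a non-empty group label")
    if (length(msg)) msg else TRUE
})

#' Per-cell miRNA expression profile on the log2 fraction scale
#'
#' Holds the miRNA x cell matrix of log2 expression fractions (each miRNA's
#' read count divided by the cell's total miRNA count, floored at a minimum
#' fraction before the log), together with the per-miRNA mean fraction used
#' to stratify miRNAs by expression level.
#'
#' @slot log2Fractions miRNA x cell numeric matrix of log2(floored fraction).
#' @slot meanFraction named numeric, across-cell mean of the post-floor,
#'   pre-log fractions; in (0, 1].
#' @slot floor positive scalar, the minimum fraction (default 1e-4).
#'
#' @seealso [normalizeMiRNA()], [groupMiRNAsByExpression()]
#' @export
setClass("MiRNAProfile",
    representation(log2Fractions = "matrix",
                   meanFraction  = "numeric",
                   floor         = "numeric"))

setValidity("MiRNAProfile", function(object) {
    msg <- character()
    lf <- object@log2Fractions
    fl <- object@floor
    if (length(fl) != 1L || !is.finite(fl) || fl <= 0 || fl > 1)
        msg <- c(msg, "floor must be a scalar in (0, 1]")
    if (is.null(rownames(lf)) || anyDuplicated(rownames(lf)))
        msg <- c(msg, "miRNA ids must be present and unique")
    if (length(fl) == 1L && is.finite(fl) && fl > 0 &&
        any(lf < log2(fl) - 1e-9))
        msg <- c(msg, "log2 fractions below log2(floor)")
    mf <- object@meanFraction
    if (length(mf) != nrow(lf) || !identical(names(mf), rownames(lf)))
        msg <- c(msg, "meanFraction must be named per miRNA row")
    if (any(!is.finite(mf)) || any(mf <= 0) || any(mf > 1 + 1e-12))
        msg <- c(msg, "meanFraction must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' miRNA-to-target-gene map
#'
#' A set of miRNA -> target gene relations reduced from any supported
#' prediction/validation resource (TargetScan conserved-site tables, miRDB
#' score tables, miRTarBase validated interactions, a plain two-column file,
#' or the synthetic generator) to a common internal form: one character
#' vector of unique target gene ids per miRNA.
#'
#' @slot entries named list; `entries[[miRNA]]` is a character vector of
#'   target gene ids.
#' @slot source provenance tag.
#'
#' @seealso [readTargetMap()], [unionTargets()], [targetingFrequency()]
#' @export
setClass("TargetMap",
    representation(entries = "list", source = "character"))

setValidity("TargetMap", function(object) {
    msg <- character()
    e <- object@entries
    if (length(e) == 0L) msg <- c(msg, "no interactions")
    nm <- names(e)
    if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
        msg <- c(msg, "entries must be uniquely named by miRNA id")
    if (!all(vapply(e, is.character, logical(1))))
        msg <- c(msg, "entries must be character vectors of gene ids")
    if (length(object@source) != 1L ||
        !object@source %in% .TARGET_SOURCES)
        msg <- c(msg, sprintf("source must be one of %s",
                              paste(.TARGET_SOURCES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Expression-level partition of miRNAs
#'
#' Assignment of each profiled miRNA to one of `nGroups` expression strata,
#' built from equal-width bins on log10(mean fraction) (or explicit
#' boundaries). Group 1 is the lowest-expressed stratum. Bins are closed on
#' the low side; the top bin is closed at both edges, so the maximum belongs
#' to the top group.
#'
#' @slot nGroups integer number of strata.
#' @slot boundaries numeric of length `nGroups + 1`, strictly ascending
#'   log10(mean fraction) cut points.
#' @slot assignment named integer, miRNA id -> group index in 1..nGroups.
#'
#' @seealso [groupMiRNAsByExpression()], [compareGroupNoise()]
#' @export
setClass("GroupPartition",
    representation(nGroups = "integer", boundaries = "numeric",
                   assignment = "integer"))

setValidity("GroupPartition", function(object) {
    msg <- character()
    k <- object@nGroups
    if (length(k) != 1L || k < 1L) msg <- c(msg, "nGroups must be >= 1")
    b <- object@boundaries
    if (length(b) != k + 1L || any(diff(b) <= 0))
        msg <- c(msg, "boundaries must be strictly ascending, length nGroups+1")
    a <- object@assignment
    if (is.null(names(a)) || anyDuplicated(names(a)))
        msg <- c(msg, "assignment must be named uniquely by miRNA id")
    if (any(a < 1L) || any(a > k))
        msg <- c(msg, "assignment outside 1..nGroups")
    if (length(msg)) msg else TRUE
})

#' Ordinary-least-squares fit of log10(CV) on log10(mean)
#'
#' The mean-noise trend fitted across genes of one cell group and one
#' normalization layer. Residuals from this fit are the residual CV (RCV)
#' noise statistic.
#'
#' @slot slope,intercept OLS coefficients.
#' @slot nGenesUsed number of eligible genes (mean > 0 and CV > 0) in the fit.
#' @slot rSquared coefficient of determination.
#'
#' @seealso [fitMeanCVRegression()], [computeRCV()]
#' @export
setClass("RegressionFit",
    representation(slope = "numeric", intercept = "numeric",
                   nGenesUsed = "integer", rSquared = "numeric"))

setValidity("RegressionFit", function(object) {
    msg <- character()
    if (object@nGenesUsed < 3L) msg <- c(msg, "fit needs >= 3 genes")
    for (s in c("slope", "intercept", "rSquared"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            msg <- c(msg, sprintf("%s must be a finite scalar", s))
    if (length(msg)) msg else TRUE
})

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d cells [layer: %s]\n",
                nrow(object), ncol(object),
                S4Vectors::metadata(object)$layer))
    grp <- table(SummarizedExperiment::colData(object)$group)
    cat("cell groups:",
        paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
    prov <- S4Vectors::metadata(object)$provenance
    if (!is.null(prov)) cat("denoise provenance:", prov, "\n")
})

setMethod("show", "MiRNAProfile", function(object) {
    cat(sprintf("MiRNAProfile: %d miRNAs x %d cells (floor %g)\n",
                nrow(object@log2Fractions), ncol(object@log2Fractions),
                object@floor))
    cat(sprintf("mean fraction range: [%.3g, %.3g]\n",
                min(object@meanFraction), max(object@meanFraction)))
})

setMethod("show", "TargetMap", function(object) {
    cat(sprintf("TargetMap [%s]: %d miRNAs, %d interactions\n",
                object@source, length(object@entries),
                sum(lengths(object@entries))))
})

setMethod("show", "GroupPartition", function(object) {
    cat(sprintf("GroupPartition: %d miRNAs in %d expression groups\n",
                length(object@assignment), object@nGroups))
    print(table(factor(object@assignment, levels = seq_len(object@nGroups))))
})

setMethod("show", "RegressionFit", function(object) {
    cat(sprintf(
        "RegressionFit: log10(CV) = %.4f %+.4f * log10(mean); n = %d, R2 = %.3f\n",
        object@intercept, object@slope, object@nGenesUsed, object@rSquared))
})
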