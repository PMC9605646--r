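#' Per-gene mean, SD and coefficient of variation for one cell group
#'
#' Computes, over the cells of one group, each gene's mean, sample standard
#' deviation (n - 1 denominator) and coefficient of variation CV = SD/mean
#' of the normalized values, plus their log10 transforms. Genes with zero
#' mean or zero CV are flagged ineligible: their log10 values (and any later
#' RCV) are undefined and they are excluded from the mean-CV regression, but
#' they stay in the table so nothing is silently dropped.
#'
#' @param x an [ExpressionMatrix-class] on layer `"rpkm"` or
#'   `"denoised-normalized"`.
#' @param group the cell-group label to use (must have >= 3 cells).
#' @return A data.frame (one row per gene) with columns `gene_id`, `mean`,
#'   `sd`, `cv`, `log10_mean`, `log10_cv`, `eligible`, and attributes
#'   `group` and `layer`.
#' @export
computeMeanCV <- function(x, group) {
    stopifnot(methods::is(x, "ExpressionMatrix"))
    layer <- expressionLayer(x)
    if (!layer %in% c("rpkm", "denoised-normalized"))
        stop("noise is computed on normalized layers (rpkm or ",
             "denoised-normalized), not ", layer)
    grp <- cellGroups(x)
    if (!group %in% grp) stop("no cells in group '", group, "'")
    v <- exprValues(x)[, grp == group, drop = FALSE]
    if (ncol(v) < 3L)
        stop("group '", group, "' has ", ncol(v), " cells; >= 3 required")
    m <- rowMeans(v)
    s <- apply(v, 1L, stats::sd)
    cv <- ifelse(m > 0, s / m, NA_real_)
    eligible <- is.finite(cv) & cv > 0 & m > 0
    tab <- data.frame(
        gene_id = rownames(v),
        mean = m, sd = s, cv = cv,
        log10_mean = ifelse(eligible, log10(m), NA_real_),
        log10_cv = ifelse(eligible, log10(cv), NA_real_),
        eligible = eligible,
        row.names = NULL, stringsAsFactors = FALSE)
    attr(tab, "group") <- group
    attr(tab, "layer") <- layer
    tab
}

#' Fit the mean-CV regression across genes
#'
#' Single-cell expression noise decreases with the mean: log10(CV) and
#' log10(mean) are linearly related across genes. This fits that trend by
#' ordinary least squares over all eligible genes (mean > 0 and CV > 0) of
#' one noise table; its residuals define the RCV statistic.
#'
#' @param tab a noise table from [computeMeanCV()].
#' @return A [RegressionFit-class].
#' @export
fitMeanCVRegression <- function(tab) {
    use <- tab$eligible
    nExcluded <- sum(!use)
    if (nExcluded)
        message(nExcluded, " gene(s) ineligible (zero mean or zero CV) ",
                "excluded from the mean-CV fit")
    if (sum(use) < 3L)
        stop("need >= 3 eligible genes to fit; have ", sum(use))
    xm <- tab$log10_mean[use]
    if (stats::var(xm) == 0)
        stop("log10(mean) has zero variance; regression undefined")
    fit <- stats::lm(log10_cv ~ log10_mean, data = tab[use, ])
    methods::new("RegressionFit",
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 nGenesUsed = as.integer(sum(use)),
                 rSquared = summary(fit)$r.squared)
}

#' Residual CV: noise relative to genes of equal expression
#'
#' RCV is the residual of the mean-CV regression:
#' `rcv = log10(cv) - (intercept + slope * log10(mean))`. It measures a
#' gene's noise relative to the average noise of genes with the same mean
#' expression, removing the confounding mean dependence. Ineligible genes
#' carry `NA`.
#'
#' @param tab a noise table from [computeMeanCV()].
#' @param fit a [RegressionFit-class], normally fitted on `tab` itself (or
#'   on a designated reference table of the same layer and group).
#' @return `tab` with an added `rcv` column and the fit attached as
#'   attribute `fit`.
#' @export
computeRCV <- function(tab, fit) {
    stopifnot(methods::is(fit, "RegressionFit"))
    predicted <- fit@intercept + fit@slope * tab$log10_mean
    tab$rcv <- ifelse(tab$eligible, tab$log10_cv - predicted, NA_real_)
    attr(tab, "fit") <- fit
    tab
}

#' One-call noise table: mean/CV, regression fit, and RCV
#'
#' Convenience wrapper running [computeMeanCV()], [fitMeanCVRegression()]
#' and [computeRCV()] for one cell group of a normalized matrix.
#'
#' @inheritParams computeMeanCV
#' @return A noise table with `rcv`, the fit attached as attribute `fit`.
#' @export
noiseTable <- function(x, group) {
    tab <- computeMeanCV(x, group)
    computeRCV(tab, fitMeanCVRegression(tab))
}

#' Write a noise table as TSV
#'
#' Serializes a noise table with its group and layer tags as columns.
#'
#' @param tab a noise table (from [noiseTable()] or [computeRCV()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNoiseTable <- function(tab, path) {
    out <- data.frame(
        gene_id = tab$gene_id,
        group = attr(tab, "group"), layer = attr(tab, "layer"),
        mean = tab$mean, sd = tab$sd, cv = tab$cv,
        log10_mean = tab$log10_mean, log10_cv = tab$log10_cv,
        rcv = if (is.null(tab$rcv)) NA_real_ else tab$rcv,
        eligible = tab$eligible,
        stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
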