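#' Load an externally denoised count matrix aligned to its raw matrix
#'
#' Ingests the output of an external single-cell denoiser (e.g. the
#' `mean.tsv` of a ZINB-autoencoder denoiser, or a consensus-clustering
#' imputer) and aligns it to the raw matrix it denoises: rows and columns
#' are reordered to the raw order, and genes absent from the denoised file
#' are dropped (their count is reported). Denoising is never performed here;
#' the pipeline's own contribution is downstream of it.
#'
#' @param path gene x cell TSV (first column gene id, header of cell ids).
#' @param raw the raw-count [ExpressionMatrix-class] the file denoises.
#' @param provenance `"dca"`, `"ccimpute"`, `"passthrough"` or
#'   `"synthetic"`.
#' @return An [ExpressionMatrix-class] on layer `"denoised"`, cells
#'   identical to `raw`, genes the intersection in raw order. Subset `raw`
#'   to `rownames()` of the result before comparing layers.
#' @export
loadDenoised <- function(path, raw,
                         provenance = c("dca", "ccimpute", "passthrough",
                                        "synthetic")) {
    provenance <- match.arg(provenance)
    stopifnot(methods::is(raw, "ExpressionMatrix"))
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate gene id(s) in denoised file")
    values <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(values) <- ids
    if (any(values < 0)) stop("denoised matrix contains negative values")
    shared <- intersect(rownames(raw), ids)
    if (length(shared) < 0.5 * nrow(raw))
        stop(sprintf(
            "only %d/%d genes of the raw matrix found in the denoised file; likely a mismatched run",
            length(shared), nrow(raw)))
    dropped <- nrow(raw) - length(shared)
    if (dropped)
        message(dropped, " raw gene(s) absent from the denoised matrix; ",
                "dropped from the denoised layer")
    missingCells <- setdiff(colnames(raw), colnames(values))
    if (length(missingCells))
        stop("denoised file lacks cell(s): ",
             paste(missingCells, collapse = ", "))
    shared <- rownames(raw)[rownames(raw) %in% shared]  # raw order
    ExpressionMatrix(values[shared, colnames(raw), drop = FALSE],
                     groups = cellGroups(raw), layer = "denoised",
                     provenance = provenance)
}

#' Pass raw counts through as a denoised layer
#'
#' Identity adapter so the full two-layer pipeline (RPKM noise and
#' denoised-normalized noise) runs without any external denoiser; the
#' denoised layer then simply reproduces the raw-layer results.
#'
#' @param raw a raw-count [ExpressionMatrix-class].
#' @return The same values on layer `"denoised"`, provenance
#'   `"passthrough"`.
#' @export
passthroughDenoise <- function(raw) {
    stopifnot(methods::is(raw, "ExpressionMatrix"))
    if (expressionLayer(raw) != "raw-count")
        stop("passthroughDenoise expects the raw-count layer")
    ExpressionMatrix(exprValues(raw), groups = cellGroups(raw),
                     layer = "denoised", provenance = "passthrough")
}
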