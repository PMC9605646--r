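#' Construct an ExpressionMatrix
#'
#' @param values gene x cell numeric matrix with row and column names.
#' @param groups cell group labels: a named character vector (names = cell
#'   ids), an unnamed vector of length `ncol(values)` in column order, or a
#'   data.frame with columns `cell_id` and `group`.
#' @param layer one of `"raw-count"`, `"rpkm"`, `"denoised"`,
#'   `"denoised-normalized"`.
#' @param provenance optional denoiser provenance tag for denoised layers.
#'
#' @details Raw-count layers may carry fractional values (expected counts
#' from EM-based quantifiers such as RSEM); these are accepted with a
#' warning rather than rejected.
#'
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, groups,
                             layer = c("raw-count", "rpkm", "denoised",
                                       "denoised-normalized"),
                             provenance = NULL) {
    layer <- match.arg(layer)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    groups <- .resolveGroups(groups, colnames(values))
    if (layer == "raw-count" && any(abs(values - round(values)) > 1e-8))
        warning("raw-count layer contains fractional values ",
                "(expected counts?); accepted as-is")
    md <- list(layer = layer)
    if (!is.null(provenance)) md$provenance <- provenance
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = values),
        colData = S4Vectors::DataFrame(group = unname(groups),
                                       row.names = colnames(values)),
        metadata = md)
    methods::new("ExpressionMatrix", se)
}

.resolveGroups <- function(groups, cellIds) {
    if (is.data.frame(groups)) {
        if (!all(c("cell_id", "group") %in% names(groups)))
            stop("group data.frame needs columns 'cell_id' and 'group'")
        groups <- stats::setNames(as.character(groups$group),
                                  as.character(groups$cell_id))
    }
    groups <- if (!is.null(names(groups))) {
        missing <- setdiff(cellIds, names(groups))
        if (length(missing))
            stop("no group label for cell(s): ",
                 paste(missing, collapse = ", "))
        groups[cellIds]
    } else {
        if (length(groups) != length(cellIds))
            stop("unnamed group vector must have one label per cell")
        stats::setNames(as.character(groups), cellIds)
    }
    as.character(groups)
}

#' Read a gene x cell expression matrix from TSV or GCT
#'
#' Reads GEO-supplementary-style flat matrices: either a plain TSV whose
#' first column is the gene id and whose header row names the cells, or a
#' GCT 1.2 file (`#1.2` header, a dimensions line, then `Name` and
#' `Description` columns before the cells).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gct"`.
#' @param groups cell group assignment (see [ExpressionMatrix()]); may also
#'   be a path to a two-column TSV (`cell_id`, `group`).
#' @param layer layer tag for the values read (default `"raw-count"`).
#' @return An [ExpressionMatrix-class]; row and column order follow the file.
#' @export
readExpressionMatrix <- function(path, dialect = c("tsv", "gct"), groups,
                                 layer = "raw-count") {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.character(groups) && length(groups) == 1L && file.exists(groups))
        groups <- readGroupAssignment(groups)
    tab <- if (dialect == "tsv") {
        utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
    } else {
        .readGCT(path)
    }
    ids <- as.character(tab[[1L]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
    body <- tab[, -1L, drop = FALSE]
    for (j in seq_along(body)) {
        col <- body[[j]]
        if (!is.numeric(col)) {
            num <- suppressWarnings(as.numeric(col))
            bad <- which(is.na(num) & !is.na(col))
            if (length(bad))
                stop(sprintf(
                    "non-numeric value '%s' at gene row %d (%s), cell column '%s'",
                    col[bad[1L]], bad[1L], ids[bad[1L]], names(body)[j]))
            body[[j]] <- num
        }
    }
    values <- as.matrix(body)
    rownames(values) <- ids
    ExpressionMatrix(values, groups = groups, layer = layer)
}

.readGCT <- function(path) {
    lines <- readLines(path, n = 2L)
    if (!startsWith(lines[1L], "#1.2"))
        stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    dims <- as.integer(strsplit(lines[2L], "\t")[[1L]][1:2])
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", skip = 2L,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("Name", "Description") %in% names(tab)[1:2]))
        stop("GCT file lacks Name/Description columns: ", path)
    tab$Description <- NULL
    if (!is.na(dims[1L]) && nrow(tab) != dims[1L])
        stop(sprintf("GCT declares %d rows but file has %d",
                     dims[1L], nrow(tab)))
    if (!is.na(dims[2L]) && ncol(tab) - 1L != dims[2L])
        stop(sprintf("GCT declares %d samples but file has %d",
                     dims[2L], ncol(tab) - 1L))
    tab
}

#' Read a two-column cell-group assignment table
#'
#' @param path TSV with columns `cell_id` and `group` (header optional when
#'   exactly two columns).
#' @return Named character vector, cell id -> group label.
#' @export
readGroupAssignment <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "group") %in% names(tab))) {
        tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                                 col.names = c("cell_id", "group"),
                                 stringsAsFactors = FALSE)
    }
    stats::setNames(as.character(tab$group), as.character(tab$cell_id))
}

#' Discard cells with small libraries
#'
#' Cells whose library size (column sum of raw read counts over all genes
#' currently in the matrix) is strictly below `minReads` are discarded.
#' Cells exactly at the threshold are retained. Library size is intended to
#' be computed on the full pre-gene-filter matrix, so apply this filter
#' before [filterGenesByPrevalence()].
#'
#' @param x an [ExpressionMatrix-class] on the raw-count layer.
#' @param minReads minimum library size (default 1e5, i.e. 0.1 million).
#' @return The filtered matrix; discarded cell ids and their library sizes
#'   are reported via [message()].
#' @export
filterCellsByLibrarySize <- function(x, minReads = 1e5) {
    stopifnot(methods::is(x, "ExpressionMatrix"))
    if (expressionLayer(x) != "raw-count")
        stop("library-size filter applies to the raw-count layer, not ",
             expressionLayer(x))
    libs <- colSums(exprValues(x))
    keep <- libs >= minReads
    if (!any(keep)) stop("all cells discarded by library-size filter")
    if (any(!keep))
        message("discarding ", sum(!keep), " cell(s) with library size < ",
                format(minReads), ": ",
                paste(sprintf("%s (%.0f)", colnames(x)[!keep], libs[!keep]),
                      collapse = ", "))
    x[, keep]
}

#' Retain genes expressed in enough cells
#'
#' A gene counts as expressed in a cell when its value is strictly positive.
#' With `perGroup = TRUE` a gene is retained iff its expressed-cell count is
#' strictly greater than `minCells` in at least one cell group; with
#' `perGroup = FALSE` the count is taken over all cells.
#'
#' @param x an [ExpressionMatrix-class].
#' @param minCells threshold (strict inequality; default 5).
#' @param perGroup evaluate the threshold within each cell group.
#' @return The filtered matrix.
#' @export
filterGenesByPrevalence <- function(x, minCells = 5L, perGroup = TRUE) {
    stopifnot(methods::is(x, "ExpressionMatrix"))
    if (minCells < 0) stop("minCells must be >= 0")
    expressed <- exprValues(x) > 0
    keep <- if (perGroup) {
        grp <- cellGroups(x)
        counts <- vapply(unique(grp), function(g)
            rowSums(expressed[, grp == g, drop = FALSE]),
            numeric(nrow(x)))
        apply(counts > minCells, 1L, any)
    } else {
        rowSums(expressed) > minCells
    }
    message(sum(!keep), " gene(s) removed by prevalence filter; ",
            sum(keep), " retained")
    x[keep, ]
}

#' Normalize raw miRNA counts to floored log2 fractions
#'
#' Each miRNA's raw read count is divided by the total miRNA count of its
#' cell; fractions below `floor` are raised to `floor`; the result is
#' log2-transformed. The per-miRNA mean fraction (used for expression
#' stratification) is the across-cell mean of the post-floor, pre-log
#' fractions.
#'
#' @param counts miRNA x cell non-negative numeric matrix with dimnames.
#' @param floor minimum fraction (default 1e-4).
#' @return A [MiRNAProfile-class].
#' @export
normalizeMiRNA <- function(counts, floor = 1e-4) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("negative miRNA counts")
    totals <- colSums(counts)
    if (any(totals <= 0))
        stop("cell(s) with zero total miRNA count: ",
             paste(colnames(counts)[totals <= 0], collapse = ", "))
    frac <- sweep(counts, 2L, totals, "/")
    frac[frac < floor] <- floor
    methods::new("MiRNAProfile",
                 log2Fractions = log2(frac),
                 meanFraction = rowMeans(frac),
                 floor = floor)
}

#' RPKM-style normalization by effective gene length and library size
#'
#' `value_out = value * 1e9 / (effective_length * column_total)`. Applied to
#' the raw-count layer this yields RPKM; applied to a denoised layer it
#' yields normalized denoised counts on the same scale, so noise statistics
#' of the two layers are directly comparable.
#'
#' @param x an [ExpressionMatrix-class] on layer `"raw-count"` or
#'   `"denoised"`.
#' @param lengths effective gene lengths in base pairs: a named numeric
#'   vector, or a data.frame with columns `gene_id` and `effective_length`.
#' @return An [ExpressionMatrix-class] on layer `"rpkm"` or
#'   `"denoised-normalized"`.
#' @export
rpkmNormalize <- function(x, lengths) {
    stopifnot(methods::is(x, "ExpressionMatrix"))
    layer <- expressionLayer(x)
    if (!layer %in% c("raw-count", "denoised"))
        stop("rpkmNormalize expects raw-count or denoised layer, not ", layer)
    if (is.data.frame(lengths)) {
        if (!all(c("gene_id", "effective_length") %in% names(lengths)))
            stop("length table needs columns 'gene_id', 'effective_length'")
        lengths <- stats::setNames(lengths$effective_length,
                                   lengths$gene_id)
    }
    missing <- setdiff(rownames(x), names(lengths))
    if (length(missing))
        stop("no effective length for gene(s): ",
             paste(utils::head(missing, 10L), collapse = ", "),
             if (length(missing) > 10L) sprintf(" (+%d more)",
                                                length(missing) - 10L))
    len <- lengths[rownames(x)]
    if (any(len < 1)) stop("effective lengths must be >= 1")
    v <- exprValues(x)
    totals <- colSums(v)
    if (any(totals <= 0))
        stop("zero column total in cell(s): ",
             paste(colnames(x)[totals <= 0], collapse = ", "))
    out <- v * 1e9 / outer(as.numeric(len), totals)
    newLayer <- if (layer == "raw-count") "rpkm" else "denoised-normalized"
    ExpressionMatrix(out, groups = cellGroups(x), layer = newLayer,
                     provenance = denoiseProvenance(x))
}
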