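#' Construct a TargetMap from miRNA/gene pairs
#'
#' @param mirna,gene character vectors of equal length (interaction pairs),
#'   de-duplicated on construction.
#' @param source provenance tag.
#' @return A [TargetMap-class].
#' @export
TargetMap <- function(mirna, gene, source = "synthetic") {
    stopifnot(length(mirna) == length(gene))
    keep <- nzchar(mirna) & nzchar(gene) & !is.na(mirna) & !is.na(gene)
    pairs <- unique(data.frame(mirna = as.character(mirna[keep]),
                               gene = as.character(gene[keep]),
                               stringsAsFactors = FALSE))
    if (nrow(pairs) == 0L) stop("zero miRNA-target interactions")
    methods::new("TargetMap",
                 entries = split(pairs$gene, pairs$mirna),
                 source = source)
}

#' Read miRNA target predictions from a flat file
#'
#' Parses one of the supported resource dialects down to the internal
#' two-column (miRNA id, gene id) model, de-duplicated:
#' \describe{
#'   \item{two-column}{headerless TSV `mirna_id<TAB>gene_id` (the internal
#'     interchange dialect; also what the simulator writes).}
#'   \item{targetscan}{TSV with columns `miR Family` and `Gene Symbol`
#'     (conserved-site predictions are keyed by miRNA family); rows are
#'     expanded to member miRNAs through `familyMap`.}
#'   \item{mirdb}{three-column TSV `miRNA<TAB>accession<TAB>score`; rows
#'     with score below `scoreThreshold` are excluded (default keeps all).}
#'   \item{mirtarbase}{CSV with columns `miRTarBase ID`, `miRNA`,
#'     `Target Gene`.}
#' }
#'
#' @param path input file.
#' @param source dialect, one of `"two-column"`, `"targetscan"`, `"mirdb"`,
#'   `"mirtarbase"`.
#' @param familyMap for `targetscan`: named list, miRNA family -> character
#'   vector of member miRNA ids.
#' @param scoreThreshold for `mirdb`: minimum prediction score (default
#'   `-Inf`, keep all).
#' @return A [TargetMap-class].
#' @export
readTargetMap <- function(path,
                          source = c("two-column", "targetscan", "mirdb",
                                     "mirtarbase"),
                          familyMap = NULL, scoreThreshold = -Inf) {
    source <- match.arg(source)
    if (!file.exists(path)) stop("file not found: ", path)
    pairs <- switch(source,
        "two-column" = {
            tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                                     stringsAsFactors = FALSE)
            if (ncol(tab) < 2L) stop("two-column dialect needs 2 columns")
            data.frame(mirna = as.character(tab[[1L]]),
                       gene = as.character(tab[[2L]]),
                       stringsAsFactors = FALSE)
        },
        targetscan = {
            tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE)
            famCol <- intersect(c("miR Family", "miR family"), names(tab))
            geneCol <- intersect(c("Gene Symbol", "Gene symbol"),
                                 names(tab))
            if (!length(famCol) || !length(geneCol))
                stop("targetscan dialect needs 'miR Family' and ",
                     "'Gene Symbol' columns")
            if (is.null(familyMap))
                stop("targetscan dialect needs a familyMap ",
                     "(family -> member miRNA ids)")
            fam <- as.character(tab[[famCol[1L]]])
            gene <- as.character(tab[[geneCol[1L]]])
            known <- fam %in% names(familyMap)
            if (any(!known))
                message(sum(!known),
                        " row(s) with unmapped miR family dropped")
            members <- familyMap[fam[known]]
            data.frame(mirna = unlist(members, use.names = FALSE),
                       gene = rep(gene[known], lengths(members)),
                       stringsAsFactors = FALSE)
        },
        mirdb = {
            tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                                     stringsAsFactors = FALSE)
            if (ncol(tab) < 3L)
                stop("mirdb dialect needs 3 columns (miRNA, accession, score)")
            keep <- as.numeric(tab[[3L]]) >= scoreThreshold
            data.frame(mirna = as.character(tab[[1L]][keep]),
                       gene = as.character(tab[[2L]][keep]),
                       stringsAsFactors = FALSE)
        },
        mirtarbase = {
            tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                                   stringsAsFactors = FALSE)
            mCol <- intersect(c("miRNA"), names(tab))
            gCol <- intersect(c("Target Gene", "Target Gene Symbol"),
                              names(tab))
            if (!length(mCol) || !length(gCol))
                stop("mirtarbase dialect needs 'miRNA' and 'Target Gene' ",
                     "columns")
            data.frame(mirna = as.character(tab[[mCol[1L]]]),
                       gene = as.character(tab[[gCol[1L]]]),
                       stringsAsFactors = FALSE)
        })
    if (nrow(pairs) == 0L) stop("zero interactions parsed from ", path)
    TargetMap(pairs$mirna, pairs$gene,
              source = if (source == "two-column") "synthetic" else source)
}

#' Stratify miRNAs by expression level
#'
#' Partitions miRNAs into `nGroups` strata along a gradient of their mean
#' expression fraction on the log10 scale. Default bins are equal-width over
#' `[min, max]` of log10(mean fraction); each bin is closed at its lower
#' edge, and the top bin also at its upper edge, so the maximum falls in the
#' top group. Group 1 is the lowest-expressed stratum.
#'
#' @param profile a [MiRNAProfile-class].
#' @param nGroups number of strata (default 4).
#' @param boundaries optional explicit log10(mean fraction) cut points
#'   (length `nGroups + 1`, ascending, covering all values).
#' @return A [GroupPartition-class].
#' @export
groupMiRNAsByExpression <- function(profile, nGroups = 4L,
                                    boundaries = NULL) {
    stopifnot(methods::is(profile, "MiRNAProfile"))
    nGroups <- as.integer(nGroups)
    lf <- log10(meanFraction(profile))
    if (length(unique(lf)) < nGroups)
        stop("need at least ", nGroups, " distinct mean fractions; ",
             "have ", length(unique(lf)))
    if (max(lf) == min(lf))
        stop("all mean fractions equal; expression gradient degenerate")
    if (is.null(boundaries)) {
        boundaries <- seq(min(lf), max(lf), length.out = nGroups + 1L)
    } else {
        if (length(boundaries) != nGroups + 1L || any(diff(boundaries) <= 0))
            stop("boundaries must be ascending, length nGroups + 1")
        if (min(lf) < boundaries[1L] || max(lf) > boundaries[nGroups + 1L])
            stop("boundaries do not cover all mean fractions")
    }
    idx <- findInterval(lf, boundaries, rightmost.closed = TRUE)
    methods::new("GroupPartition", nGroups = nGroups,
                 boundaries = as.numeric(boundaries),
                 assignment = stats::setNames(as.integer(idx), names(lf)))
}

#' Union target set of a group of miRNAs
#'
#' The target genes of multiple miRNAs are defined as the union of the
#' target genes of each miRNA, intersected with the expressed (analyzable)
#' gene universe.
#'
#' @param mirnas character vector of miRNA ids.
#' @param targetMap a [TargetMap-class].
#' @param expressedGenes character vector of analyzable gene ids.
#' @return Character vector of gene ids (possibly empty, with a warning).
#' @export
unionTargets <- function(mirnas, targetMap, expressedGenes) {
    stopifnot(methods::is(targetMap, "TargetMap"))
    out <- intersect(targetsOf(targetMap, mirnas), expressedGenes)
    if (length(out) == 0L)
        warning("empty union target set for ", length(mirnas), " miRNA(s)")
    out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided KS test: D is the supremum distance between the two empirical
#' CDFs; the p-value uses the asymptotic Kolmogorov distribution (target-set
#' sizes here are typically hundreds to thousands of genes, where the
#' asymptotic form is standard).
#'
#' @param x,y numeric samples (NAs dropped; at least one value each).
#' @return A list with elements `d` and `p`.
#' @export
ksTwoSample <- function(x, y) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 1L || length(y) < 1L)
        stop("both samples must be non-empty")
    kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    # keep p strictly positive so -log10(p) stays finite after underflow
    p <- min(1, max(unname(kt$p.value), 1e-300))
    list(d = unname(kt$statistic), p = p)
}

#' Compare RCV distributions of target sets across miRNA expression groups
#'
#' For every unordered pair of miRNA expression strata, runs a two-sample KS
#' test on the RCV values of the two union target sets (which may overlap;
#' shared genes appear in both samples). Groups with fewer than `minTargets`
#' eligible target genes are skipped with a warning.
#'
#' @param partition a [GroupPartition-class].
#' @param targetMap a [TargetMap-class].
#' @param noise a noise table with `rcv` (see [noiseTable()]).
#' @param minTargets minimum eligible target genes per group (default 10).
#' @param exclusiveTargets drop genes shared between the two groups' sets
#'   from both samples (sensitivity analysis; default `FALSE`).
#' @return A data.frame with one row per compared pair: `group_i`,
#'   `group_j`, `d`, `p`, `neglog10p`, `n_i`, `n_j`; the per-group RCV
#'   samples (for CDF plots) are attached as attribute `samples`, a named
#'   list of numeric vectors.
#' @export
compareGroupNoise <- function(partition, targetMap, noise,
                              minTargets = 10L, exclusiveTargets = FALSE) {
    stopifnot(methods::is(partition, "GroupPartition"))
    if (is.null(noise$rcv)) stop("noise table lacks rcv; run computeRCV()")
    rcv <- stats::setNames(noise$rcv, noise$gene_id)
    universe <- noise$gene_id[noise$eligible & is.finite(noise$rcv)]
    assign <- groupAssignment(partition)
    k <- nGroups(partition)
    sets <- lapply(seq_len(k), function(g) {
        members <- names(assign)[assign == g]
        suppressWarnings(unionTargets(members, targetMap, universe))
    })
    names(sets) <- paste0("group", seq_len(k))
    small <- which(lengths(sets) < minTargets)
    if (length(small))
        warning("group(s) ", paste(small, collapse = ", "), " have < ",
                minTargets, " eligible target genes; their comparisons ",
                "are skipped")
    rows <- list()
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
        if (i %in% small || j %in% small) next
        si <- sets[[i]]; sj <- sets[[j]]
        if (exclusiveTargets) {
            shared <- intersect(si, sj)
            si <- setdiff(si, shared); sj <- setdiff(sj, shared)
            if (length(si) < minTargets || length(sj) < minTargets) next
        }
        ks <- ksTwoSample(rcv[si], rcv[sj])
        rows[[length(rows) + 1L]] <- data.frame(
            group_i = i, group_j = j, d = ks$d, p = ks$p,
            neglog10p = -log10(ks$p),
            n_i = length(si), n_j = length(sj))
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(group_i = integer(), group_j = integer(),
                   d = numeric(), p = numeric(), neglog10p = numeric(),
                   n_i = integer(), n_j = integer())
    attr(out, "samples") <- lapply(sets, function(s) unname(rcv[s]))
    out
}
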