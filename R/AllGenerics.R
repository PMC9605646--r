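#' @name miRNoise-accessors
#' @title Accessors for miRNoise classes
#'
#' @description Small accessor generics for the package's S4 containers;
#' user code should use these rather than reaching into slots.
#'
#' @param x,object a miRNoise S4 object.
#' @param mirna a miRNA identifier.
#' @return The corresponding component (see individual generics).
NULL

#' @rdname miRNoise-accessors
#' @export
setGeneric("expressionLayer", function(x) standardGeneric("expressionLayer"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("cellGroups", function(x) standardGeneric("cellGroups"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("denoiseProvenance",
           function(x) standardGeneric("denoiseProvenance"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("log2Fractions", function(x) standardGeneric("log2Fractions"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("meanFraction", function(x) standardGeneric("meanFraction"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("targetsOf", function(x, mirna) standardGeneric("targetsOf"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("targetSource", function(x) standardGeneric("targetSource"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("groupAssignment", function(x) standardGeneric("groupAssignment"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("groupBoundaries", function(x) standardGeneric("groupBoundaries"))

#' @rdname miRNoise-accessors
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname miRNoise-accessors
#' @export
setMethod("expressionLayer", "ExpressionMatrix",
          function(x) S4Vectors::metadata(x)$layer)

#' @rdname miRNoise-accessors
#' @export
setMethod("cellGroups", "ExpressionMatrix", function(x) {
    g <- SummarizedExperiment::colData(x)$group
    names(g) <- colnames(x)
    g
})

#' @rdname miRNoise-accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "values"))

#' @rdname miRNoise-accessors
#' @export
setMethod("denoiseProvenance", "ExpressionMatrix",
          function(x) S4Vectors::metadata(x)$provenance)

#' @rdname miRNoise-accessors
#' @export
setMethod("log2Fractions", "MiRNAProfile", function(x) x@log2Fractions)

#' @rdname miRNoise-accessors
#' @export
setMethod("meanFraction", "MiRNAProfile", function(x) x@meanFraction)

#' @rdname miRNoise-accessors
#' @export
setMethod("mirnaIds", "MiRNAProfile", function(x) rownames(x@log2Fractions))

#' @rdname miRNoise-accessors
#' @export
setMethod("mirnaIds", "TargetMap", function(x) names(x@entries))

#' @rdname miRNoise-accessors
#' @export
setMethod("targetsOf", "TargetMap", function(x, mirna) {
    hits <- x@entries[intersect(mirna, names(x@entries))]
    unique(unlist(hits, use.names = FALSE))
})

#' @rdname miRNoise-accessors
#' @export
setMethod("targetSource", "TargetMap", function(x) x@source)

#' @rdname miRNoise-accessors
#' @export
setMethod("groupAssignment", "GroupPartition", function(x) x@assignment)

#' @rdname miRNoise-accessors
#' @export
setMethod("groupBoundaries", "GroupPartition", function(x) x@boundaries)

#' @rdname miRNoise-accessors
#' @export
setMethod("nGroups", "GroupPartition", function(x) x@nGroups)

#' @rdname miRNoise-accessors
#' @export
setMethod("coef", "RegressionFit", function(object)
    c(intercept = object@intercept, slope = object@slope))
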