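#' @rdname ProteinArraySet-accessors
#' @export
setGeneric("fgIntensity", function(x) standardGeneric("fgIntensity"))

#' @rdname ProteinArraySet-accessors
#' @export
setGeneric("bgIntensity", function(x) standardGeneric("bgIntensity"))

#' @rdname ProteinArraySet-accessors
#' @export
setGeneric("probeInfo", function(x) standardGeneric("probeInfo"))

#' @rdname ProteinArraySet-accessors
#' @export
setGeneric("arrayTargets", function(x) standardGeneric("arrayTargets"))

#' @rdname ProteinArraySet-accessors
#' @export
setGeneric("logState", function(x) standardGeneric("logState"))

#' @rdname ProteinArraySet-accessors
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))

#' Accessors for ProteinArraySet
#'
#' \code{fgIntensity} and \code{bgIntensity} return the foreground
#' (expression) and background matrices; \code{probeInfo} the spot
#' annotation as a \code{data.frame}; \code{arrayTargets} the sample
#' targets; \code{logState} whether the expression matrix is on the
#' \code{"linear"} or \code{"log2"} scale; \code{processingLog} the ordered
#' record of applied processing steps.
#'
#' @param x A \linkS4class{ProteinArraySet}.
#' @return See description.
#' @name ProteinArraySet-accessors
#' @aliases fgIntensity bgIntensity probeInfo arrayTargets logState
#'   processingLog
#'
#' @examples
#' aset <- simulateArraySet(simDesign(nProteins = 10, nArraysPerCondition =
#'   c(A = 2, B = 2)), seed = 1)$arrays
#' dim(fgIntensity(aset))
#' logState(aset)
NULL

#' @rdname ProteinArraySet-accessors
setMethod("fgIntensity", "ProteinArraySet", function(x)
    SummarizedExperiment::assay(x, "fg"))

#' @rdname ProteinArraySet-accessors
setMethod("bgIntensity", "ProteinArraySet", function(x)
    SummarizedExperiment::assay(x, "bg"))

#' @rdname ProteinArraySet-accessors
setMethod("probeInfo", "ProteinArraySet", function(x)
    as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname ProteinArraySet-accessors
setMethod("arrayTargets", "ProteinArraySet", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname ProteinArraySet-accessors
setMethod("logState", "ProteinArraySet", function(x)
    S4Vectors::metadata(x)$logState)

#' @rdname ProteinArraySet-accessors
setMethod("processingLog", "ProteinArraySet", function(x)
    S4Vectors::metadata(x)$processing)

## internal helpers ---------------------------------------------------------

`fgIntensity<-` <- function(x, value) {
    SummarizedExperiment::assay(x, "fg") <- value
    x
}

`bgIntensity<-` <- function(x, value) {
    SummarizedExperiment::assay(x, "bg") <- value
    x
}

setLogState <- function(x, state) {
    S4Vectors::metadata(x)$logState <- state
    x
}

recordStep <- function(x, step) {
    S4Vectors::metadata(x)$processing <-
        c(S4Vectors::metadata(x)$processing, step)
    x
}

#' @export
setMethod("show", "ProteinArraySet", function(object) {
    cat("ProteinArraySet with", nrow(object), "spots and", ncol(object),
        "arrays\n")
    cat("  scale:", logState(object), "\n")
    tab <- table(SummarizedExperiment::rowData(object)$Category)
    cat("  categories:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
    pl <- processingLog(object)
    if (length(pl))
        cat("  processing:", paste(pl, collapse = " -> "), "\n")
})

#' @export
setMethod("show", "SpotTable", function(object) {
    cat("SpotTable", object@arrayId, "with", nrow(object@spots),
        "spots\n")
    cat("  intensity columns:", object@fgColumn, "/", object@bgColumn, "\n")
})

#' @export
setMethod("show", "NormexpParams", function(object) {
    cat("NormexpParams: mu =", format(object@mu, digits = 5),
        ", sigma =", format(object@sigma, digits = 5),
        ", alpha =", format(object@alpha, digits = 5),
        ", offset =", object@offset, "\n")
    cat("  logLik =", format(object@logLik, digits = 8),
        ", converged =", object@converged, "\n")
})

#' @export
setMethod("show", "ArrayWeights", function(object) {
    cat("ArrayWeights over", length(object@weights), "arrays (",
        object@iterations, "scoring iterations, converged =",
        object@converged, ")\n")
    print(round(object@weights, 4))
})

#' @export
setMethod("show", "ProbeFit", function(object) {
    cat("ProbeFit:", nrow(object@coefficients), "probes,",
        ncol(object@design), "coefficients,",
        length(object@weights), "arrays\n")
})

#' @export
setMethod("show", "ModeratedStats", function(object) {
    cat("ModeratedStats:", nrow(object@t), "probes,",
        ncol(object@t), "contrast(s);",
        "d0 =", format(object@df.prior, digits = 5),
        ", s0^2 =", format(object@var.prior, digits = 5), "\n")
})

#' Prior degrees of freedom and prior variance
#'
#' @param x A \linkS4class{ModeratedStats}.
#' @return \code{priorDf}: the estimated prior degrees of freedom d0
#'   (\code{Inf} when the probe variances show no excess dispersion);
#'   \code{priorVar}: the prior variance s0^2.
#' @export
priorDf <- function(x) {
    stopifnot(is(x, "ModeratedStats"))
    x@df.prior
}

#' @rdname priorDf
#' @export
priorVar <- function(x) {
    stopifnot(is(x, "ModeratedStats"))
    x@var.prior
}

#' Array weights as a numeric vector
#'
#' @param x An \linkS4class{ArrayWeights} object.
#' @return Named numeric vector of per-array weights.
#' @export
weightValues <- function(x) {
    stopifnot(is(x, "ArrayWeights"))
    x@weights
}
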