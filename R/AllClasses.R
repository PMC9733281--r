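#' @import methods
#' @importFrom stats approx dnorm pnorm qnorm rnorm rexp runif median sd var
#'   quantile optim lowess lm.wfit pt p.adjust setNames complete.cases
#'   model.matrix rchisq aov TukeyHSD
#' @importFrom utils read.delim write.table head
#' @importFrom graphics abline barplot boxplot legend lines
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Spot-level records for a single array
#'
#' One scanned array as extracted by image-analysis software: spot geometry
#' (block, row, column), probe identity and category, and the median
#' foreground and background fluorescence of every spot.
#'
#' @slot arrayId Character label for the array (usually the file name).
#' @slot spots A \code{data.frame} with columns \code{Block}, \code{Row},
#'   \code{Column}, \code{ID}, \code{Name}, \code{Category} (one of
#'   \code{"sample"}, \code{"control"}, \code{"empty"}), \code{Fg}, \code{Bg}
#'   and \code{Flag}.
#' @slot fgColumn,bgColumn Names of the source intensity columns.
#'
#' @export
setClass("SpotTable",
    representation(
        arrayId = "character",
        spots = "data.frame",
        fgColumn = "character",
        bgColumn = "character"
    )
)

setValidity("SpotTable", function(object) {
    need <- c("Block", "Row", "Column", "ID", "Name", "Category", "Fg",
        "Bg", "Flag")
    miss <- setdiff(need, names(object@spots))
    if (length(miss))
        return(paste("missing spot columns:", paste(miss, collapse = ", ")))
    sp <- object@spots
    if (anyDuplicated(sp[, c("Block", "Row", "Column")]))
        return("duplicate (Block,Row,Column) spot coordinates")
    if (any(!is.finite(sp$Fg)) || any(!is.finite(sp$Bg)))
        return("non-finite foreground/background intensities")
    if (any(sp$Fg < 0) || any(sp$Bg < 0))
        return("negative foreground/background intensities")
    if (!all(sp$Category %in% c("sample", "control", "empty")))
        return("Category must be sample, control or empty")
    TRUE
})

#' Aligned set of single-channel protein arrays
#'
#' Extends \linkS4class{SummarizedExperiment} with assays \code{fg}
#' (foreground, or corrected/log2 expression as processing proceeds) and
#' \code{bg} (background), spot annotation as \code{rowData} and the sample
#' targets as \code{colData}.  \code{metadata()} tracks \code{logState}
#' (\code{"linear"} or \code{"log2"}) and an ordered \code{processing} log.
#'
#' @export
setClass("ProteinArraySet", contains = "SummarizedExperiment")

setValidity("ProteinArraySet", function(object) {
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("fg", "bg") %in% an))
        return("assays 'fg' and 'bg' are required")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("Block", "Row", "Column", "ID", "Name", "Category")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        return(paste("missing rowData columns:",
            paste(miss, collapse = ", ")))
    ls <- S4Vectors::metadata(object)$logState
    if (is.null(ls) || !ls %in% c("linear", "log2"))
        return("metadata logState must be 'linear' or 'log2'")
    TRUE
})

#' Normal+exponential convolution model parameters
#'
#' Maximum-likelihood parameters of the normexp background model fitted to
#' background-subtracted intensities x = fg - bg: background ~
#' Normal(mu, sigma^2), signal ~ Exponential(mean alpha), plus the offset k
#' added after correction.
#'
#' @slot mu Background normal mean (fluorescence units).
#' @slot sigma Background normal standard deviation (> 0).
#' @slot alpha Exponential signal mean (> 0).
#' @slot offset Offset k added to corrected intensities (>= 0).
#' @slot logLik Log-likelihood at the optimum.
#' @slot converged Logical optimizer convergence flag.
#'
#' @export
setClass("NormexpParams",
    representation(
        mu = "numeric",
        sigma = "numeric",
        alpha = "numeric",
        offset = "numeric",
        logLik = "numeric",
        converged = "logical"
    ),
    prototype(offset = 0, converged = NA)
)

setValidity("NormexpParams", function(object) {
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma <= 0)
        return("sigma must be a single positive number")
    if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
        object@alpha <= 0)
        return("alpha must be a single positive number")
    if (!is.finite(object@mu)) return("mu must be finite")
    if (object@offset < 0) return("offset must be >= 0")
    TRUE
})

#' Per-array quality weights from REML scoring
#'
#' Log-variance factors gamma (sum-to-zero) and weights w = exp(-gamma) of
#' the heteroscedastic probe-wise linear model, estimated by restricted
#' maximum likelihood Fisher-scoring iterations aggregated over probes.
#'
#' @slot gamma Named per-array log-variance factors, summing to zero.
#' @slot weights Named per-array weights \code{exp(-gamma)}; product is 1.
#' @slot iterations Number of scoring iterations used.
#' @slot converged Logical convergence flag.
#'
#' @export
setClass("ArrayWeights",
    representation(
        gamma = "numeric",
        weights = "numeric",
        iterations = "integer",
        converged = "logical"
    )
)

setValidity("ArrayWeights", function(object) {
    if (length(object@gamma) != length(object@weights))
        return("gamma and weights lengths differ")
    if (abs(sum(object@gamma)) > 1e-6)
        return("gamma must sum to zero")
    if (any(object@weights <= 0))
        return("weights must be positive")
    TRUE
})

#' Probe-wise weighted least-squares fits
#'
#' Group-mean coefficients, residual standard deviations and residual
#' degrees of freedom from probe-wise weighted linear models, together with
#' the unscaled covariance of the coefficients needed for contrasts.
#'
#' @slot coefficients probes x coefficients matrix of estimates (log2 units).
#' @slot cov.unscaled coefficients x coefficients x probes array of
#'   \eqn{(X'WX)^{-1}} matrices (NA where inestimable).
#' @slot sigma Residual standard deviation per probe (log2 units).
#' @slot df.residual Residual degrees of freedom per probe.
#' @slot design The design matrix used.
#' @slot weights The per-array prior weights used.
#'
#' @export
setClass("ProbeFit",
    representation(
        coefficients = "matrix",
        cov.unscaled = "array",
        sigma = "numeric",
        df.residual = "numeric",
        design = "matrix",
        weights = "numeric"
    )
)

#' Empirical-Bayes moderated statistics
#'
#' Moderated t-statistics per contrast after squeezing probe-wise residual
#' variances towards a common prior: prior df d0 (possibly infinite), prior
#' variance s0^2, posterior variances, two-sided p-values and
#' Benjamini-Hochberg adjusted p-values.
#'
#' @slot contrasts coefficients x contrasts matrix.
#' @slot logFC probes x contrasts matrix of contrast estimates.
#' @slot stdev.unscaled probes x contrasts matrix of unscaled standard
#'   deviations of the contrast estimates.
#' @slot df.prior Prior degrees of freedom (may be \code{Inf}).
#' @slot var.prior Prior variance s0^2.
#' @slot var.post Posterior (squeezed) variance per probe.
#' @slot t,p.value,adj.p.value probes x contrasts matrices.
#' @slot df.total Total degrees of freedom per probe.
#' @slot sigma,df.residual Carried over from the \linkS4class{ProbeFit}.
#'
#' @export
setClass("ModeratedStats",
    representation(
        contrasts = "matrix",
        logFC = "matrix",
        stdev.unscaled = "matrix",
        df.prior = "numeric",
        var.prior = "numeric",
        var.post = "numeric",
        t = "matrix",
        p.value = "matrix",
        adj.p.value = "matrix",
        df.total = "numeric",
        sigma = "numeric",
        df.residual = "numeric"
    )
)
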