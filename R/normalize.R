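## The four normalization methods compared for single-channel arrays:
## none (plain log2), scale (linear-scale median equalization), quantile
## (rank-mean), and fast cyclic loess against the average array.

#' Log2-transform a background-corrected set
#'
#' Non-positive corrected intensities become missing; this is where
#' subtraction-style corrections pay their missing-value cost.
#'
#' @param aset Background-corrected linear-scale
#'   \linkS4class{ProteinArraySet}.
#' @return List with \code{arrays} (log2-scale set, method "none") and
#'   \code{Y} (the log2 matrix).
#' @export
toLog2 <- function(aset) {
    stopifnot(is(aset, "ProteinArraySet"))
    if (logState(aset) != "linear")
        stop("array set is already on the log2 scale")
    E <- fgIntensity(aset)
    Y <- ifelse(is.finite(E) & E > 0, log2(pmax(E, .Machine$double.xmin)),
        NA_real_)
    dimnames(Y) <- dimnames(E)
    fgIntensity(aset) <- Y
    aset <- setLogState(aset, "log2")
    aset <- recordStep(aset, "normalize:none")
    list(arrays = aset, Y = Y)
}

#' Scale normalization on the linear scale
#'
#' Each array is multiplied by f_j = g / median_j, where g is the
#' geometric mean of the per-array medians (missing values excluded), so
#' all arrays end up with the same median; the result is then
#' log2-transformed.
#'
#' @param aset Background-corrected linear-scale
#'   \linkS4class{ProteinArraySet}.
#' @return List with \code{arrays} (log2-scale set), \code{Y} and
#'   \code{factors} (per-array scale factors).
#' @export
normalizeScaleSet <- function(aset) {
    stopifnot(is(aset, "ProteinArraySet"), logState(aset) == "linear")
    E <- fgIntensity(aset)
    med <- apply(E, 2, median, na.rm = TRUE)
    if (any(!is.finite(med)) || any(med <= 0))
        stop("scale normalization needs positive per-array medians")
    g <- exp(mean(log(med)))
    f <- g / med
    E <- sweep(E, 2, f, `*`)
    fgIntensity(aset) <- E
    out <- toLog2(aset)
    out$arrays <- recordStep(out$arrays, sprintf("normalize:scale (g=%.4g)",
        g))
    ## overwrite the "none" log entry position: keep both entries, the
    ## scale entry is authoritative
    out$factors <- setNames(f, colnames(E))
    out
}

#' Quantile normalization (rank-mean)
#'
#' Classic rank-mean algorithm on a log2 matrix: the reference
#' distribution is the mean of the column-sorted values over complete
#' rows; each column is re-assigned its reference values by rank, tied
#' values receiving the mean of their tied reference values.  Rows with
#' missing values are rank-interpolated against the reference.  Output
#' columns have identical sorted values.
#'
#' @param Y Log2 matrix (missing values allowed).
#' @return List with \code{Y} (normalized matrix) and \code{reference}
#'   (the reference distribution).
#' @export
normalizeQuantile <- function(Y) {
    if (any(colSums(is.finite(Y)) == 0L))
        stop("quantile normalization: a column is entirely missing")
    cc <- which(complete.cases(Y))
    if (length(cc) < 2L)
        stop("quantile normalization needs at least 2 complete rows")
    ref <- rowMeans(apply(Y[cc, , drop = FALSE], 2, sort))
    m <- length(ref)
    refProbs <- if (m > 1) (seq_len(m) - 1) / (m - 1) else 0.5
    out <- Y
    for (j in seq_len(ncol(Y))) {
        ok <- is.finite(Y[, j])
        v <- Y[ok, j]
        n <- length(v)
        r <- rank(v, ties.method = "average")
        p <- if (n > 1) (r - 1) / (n - 1) else 0.5
        out[ok, j] <- approx(refProbs, ref, xout = p, rule = 2,
            ties = "ordered")$y
    }
    list(Y = out, reference = ref)
}

#' Fast cyclic loess normalization
#'
#' Each array is normalized against the reference array -- the probe-wise
#' mean of all arrays -- by subtracting a robust local-linear loess fit of
#' M = Y_j - ref on A = (Y_j + ref)/2, iterated a few times with the
#' reference recomputed at the start of each pass.
#'
#' @param Y Log2 matrix with >= 2 columns.
#' @param span Loess span in (0, 1], default 0.7.
#' @param iterations Number of full passes, default 3.
#' @return List with \code{Y} (normalized matrix), \code{span} and
#'   \code{iterations}.
#' @export
#'
#' @examples
#' Y <- cbind(a = rnorm(200, 8), b = rnorm(200, 8))
#' str(normalizeCyclicLoessFast(Y)$Y)
normalizeCyclicLoessFast <- function(Y, span = 0.7, iterations = 3L) {
    if (ncol(Y) < 2L) stop("cyclic loess needs at least 2 arrays")
    if (span <= 0 || span > 1) stop("span must be in (0, 1]")
    for (it in seq_len(iterations)) {
        ref <- rowMeans(Y, na.rm = TRUE)
        for (j in seq_len(ncol(Y))) {
            M <- Y[, j] - ref
            ## the abscissa is the reference itself: regressing on
            ## (Y_j + ref)/2 would put the array's own noise into the
            ## regressor and let the smoother strip array-specific signal
            A <- ref
            ok <- is.finite(M) & is.finite(A)
            if (sum(ok) < 10L)
                stop("cyclic loess: fewer than 10 complete points in ",
                    "array ", j)
            ## robust local-linear smoother with tricube weights and 2
            ## robustness iterations
            fit <- lowess(A[ok], M[ok], f = span, iter = 2)
            adj <- approx(fit$x, fit$y, xout = A, rule = 2,
                ties = mean)$y
            Y[ok, j] <- Y[ok, j] - adj[ok]
        }
    }
    list(Y = Y, span = span, iterations = iterations)
}

#' Apply a named normalization method to a corrected set
#'
#' Dispatch helper used by the pipeline: \code{"none"}, \code{"scale"},
#' \code{"quantile"} or \code{"cyclicloess"}.  Scale operates on the
#' linear intensities; quantile and cyclic loess on the log2 matrix.
#'
#' @param aset Background-corrected linear-scale
#'   \linkS4class{ProteinArraySet}.
#' @param method Normalization method name.
#' @param span,iterations Cyclic loess settings.
#' @return List with \code{arrays} (log2-scale \linkS4class{ProteinArraySet})
#'   and method-specific parameter entries.
#' @export
normalizeSet <- function(aset, method = c("cyclicloess", "none", "scale",
                         "quantile"), span = 0.7, iterations = 3L) {
    method <- match.arg(method)
    if (method == "scale") return(normalizeScaleSet(aset))
    out <- toLog2(aset)
    if (method == "none") return(out)
    res <- switch(method,
        quantile = normalizeQuantile(out$Y),
        cyclicloess = normalizeCyclicLoessFast(out$Y, span = span,
            iterations = iterations))
    fgIntensity(out$arrays) <- res$Y
    out$arrays <- recordStep(out$arrays,
        if (method == "quantile") "normalize:quantile" else
            sprintf("normalize:cyclicloess (span=%g, iter=%d)", span,
                iterations))
    out$Y <- res$Y
    out[names(res)[-1]] <- res[-1]
    out
}
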