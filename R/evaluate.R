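## Method-comparison metrics: MA values of one array against the
## leave-one-out average, control-replicate coefficients of variation,
## residual-variance-versus-intensity precision curves, and the
## filtering-strategy comparison (equal weights / REML weights / drop the
## lowest-weight arrays).

#' MA values of one array against the average of the others
#'
#' x = Y_j and y = the probe-wise mean of all other arrays (missing-aware);
#' M = x - y, A = (x + y)/2.
#'
#' @param Y Log2 matrix, probes x arrays (>= 2 arrays).
#' @param j Array (column) index.
#' @return List with \code{table} (\code{data.frame} of M, A per probe),
#'   \code{maxAbsM} and \code{fracMissing} (fraction of probes whose M is
#'   undefined).
#' @export
#'
#' @examples
#' Y <- cbind(a = c(3, 4), b = c(1, 4), c = c(1, 4))
#' maVersusRest(Y, 1)$table
maVersusRest <- function(Y, j) {
    Y <- as.matrix(Y)
    if (ncol(Y) < 2L) stop("need at least 2 arrays")
    if (j < 1L || j > ncol(Y)) stop("array index out of range: ", j)
    x <- Y[, j]
    y <- rowMeans(Y[, -j, drop = FALSE], na.rm = TRUE)
    y[!is.finite(y)] <- NA_real_
    M <- x - y
    A <- (x + y) / 2
    ids <- rownames(Y)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(Y)))
    tab <- data.frame(ID = ids, M = M, A = A, array = j,
        stringsAsFactors = FALSE)
    list(table = tab,
        maxAbsM = if (any(is.finite(M))) max(abs(M), na.rm = TRUE)
            else NA_real_,
        fracMissing = mean(!is.finite(M)))
}

#' Replicate coefficients of variation for control probes
#'
#' Per control probe per array, CV = sd/mean over the replicate spots, in
#' percent.  Computed on the linear intensity scale by default (log2
#' inputs are un-logged first); a log2-scale option is exposed.  The CV is
#' missing when fewer than 2 finite replicates exist or the mean is
#' non-positive.
#'
#' @param Y Spot-level matrix (spots x arrays).
#' @param probes Spot annotation with \code{ID} aligned to \code{Y}.
#' @param controls Character vector of control probe IDs.
#' @param inputLog2 Is \code{Y} on the log2 scale?
#' @param scale Scale on which to compute the CV: \code{"linear"}
#'   (default) or \code{"log2"}.
#' @param across \code{"spots"} (default): one CV per control per array
#'   over its replicate spots, measuring within-array printing/scanning
#'   variability.  \code{"arrays"}: one CV per control over the per-array
#'   replicate means, measuring cross-array reproducibility -- the
#'   quantity a normalization method can actually improve, since any
#'   per-array monotone correction moves all replicate spots of a control
#'   together.
#' @return \code{data.frame} with columns \code{ID}, \code{SampleID}
#'   (\code{"all"} for \code{across = "arrays"}), \code{cv} (percent).
#' @export
controlCV <- function(Y, probes, controls, inputLog2 = TRUE,
                      scale = c("linear", "log2"),
                      across = c("spots", "arrays")) {
    scale <- match.arg(scale)
    across <- match.arg(across)
    Y <- as.matrix(Y)
    stopifnot(nrow(Y) == nrow(probes))
    unknown <- setdiff(controls, probes$ID)
    if (length(unknown))
        stop("unknown control probe(s): ", paste(unknown, collapse = ", "))
    V <- if (inputLog2 && scale == "linear") 2^Y
        else if (!inputLog2 && scale == "log2")
            ifelse(Y > 0, log2(Y), NA_real_)
        else Y
    cvOf <- function(v) {
        v <- v[is.finite(v)]
        if (length(v) >= 2L && mean(v) > 0) 100 * sd(v) / mean(v)
        else NA_real_
    }
    out <- do.call(rbind, lapply(controls, function(id) {
        idx <- which(probes$ID == id)
        if (across == "arrays") {
            means <- colMeans(V[idx, , drop = FALSE], na.rm = TRUE)
            data.frame(ID = id, SampleID = "all", cv = cvOf(means),
                stringsAsFactors = FALSE)
        } else {
            do.call(rbind, lapply(seq_len(ncol(V)), function(j)
                data.frame(ID = id,
                    SampleID = colnames(V)[j] %||% as.character(j),
                    cv = cvOf(V[idx, j]), stringsAsFactors = FALSE)))
        }
    }))
    rownames(out) <- NULL
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residual-variance versus intensity trend
#'
#' Probe-wise residual variances from \code{\link{fitProbewise}} against
#' the probe mean log2 intensity, with A rank-standardized to a common
#' grid so different correction methods are comparable, and a robust
#' local-linear smooth of log2 variance on standardized A.
#'
#' @param Y Log2 matrix, probes x arrays.
#' @param design Design matrix for the probe-wise fits.
#' @param span Smoother span (default 0.5).
#' @return List with \code{table} (\code{data.frame} of A, standardized A,
#'   sigma2 and log2 sigma2 per probe with positive residual df),
#'   \code{curve} (\code{data.frame} of the smooth over the observed
#'   range) and \code{log2Var} (the log2-variance distribution, for
#'   box-plot style summaries).
#' @export
varianceTrend <- function(Y, design, span = 0.5) {
    fit <- fitProbewise(Y, design)
    ok <- fit@df.residual >= 1 & is.finite(fit@sigma)
    if (!any(ok)) stop("no probes with positive residual df")
    s2 <- fit@sigma[ok]^2
    A <- rowMeans(as.matrix(Y), na.rm = TRUE)[ok]
    Astd <- (rank(A) - 0.5) / length(A)
    l2v <- ifelse(s2 > 0, log2(s2), NA_real_)
    okv <- is.finite(l2v)
    curve <- if (sum(okv) >= 10L) {
        sm <- lowess(Astd[okv], l2v[okv], f = span, iter = 2)
        data.frame(Astd = sm$x, log2Var = sm$y)
    } else data.frame(Astd = numeric(0), log2Var = numeric(0))
    list(table = data.frame(A = A, Astd = Astd, sigma2 = s2,
            log2Var = l2v),
        curve = curve,
        log2Var = l2v[okv])
}

#' Compare array-filtering strategies
#'
#' Runs the weighted differential-expression analysis three ways -- equal
#' weights, REML array weights, and removal of the \code{nDrop}
#' lowest-weight arrays -- and tabulates the moderated-t and adjusted-p
#' distributions per strategy.
#'
#' @param E Consolidated expression matrix, proteins x arrays (log2).
#' @param targets Targets \code{data.frame} aligned with the columns.
#' @param comparisons Contrast strings, e.g. \code{"B-A"}.
#' @param weights Optional precomputed \linkS4class{ArrayWeights}.
#' @param nDrop Arrays to remove for the filtering strategy (default 2).
#' @param alpha Significance level used in the per-strategy summaries.
#' @return List of class \code{"filteringComparison"} with one element per
#'   strategy (\code{equal}, \code{weighted}, \code{dropped}), each
#'   holding the \linkS4class{ModeratedStats}, its ranked table, and
#'   summary statistics; plus the weights used.
#' @export
compareFiltering <- function(E, targets, comparisons, weights = NULL,
                             nDrop = 2L, alpha = 0.05) {
    design <- conditionDesign(targets)
    cm <- makeComparisons(targets, comparisons)
    if (is.null(weights)) weights <- fitArrayWeights(E, design)
    strategies <- list()
    runOne <- function(Y, tg, w) {
        X <- conditionDesign(tg)
        fit <- fitProbewise(Y, X, w)
        st <- moderateStats(fit, cm)
        tab <- rankedTable(st, 1L, alpha)
        list(stats = st, table = tab,
            summary = data.frame(
                meanAbsT = mean(abs(st@t[, 1]), na.rm = TRUE),
                nSigRaw = sum(tab$p.value < alpha, na.rm = TRUE),
                nSigAdj = sum(tab$adj.p.value < alpha, na.rm = TRUE)))
    }
    strategies$equal <- runOne(E, targets, NULL)
    strategies$weighted <- runOne(E, targets, weightValues(weights))
    red <- dropLowestArrays(E, weights, nDrop = nDrop, targets = targets)
    strategies$dropped <- runOne(red$Y, red$targets, NULL)
    strategies$weights <- weights
    strategies$dropped$removed <- red$dropped
    class(strategies) <- "filteringComparison"
    strategies
}
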