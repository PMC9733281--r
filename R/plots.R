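## Static base-graphics summaries of the evaluation metrics: MA scatter,
## control-CV distributions by method, per-array weights, and the
## residual-variance trend.

#' One-way ANOVA and Tukey HSD on control CVs by method
#'
#' Compares mean control CVs between normalization (or correction)
#' methods with a plain one-way ANOVA F-test followed by Tukey's honest
#' significant differences.
#'
#' @param cvs Numeric vector of CVs (percent).
#' @param method Factor (or character) of the same length naming the
#'   method each CV came from.
#' @return List with \code{p.value} (ANOVA F-test), \code{anova} (the
#'   \code{aov} summary) and \code{tukey} (\code{TukeyHSD} table).
#' @export
compareCVs <- function(cvs, method) {
    df <- data.frame(cv = cvs, method = factor(method))
    df <- df[is.finite(df$cv), , drop = FALSE]
    if (nlevels(droplevels(df$method)) < 2L)
        stop("need CVs from at least two methods")
    fit <- aov(cv ~ method, data = df)
    list(p.value = summary(fit)[[1]][["Pr(>F)"]][1],
        anova = summary(fit),
        tukey = TukeyHSD(fit)$method)
}

#' Evaluation plots
#'
#' \code{plotMA} draws M versus A for one array against the average of
#' the others; \code{plotControlCV} box-plots control CVs by method;
#' \code{plotArrayWeights} bar-plots per-array weights with a reference
#' line at 1; \code{plotVarianceTrend} draws the smoothed log2 residual
#' variance against standardized intensity for one or more methods.
#'
#' @param ma Result of \code{\link{maVersusRest}}.
#' @param ... Further arguments to the underlying base-graphics call.
#' @name evaluation-plots
#' @export
plotMA <- function(ma, ...) {
    tab <- ma$table
    plot(tab$A, tab$M, pch = 16, cex = 0.4,
        col = grDevices::grey(0.4, 0.5),
        xlab = "A (average log2 intensity)",
        ylab = "M (log2 ratio vs other arrays)", ...)
    graphics::abline(h = 0, col = "red3")
    invisible(ma)
}

#' @rdname evaluation-plots
#' @param cvs,method As in \code{\link{compareCVs}}.
#' @export
plotControlCV <- function(cvs, method, ...) {
    graphics::boxplot(split(cvs, method), ylab = "control CV (%)", ...)
    invisible(NULL)
}

#' @rdname evaluation-plots
#' @param weights An \linkS4class{ArrayWeights}.
#' @export
plotArrayWeights <- function(weights, ...) {
    w <- weightValues(weights)
    graphics::barplot(w, ylab = "array weight", las = 2, ...)
    graphics::abline(h = 1, lty = 2)
    invisible(w)
}

#' @rdname evaluation-plots
#' @param trends Named list of \code{\link{varianceTrend}} results.
#' @export
plotVarianceTrend <- function(trends, ...) {
    if (!is.null(trends$curve)) trends <- list(trend = trends)
    ylim <- range(unlist(lapply(trends, function(tr) tr$curve$log2Var)),
        finite = TRUE)
    plot(NA, xlim = c(0, 1), ylim = ylim,
        xlab = "standardized A (rank)", ylab = "log2 residual variance",
        ...)
    for (i in seq_along(trends))
        graphics::lines(trends[[i]]$curve$Astd, trends[[i]]$curve$log2Var,
            col = i, lwd = 2)
    if (length(trends) > 1L)
        graphics::legend("topright", legend = names(trends),
            col = seq_along(trends), lwd = 2, bty = "n")
    invisible(NULL)
}
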