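## Weighted probe-wise linear models, contrasts from the sample metadata,
## empirical-Bayes moderation of the residual variances, and
## Benjamini-Hochberg adjustment.

#' Group-means design matrix from a targets table
#'
#' One indicator column per condition level; used with explicit contrasts
#' so multi-group designs are uniform.
#'
#' @param targets Targets \code{data.frame} with a \code{Condition} column.
#' @return Design matrix (arrays x conditions).
#' @export
conditionDesign <- function(targets) {
    f <- factor(targets$Condition)
    X <- model.matrix(~ 0 + f)
    colnames(X) <- levels(f)
    rownames(X) <- if ("SampleID" %in% names(targets)) targets$SampleID
    X
}

#' Contrast matrix from "A-B" comparison strings
#'
#' @param targets Targets \code{data.frame} with a \code{Condition} column.
#' @param comparisons Character vector like \code{"PDAC-control"}; each
#'   level must exist in \code{Condition} and the two sides must differ.
#' @return Conditions x comparisons contrast matrix.
#' @export
#'
#' @examples
#' tg <- data.frame(Condition = rep(c("PDAC", "control"), each = 4))
#' makeComparisons(tg, "PDAC-control")
makeComparisons <- function(targets, comparisons) {
    lev <- levels(factor(targets$Condition))
    cm <- matrix(0, length(lev), length(comparisons),
        dimnames = list(lev, comparisons))
    for (i in seq_along(comparisons)) {
        parts <- strsplit(comparisons[i], "-", fixed = TRUE)[[1]]
        if (length(parts) != 2L)
            stop("comparison must be of the form 'A-B': ", comparisons[i])
        bad <- setdiff(parts, lev)
        if (length(bad))
            stop("unknown condition level(s): ", paste(bad, collapse = ", "))
        if (parts[1] == parts[2])
            stop("degenerate contrast (zero column): ", comparisons[i])
        cm[parts[1], i] <- 1
        cm[parts[2], i] <- -1
    }
    cm
}

#' Probe-wise weighted least squares
#'
#' Fits each probe by weighted least squares with the per-array prior
#' weights; missing values reduce the residual degrees of freedom per
#' probe.  Probes observed on fewer arrays than the design rank get
#' coefficients where estimable and no variance estimate.
#'
#' @param Y Expression matrix, probes x arrays (log2).
#' @param design Design matrix (arrays x coefficients).
#' @param weights Per-array prior weights, an \linkS4class{ArrayWeights},
#'   or \code{NULL} for equal weights.
#' @return A \linkS4class{ProbeFit}.
#' @export
fitProbewise <- function(Y, design, weights = NULL) {
    Y <- as.matrix(Y)
    design <- as.matrix(design)
    J <- ncol(Y)
    p <- ncol(design)
    w <- if (is.null(weights)) rep(1, J)
        else if (is(weights, "ArrayWeights")) weightValues(weights)
        else weights
    if (length(w) != J) stop("weights length must match array count")
    if (any(w <= 0)) stop("weights must be positive")
    P <- nrow(Y)
    coefs <- matrix(NA_real_, P, p,
        dimnames = list(rownames(Y), colnames(design)))
    covun <- array(NA_real_, c(p, p, P))
    sigma <- rep(NA_real_, P)
    dfres <- rep(0, P)
    for (g in seq_len(P)) {
        obs <- which(is.finite(Y[g, ]))
        n <- length(obs)
        if (n == 0L) next
        Xg <- design[obs, , drop = FALSE]
        qrX <- qr(Xg)
        if (qrX$rank < p) {
            ## partially estimable: fill what a reduced fit identifies
            fit <- lm.wfit(Xg, Y[g, obs], w[obs])
            est <- !is.na(fit$coefficients)
            coefs[g, est] <- fit$coefficients[est]
            next
        }
        fit <- lm.wfit(Xg, Y[g, obs], w[obs])
        coefs[g, ] <- fit$coefficients
        xtwx <- crossprod(Xg * sqrt(w[obs]))
        covun[, , g] <- solve(xtwx)
        dfres[g] <- n - p
        if (dfres[g] > 0) {
            rss <- sum(w[obs] * fit$residuals^2)
            sigma[g] <- sqrt(rss / dfres[g])
        }
    }
    new("ProbeFit", coefficients = coefs, cov.unscaled = covun,
        sigma = sigma, df.residual = dfres, design = design,
        weights = setNames(w, colnames(Y)))
}

#' Invert the trigamma function
#'
#' Newton iteration solving \code{trigamma(y) = x} for \code{y > 0},
#' started at \code{0.5 + 1/x}.
#'
#' @param x Positive value.
#' @param tol Convergence tolerance (default 1e-8).
#' @return The solution y, \code{Inf} for \code{x <= 0}.
#' @export
trigammaInverse <- function(x, tol = 1e-8) {
    if (!is.finite(x)) return(NA_real_)
    if (x <= 0) return(Inf)
    y <- 0.5 + 1 / x
    for (i in 1:100) {
        f <- trigamma(y) - x
        step <- f / psigamma(y, 2L)
        yNew <- y - step
        if (yNew <= 0) yNew <- y / 2
        if (abs(yNew - y) < tol * max(1, y)) return(yNew)
        y <- yNew
    }
    y
}

#' Empirical-Bayes moderation of probe variances
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 by
#' moment matching on \code{e_g = log s_g^2 - digamma(d_g/2) +
#' log(d_g/2)}: the trigamma equation \code{trigamma(d0/2) = mean[(e_g -
#' mean(e))^2 n/(n-1) - trigamma(d_g/2)]} is solved by Newton inversion of
#' the trigamma function, with d0 = Inf when the right-hand side is
#' non-positive (no excess dispersion).  Posterior variances are
#' \code{(d0 s0^2 + d_g s_g^2)/(d0 + d_g)}; moderated t-statistics are
#' computed per contrast on d0 + d_g degrees of freedom (normal limit when
#' d0 is infinite) with two-sided p-values and Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param fit A \linkS4class{ProbeFit}.
#' @param contrasts Coefficients x contrasts matrix (default: identity,
#'   one contrast per design coefficient).
#' @param priorDf Optional override of the estimated d0 (e.g. 0 for
#'   ordinary t-statistics); the prior variance is still estimated.
#' @return A \linkS4class{ModeratedStats}.
#' @export
moderateStats <- function(fit, contrasts = NULL, priorDf = NULL) {
    stopifnot(is(fit, "ProbeFit"))
    p <- ncol(fit@coefficients)
    if (is.null(contrasts)) {
        contrasts <- diag(p)
        dimnames(contrasts) <- list(colnames(fit@coefficients),
            colnames(fit@coefficients))
    }
    contrasts <- as.matrix(contrasts)
    ok <- which(fit@df.residual > 0 & is.finite(fit@sigma))
    if (is.null(priorDf) && length(ok) < 3L)
        stop("need at least 3 probes with positive residual df")
    s2 <- fit@sigma[ok]^2
    if (all(s2 == 0)) stop("all residual variances are zero")
    dg <- fit@df.residual[ok]
    ## work on strictly positive variances; zeros would send log to -Inf
    pos <- s2 > 0
    e <- log(s2[pos]) - digamma(dg[pos] / 2) + log(dg[pos] / 2)
    ebar <- mean(e)
    n <- length(e)
    if (is.null(priorDf)) {
        if (n < 3L) stop("need at least 3 probes with positive variance")
        rhs <- mean((e - ebar)^2 * n / (n - 1) - trigamma(dg[pos] / 2))
        d0 <- if (rhs > 0) 2 * trigammaInverse(rhs) else Inf
    } else d0 <- priorDf
    ## infinite d0 says all true variances coincide; their joint MLE is the
    ## arithmetic mean, which also keeps the degenerate all-equal case an
    ## exact fixed point
    s02 <- if (is.finite(d0) && d0 > 0)
        exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    else mean(s2[pos])
    P <- nrow(fit@coefficients)
    varPost <- rep(NA_real_, P)
    sg2 <- fit@sigma^2
    dgAll <- fit@df.residual
    est <- dgAll > 0 & is.finite(sg2)
    varPost[est] <- if (is.infinite(d0)) s02
        else if (d0 == 0) sg2[est]
        else (d0 * s02 + dgAll[est] * sg2[est]) / (d0 + dgAll[est])
    nc <- ncol(contrasts)
    logFC <- se <- matrix(NA_real_, P, nc,
        dimnames = list(rownames(fit@coefficients), colnames(contrasts)))
    for (g in seq_len(P)) {
        b <- fit@coefficients[g, ]
        if (anyNA(b)) next
        V <- fit@cov.unscaled[, , g]
        if (anyNA(V)) { logFC[g, ] <- drop(crossprod(contrasts, b)); next }
        logFC[g, ] <- drop(crossprod(contrasts, b))
        se[g, ] <- sqrt(diag(t(contrasts) %*% V %*% contrasts))
    }
    tstat <- logFC / (se * sqrt(varPost))
    dfTotal <- ifelse(est, d0 + dgAll, NA_real_)
    pval <- tstat
    for (k in seq_len(nc)) {
        tk <- tstat[, k]
        pk <- rep(NA_real_, P)
        fin <- is.finite(tk) & is.finite(dfTotal)
        inf <- is.finite(tk) & !is.finite(dfTotal) & est
        pk[fin] <- 2 * pt(-abs(tk[fin]), df = dfTotal[fin])
        pk[inf] <- 2 * pnorm(-abs(tk[inf]))
        pval[, k] <- pk
    }
    adj <- apply(pval, 2, function(p) {
        out <- rep(NA_real_, length(p))
        out[!is.na(p)] <- bhAdjust(p[!is.na(p)])
        out
    })
    dim(adj) <- dim(pval); dimnames(adj) <- dimnames(pval)
    new("ModeratedStats", contrasts = contrasts, logFC = logFC,
        stdev.unscaled = se, df.prior = d0, var.prior = s02,
        var.post = varPost, t = tstat, p.value = pval,
        adj.p.value = adj, df.total = dfTotal, sigma = fit@sigma,
        df.residual = fit@df.residual)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper over the standard step-up rule: sort ascending,
#' \code{q_(i) = min over k >= i of m p_(k)/k}, capped at 1, returned in
#' input order.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must be finite and in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Ranked differential-expression table
#'
#' Probes sorted by raw p-value with log2 fold change, moderated t, raw
#' and adjusted p-values and a significance flag at \code{alpha} (on the
#' raw p-value; the adjusted p-value is reported alongside).
#'
#' @param stats A \linkS4class{ModeratedStats}.
#' @param contrast Contrast column name or index (default 1).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return \code{data.frame} with one row per probe, p-ascending.
#' @export
rankedTable <- function(stats, contrast = 1L, alpha = 0.05) {
    stopifnot(is(stats, "ModeratedStats"))
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (!nrow(stats@t))
        return(data.frame(ID = character(0), logFC = numeric(0),
            t = numeric(0), p.value = numeric(0),
            adj.p.value = numeric(0), significant = logical(0)))
    ids <- rownames(stats@t)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(stats@t)))
    df <- data.frame(ID = ids,
        logFC = stats@logFC[, contrast],
        t = stats@t[, contrast],
        p.value = stats@p.value[, contrast],
        adj.p.value = stats@adj.p.value[, contrast],
        stringsAsFactors = FALSE)
    df$significant <- !is.na(df$p.value) & df$p.value < alpha
    df[order(df$p.value), , drop = FALSE]
}
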