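## Per-array quality weights from a heteroscedastic probe-wise linear
## model: y_g = X beta_g + e_g with Var(e_gj) = sigma_g^2 exp(z_j' gamma),
## z encoding array indicators under a sum-to-zero constraint.  gamma is
## estimated by Fisher scoring on the restricted (REML) log-likelihood
## aggregated over probes, with sigma_g^2 profiled out per probe.

#' Estimate per-array quality weights by REML scoring
#'
#' At each iteration every probe is fitted by weighted least squares with
#' the current weights w = exp(-Z gamma); squared standardized residuals
#' and hat-matrix leverages form the score and expected information for
#' gamma, which is updated until max|change| < \code{tol} or \code{maxit}
#' iterations.  Probes with missing values participate with their
#' available arrays (leverages computed on the reduced design); probes
#' without positive residual degrees of freedom are skipped.  The
#' sum-to-zero constraint makes the weights multiply to 1.
#'
#' @param Y Log2 expression matrix, probes x arrays.
#' @param design Design matrix (arrays x coefficients), full column rank.
#' @param maxit,tol Scoring iteration limit and convergence tolerance on
#'   max|change in gamma|.
#' @return An \linkS4class{ArrayWeights}.
#' @export
#'
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(200 * 6), 200, 6)
#' X <- cbind(1, rep(0:1, each = 3))
#' fitArrayWeights(Y, X)
fitArrayWeights <- function(Y, design, maxit = 200L, tol = 1e-6) {
    Y <- as.matrix(Y)
    J <- ncol(Y)
    design <- as.matrix(design)
    p <- ncol(design)
    if (J < p + 2L)
        stop("need at least ", p + 2L, " arrays for ", p,
            " design coefficients")
    if (qr(design)$rank < p) stop("design matrix is singular")
    keep <- rowSums(is.finite(Y)) >= 2L
    Y <- Y[keep, , drop = FALSE]
    C <- stats::contr.sum(J)          # gamma = C eta, sum(gamma) = 0
    eta <- rep(0, J - 1L)
    iter <- 0L
    converged <- FALSE
    while (iter < maxit) {
        iter <- iter + 1L
        gamma <- drop(C %*% eta)
        w <- exp(-gamma)
        score <- rep(0, J - 1L)
        info <- matrix(0, J - 1L, J - 1L)
        for (g in seq_len(nrow(Y))) {
            obs <- which(is.finite(Y[g, ]))
            Xg <- design[obs, , drop = FALSE]
            qrX <- qr(Xg)
            n <- length(obs)
            if (n - qrX$rank < 1L) next
            wg <- w[obs]
            sw <- sqrt(wg)
            Xs <- Xg * sw
            qrS <- qr(Xs)
            Q <- qr.Q(qrS)[, seq_len(qrS$rank), drop = FALSE]
            H <- tcrossprod(Q)
            h <- diag(H)
            fit <- lm.wfit(Xg, Y[g, obs], wg)
            e <- fit$residuals
            rss <- sum(wg * e^2)
            dfg <- n - qrX$rank
            s2 <- rss / dfg
            if (!is.finite(s2) || s2 <= 0) next
            d <- wg * e^2 / s2
            Zg <- C[obs, , drop = FALSE]
            score <- score + 0.5 * drop(crossprod(Zg, d - (1 - h)))
            M <- diag(n) - H
            info <- info + 0.5 * crossprod(Zg, (M * M) %*% Zg)
        }
        ## pseudoinverse solve: directions the design renders unidentifiable
        ## (zero expected information) are left unchanged
        ev <- eigen(info, symmetric = TRUE)
        pos <- ev$values > max(ev$values, 0) * 1e-10
        if (!any(pos))
            stop("zero information for all array variance factors")
        V <- ev$vectors[, pos, drop = FALSE]
        step <- drop(V %*% (crossprod(V, score) / ev$values[pos]))
        etaNew <- eta + step
        delta <- max(abs(C %*% etaNew - C %*% eta))
        eta <- etaNew
        if (delta < tol) { converged <- TRUE; break }
    }
    gamma <- drop(C %*% eta)
    names(gamma) <- colnames(Y)
    w <- exp(-gamma)
    new("ArrayWeights", gamma = gamma, weights = w,
        iterations = iter, converged = converged)
}

#' Drop the lowest-weight arrays
#'
#' Removes the \code{nDrop} arrays with the lowest estimated weights (ties
#' broken by array order) ahead of further analysis -- the "filter by
#' weight" strategy.
#'
#' @param Y Expression matrix, probes x arrays.
#' @param weights An \linkS4class{ArrayWeights} (or numeric vector) over
#'   the columns of \code{Y}.
#' @param nDrop Number of arrays to remove (default 2).
#' @param targets Optional targets \code{data.frame} subset alongside.
#' @return List with \code{Y}, \code{targets} (reduced) and
#'   \code{dropped} (column names or indices removed).
#' @export
dropLowestArrays <- function(Y, weights, nDrop = 2L, targets = NULL) {
    w <- if (is(weights, "ArrayWeights")) weightValues(weights) else weights
    if (length(w) != ncol(Y))
        stop("weights length does not match number of arrays")
    if (nDrop >= ncol(Y))
        stop("cannot drop ", nDrop, " of ", ncol(Y), " arrays")
    if (nDrop == 0L)
        return(list(Y = Y, targets = targets, dropped = character(0)))
    dropIdx <- order(w)[seq_len(nDrop)]   # order() breaks ties by position
    dropped <- if (!is.null(colnames(Y))) colnames(Y)[dropIdx] else dropIdx
    list(Y = Y[, -dropIdx, drop = FALSE],
        targets = if (!is.null(targets)) targets[-dropIdx, , drop = FALSE],
        dropped = dropped)
}
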