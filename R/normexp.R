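## Normal + exponential convolution model for background correction.
##
## Observed background-subtracted intensity X = B + S with
## B ~ Normal(mu, sigma^2) and S ~ Exponential(mean alpha).  The marginal
## density is
##   f(x) = (1/alpha) exp((mu - x)/alpha + sigma^2/(2 alpha^2))
##          * Phi((x - mu - sigma^2/alpha)/sigma)
## and the corrected intensity is the posterior mean E[S | X = x], the mean
## of a Normal(x - mu - sigma^2/alpha, sigma^2) truncated to (0, Inf).

## negative log-likelihood under log-parametrization (mu, log sigma,
## log alpha).  With t = (x - mu)/sigma and a = sigma/alpha the exact
## log-density rearranges to
##   log f = -log alpha - t^2/2 + h(a - t),  h(u) = u^2/2 + log Phi(-u),
## which avoids the catastrophic cancellation between sigma^2/(2 alpha^2)
## and log Phi when alpha << sigma (the rearranged form tends exactly to
## the normal log-density in that limit); h is evaluated by its Mills
## asymptotic series for large u.
normexpNegLogLik <- function(theta, x) {
    mu <- theta[1]
    sigma <- exp(theta[2])
    alpha <- exp(theta[3])
    t <- (x - mu) / sigma
    u <- sigma / alpha - t
    h <- numeric(length(u))
    lo <- u < 10
    h[lo] <- u[lo]^2 / 2 + pnorm(-u[lo], log.p = TRUE)
    if (any(!lo)) {
        uh <- u[!lo]
        h[!lo] <- -log(uh) - 0.5 * log(2 * pi) +
            log1p(-1 / uh^2 + 3 / uh^4 - 15 / uh^6)
    }
    ll <- -log(alpha) - t^2 / 2 + h
    -sum(ll)
}

#' Fit the normexp convolution model by maximum likelihood
#'
#' Fits (mu, sigma, alpha) to background-subtracted intensities
#' x = fg - bg by unconstrained numerical optimization of the exact
#' log-likelihood under a log-parametrization of sigma and alpha.
#' Initialization is moment-based: mu0 is the 5th percentile of x, sigma0
#' the standard deviation of the mirrored lower tail below mu0, and alpha0
#' = max(mean(x) - mu0, small positive).
#'
#' @param x Numeric vector of background-subtracted intensities (>= 10
#'   finite values with positive spread).
#' @param tol Convergence tolerance on the objective (default 1e-8).
#' @return A \linkS4class{NormexpParams}.
#' @export
#'
#' @examples
#' set.seed(1)
#' x <- rnorm(5000, 100, 15) + rexp(5000, 1 / 200)
#' normexpFit(x)
normexpFit <- function(x, tol = 1e-8) {
    x <- x[is.finite(x)]
    if (length(x) < 10L)
        stop("need at least 10 finite values to fit the normexp model")
    if (sd(x) == 0)
        stop("cannot fit normexp model: values have no spread")
    mu0 <- quantile(x, 0.05, names = FALSE)
    tail <- x[x <= mu0] - mu0
    sigma0 <- sqrt(mean(c(tail, -tail)^2))
    if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- sd(x) / 10
    alpha0 <- max(mean(x) - mu0, sigma0 / 10, 1e-6)
    theta0 <- c(mu0, log(sigma0), log(alpha0))
    fit <- optim(theta0, normexpNegLogLik, x = x, method = "Nelder-Mead",
        control = list(maxit = 5000, reltol = tol))
    ## polish with quasi-Newton from the simplex solution
    fit2 <- tryCatch(
        optim(fit$par, normexpNegLogLik, x = x, method = "BFGS",
            control = list(maxit = 500, reltol = tol)),
        error = function(e) fit)
    if (is.finite(fit2$value) && fit2$value <= fit$value) fit <- fit2
    new("NormexpParams",
        mu = fit$par[1],
        sigma = exp(fit$par[2]),
        alpha = exp(fit$par[3]),
        offset = 0,
        logLik = -fit$value,
        converged = fit$convergence == 0L)
}

#' Expected true signal given an observed intensity
#'
#' Returns E[S | X = x] under the normexp model: the mean of a normal with
#' mean \code{x - mu - sigma^2/alpha} and sd \code{sigma}, truncated to the
#' positive half-line, evaluated in log-space so the deep lower tail stays
#' numerically stable.  The result is strictly positive and strictly
#' increasing in x.  The offset in \code{params} is \emph{not} added here;
#' \code{\link{bgCorrectNormexp}} adds it after correction.
#'
#' @param x Finite numeric vector of (background-subtracted) intensities.
#' @param params A \linkS4class{NormexpParams}.
#' @return Numeric vector of corrected intensities, all > 0.
#' @export
normexpSignal <- function(x, params) {
    stopifnot(is(params, "NormexpParams"))
    if (any(!is.finite(c(params@mu, params@sigma, params@alpha))))
        stop("non-finite normexp parameters")
    if (any(!is.finite(x))) stop("x must be finite")
    sigma <- params@sigma
    muSX <- x - params@mu - sigma^2 / params@alpha
    z <- muSX / sigma
    ## truncated-normal mean: muSX + sigma * phi(z)/Phi(z), with the Mills
    ## ratio computed on the log scale
    out <- muSX + sigma * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
    ## guard against cancellation for extremely negative z
    bad <- !is.finite(out) | out <= 0
    if (any(bad)) out[bad] <- .Machine$double.eps * sigma
    out
}

#' Select the normexp offset by maximizing the prior degrees of freedom
#'
#' For each candidate offset k the set is normexp-corrected with offset k,
#' log2-transformed, cyclic-loess normalized, probe-wise linear models are
#' fitted and the empirical-Bayes prior degrees of freedom d0 estimated;
#' the k with the largest d0 (best stabilized variance) wins, first
#' occurrence on ties.  Infinite d0 outranks any finite value.
#'
#' @param aset Linear-scale, spot-filtered \linkS4class{ProteinArraySet}.
#' @param design Design matrix for the probe-wise fits (defaults to group
#'   means of \code{Condition}).
#' @param kGrid Candidate offsets (default \code{seq(0, 50, by = 5)}).
#' @param span,iterations Cyclic loess settings.
#' @return List with \code{k} (chosen offset) and \code{table}
#'   (\code{data.frame} of k, d0 and s0^2; failed candidates carry NA).
#' @export
selectOffset <- function(aset, design = NULL, kGrid = seq(0, 50, by = 5),
                         span = 0.7, iterations = 3L) {
    if (!length(kGrid)) stop("kGrid must be non-empty")
    if (any(kGrid < 0)) stop("offsets must be >= 0")
    if (is.null(design))
        design <- conditionDesign(arrayTargets(aset))
    ## the ML fit does not depend on k: correct once with k = 0, then add
    ## each candidate offset before the log2 step
    base <- bgCorrectNormexp(aset, k = 0)
    E0 <- fgIntensity(base)
    d0s <- s0s <- rep(NA_real_, length(kGrid))
    for (i in seq_along(kGrid)) {
        res <- tryCatch({
            Y <- log2(E0 + kGrid[i])
            Y[!is.finite(Y)] <- NA_real_
            Y <- normalizeCyclicLoessFast(Y, span = span,
                iterations = iterations)$Y
            fit <- fitProbewise(Y, design)
            eb <- moderateStats(fit)
            c(eb@df.prior, eb@var.prior)
        }, error = function(e) c(NA_real_, NA_real_))
        d0s[i] <- res[1]; s0s[i] <- res[2]
    }
    if (all(is.na(d0s)))
        stop("offset selection failed for every candidate k")
    best <- which(d0s == max(d0s, na.rm = TRUE))[1]
    list(k = kGrid[best],
        table = data.frame(k = kGrid, df.prior = d0s, var.prior = s0s))
}
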