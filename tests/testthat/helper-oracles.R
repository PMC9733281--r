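## Independent oracles and small fixture builders shared across tests.

## Quadrature oracle for the normexp conditional mean E[S | X = x]:
## integrates the convolution posterior s * f(s|x) directly, shifted in
## log space so the deep lower tail stays representable.
quadratureSignal <- function(x, mu, sigma, alpha) {
    muSX <- x - mu - sigma^2 / alpha
    logh <- function(s) dexp(s, 1 / alpha, log = TRUE) +
        dnorm(x - s, mu, sigma, log = TRUE)
    shift <- logh(max(muSX, 0))
    upper <- max(muSX + 12 * sigma, 12 * sigma)
    num <- integrate(function(s) s * exp(logh(s) - shift), 0, upper,
        rel.tol = 1e-11, subdivisions = 500L)$value
    den <- integrate(function(s) exp(logh(s) - shift), 0, upper,
        rel.tol = 1e-11, subdivisions = 500L)$value
    num / den
}

neParams <- function(mu, sigma, alpha) {
    new("NormexpParams", mu = mu, sigma = sigma, alpha = alpha,
        offset = 0, logLik = NA_real_, converged = TRUE)
}

## Brute-force quadratic-time BH step-up rule, straight from the
## definition: q_(i) = min_{k >= i} min(1, m p_(k) / k), in input order.
bhBruteForce <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(m * ps[i:m] / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
}

## Profiled REML log-likelihood of the heteroscedastic array-variance
## model, summed over probes; the brute-force oracle maximizes this with a
## generic optimizer.
remlCriterion <- function(Y, X, gamma) {
    lam <- exp(gamma)
    tot <- 0
    for (g in seq_len(nrow(Y))) {
        obs <- which(is.finite(Y[g, ]))
        Xg <- X[obs, , drop = FALSE]
        wts <- 1 / lam[obs]
        fit <- lm.wfit(Xg, Y[g, obs], wts)
        df <- length(obs) - qr(Xg)$rank
        if (df < 1L) next
        rss <- sum(wts * fit$residuals^2)
        xtwx <- crossprod(Xg * sqrt(wts))
        tot <- tot - 0.5 * (df * log(rss / df) + sum(gamma[obs]) +
            as.numeric(determinant(xtwx)$modulus))
    }
    tot
}

## Assemble a linear-scale ProteinArraySet straight from matrices.
makeTestArraySet <- function(E, B, ids = NULL, categories = NULL,
                             conditions = NULL, block = 1L) {
    n <- nrow(E)
    if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
    if (is.null(categories)) categories <- rep("sample", n)
    J <- ncol(E)
    if (is.null(conditions)) conditions <- rep(c("A", "B"), length.out = J)
    ncols <- ceiling(sqrt(n))
    rows <- (seq_len(n) - 1L) %/% ncols + 1L
    cols <- (seq_len(n) - 1L) %% ncols + 1L
    sid <- sprintf("S%02d", seq_len(J))
    colnames(E) <- colnames(B) <- sid
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fg = E, bg = B),
        rowData = S4Vectors::DataFrame(Block = block, Row = rows,
            Column = cols, ID = ids, Name = ids,
            Category = categories, Flag = 0L),
        colData = S4Vectors::DataFrame(
            FileName = paste0(sid, ".gpr"), SampleID = sid,
            Condition = conditions, row.names = sid),
        metadata = list(logState = "linear", processing = character(0)))
    new("ProteinArraySet", se)
}

## Hand-written six-spot GPR in ATF 1.0 dialect.
writeTinyGPR <- function(path, fgName = "F635 Median",
                         bgName = "B635 Median", extraChannel = FALSE,
                         eol = "\n") {
    cols <- c("Block", "Column", "Row", "Name", "ID",
        if (extraChannel) c("F532 Median", "B532 Median"),
        fgName, bgName, "Flags")
    vals <- function(i) c(1, (i - 1) %% 3 + 1, (i - 1) %/% 3 + 1,
        sprintf("\"gene%d\"", i), sprintf("\"g%d\"", i),
        if (extraChannel) c(100 + i, 40 + i),
        200 + 10 * i, 90 + i, 0)
    lines <- c("ATF\t1.0", "2\t9",
        "\"Type=GenePix Results 3\"", "\"Wavelengths=635\"",
        paste(sprintf("\"%s\"", cols), collapse = "\t"),
        vapply(1:6, function(i) paste(vals(i), collapse = "\t"), ""))
    con <- file(path, "wb")
    writeLines(lines, con, sep = eol)
    close(con)
    invisible(path)
}
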