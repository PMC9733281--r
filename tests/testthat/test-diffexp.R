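twoGroupTargets <- function(nA = 2, nB = 2, levels = c("A", "B")) {
    data.frame(SampleID = sprintf("S%d", seq_len(nA + nB)),
        Condition = rep(levels, c(nA, nB)))
}

test_that("probe-wise least squares reproduces the hand-computed fit", {
    tg <- twoGroupTargets()
    X <- conditionDesign(tg)
    Y <- rbind(p1 = c(1, 3, 5, 7))
    fit <- fitProbewise(Y, X)
    expect_equal(unname(fit@coefficients[1, ]), c(2, 6))
    expect_equal(fit@df.residual, 2)
    expect_equal(fit@sigma[1]^2, 2)        # RSS 4 on 2 df
    cm <- makeComparisons(tg, "B-A")
    st <- moderateStats(fit, cm, priorDf = 0)
    expect_equal(unname(st@logFC[1, 1]), 4)
    expect_equal(unname(st@stdev.unscaled[1, 1]), 1)  # sqrt(1/2 + 1/2)
})

test_that("point estimates are invariant to rescaling all weights", {
    set.seed(81)
    tg <- twoGroupTargets(3, 3)
    X <- conditionDesign(tg)
    Y <- matrix(rnorm(60, 8), 10, 6)
    w <- runif(6, 0.4, 2)
    a <- fitProbewise(Y, X, w)
    b <- fitProbewise(Y, X, 7.5 * w)
    expect_equal(a@coefficients, b@coefficients, tolerance = 1e-12)
})

test_that("probes missing an entire group are flagged inestimable", {
    tg <- twoGroupTargets()
    X <- conditionDesign(tg)
    Y <- rbind(p1 = c(1, 2, NA, NA), p2 = c(1, 2, 3, 4),
        p3 = c(2, 1, 4, 3), p4 = c(0, 1, 1, 2))
    fit <- fitProbewise(Y, X)
    expect_true(is.na(fit@coefficients["p1", "B"]))
    expect_equal(fit@df.residual[1], 0)
    st <- moderateStats(fit, makeComparisons(tg, "B-A"))
    expect_true(is.na(st@t["p1", 1]))
    expect_false(is.na(st@t["p2", 1]))
})

test_that("contrast matrices come from the metadata and reject bad levels", {
    tg <- data.frame(Condition = rep(c("PDAC", "control"), each = 3))
    cm <- makeComparisons(tg, "PDAC-control")
    expect_equal(cm["PDAC", 1], 1)
    expect_equal(cm["control", 1], -1)
    tg3 <- data.frame(Condition = rep(c("A", "B", "C"), 2))
    expect_equal(dim(makeComparisons(tg3, c("B-A", "C-A"))), c(3L, 2L))
    expect_error(makeComparisons(tg, "PDAC-PDAC"), "degenerate")
    expect_error(makeComparisons(tg, "PDAC-ctrl"), "unknown condition.*ctrl")
})

test_that("equal variances drive the prior df to infinity; d0 = 0 gives the classical t", {
    tg <- twoGroupTargets(3, 3)
    X <- conditionDesign(tg)
    set.seed(82)
    Y <- matrix(rnorm(50 * 6, 8), 50, 6)
    fit <- fitProbewise(Y, X)
    ## identical residual variances
    fitC <- fit
    fitC@sigma <- rep(0.7, 50)
    stC <- moderateStats(fitC, makeComparisons(tg, "B-A"))
    expect_true(is.infinite(priorDf(stC)))
    expect_equal(unname(stC@var.post), rep(0.49, 50), tolerance = 1e-9)
    ## d0 = 0: moderated t collapses to the ordinary two-sample t
    st0 <- moderateStats(fit, makeComparisons(tg, "B-A"), priorDf = 0)
    tClassic <- apply(Y, 1, function(y)
        unname(t.test(y[4:6], y[1:3], var.equal = TRUE)$statistic))
    expect_equal(unname(st0@t[, 1]), tClassic, tolerance = 1e-10)
})

test_that("prior parameters are recovered from the scaled-F model", {
    set.seed(83)
    P <- 3000; d0 <- 4; s02 <- 0.05; dg <- 6
    sg2 <- s02 * d0 / rchisq(P, d0) * rchisq(P, dg) / dg
    tg <- twoGroupTargets(4, 4)
    X <- conditionDesign(tg)
    fit <- fitProbewise(matrix(rnorm(P * 8), P, 8), X)
    fit@sigma <- sqrt(sg2)
    fit@df.residual <- rep(dg, P)
    st <- moderateStats(fit)
    expect_lt(abs(priorDf(st) - d0) / d0, 0.25)
    expect_lt(abs(priorVar(st) - s02) / s02, 0.15)
    skip_if_not_installed("limma")
    sq <- limma::squeezeVar(sg2, df = dg)
    expect_equal(priorDf(st), sq$df.prior, tolerance = 1e-8)
    expect_equal(priorVar(st), sq$var.prior, tolerance = 1e-8)
})

test_that("trigamma inversion solves its defining equation", {
    for (x in c(1e-4, 0.01, 0.5, 2, 10, 1e4)) {
        y <- trigammaInverse(x)
        expect_equal(trigamma(y), x, tolerance = 1e-6)
    }
    expect_equal(trigammaInverse(0), Inf)
})

test_that("BH adjustment equals the brute-force step-up rule", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_equal(bhAdjust(c(1, 1)), c(1, 1))
    set.seed(84)
    for (i in 1:25) {
        p <- runif(sample(1:40, 1))^sample(1:3, 1)
        expect_equal(bhAdjust(p), bhBruteForce(p), tolerance = 1e-12)
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    expect_error(bhAdjust(c(0.5, NA)), "finite")
})

test_that("adjusted p-values dominate raw ones and preserve their order", {
    set.seed(85)
    p <- runif(200)
    q <- bhAdjust(p)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("the ranked table sorts by p and flags at the chosen level", {
    set.seed(86)
    tg <- twoGroupTargets(4, 4)
    X <- conditionDesign(tg)
    Y <- matrix(rnorm(100 * 8, 8, 0.3), 100, 8,
        dimnames = list(sprintf("p%03d", 1:100), tg$SampleID))
    Y[1:5, 5:8] <- Y[1:5, 5:8] + 2  # strong spiked effects
    st <- moderateStats(fitProbewise(Y, X), makeComparisons(tg, "B-A"))
    tab <- rankedTable(st, alpha = 0.05)
    expect_equal(tab$ID[order(tab$p.value)], tab$ID)
    expect_true(all(sprintf("p%03d", 1:5) %in% tab$ID[1:10]))
    expect_equal(tab$significant, tab$p.value < 0.05)
    empty <- new("ModeratedStats", contrasts = matrix(0, 0, 0),
        logFC = matrix(0, 0, 1), stdev.unscaled = matrix(0, 0, 1),
        df.prior = Inf, var.prior = 1, var.post = numeric(0),
        t = matrix(0, 0, 1), p.value = matrix(0, 0, 1),
        adj.p.value = matrix(0, 0, 1), df.total = numeric(0),
        sigma = numeric(0), df.residual = numeric(0))
    expect_equal(nrow(rankedTable(empty)), 0L)
})
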