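test_that("MA values against the leave-one-out average follow the formulas", {
    Y <- cbind(a = c(3, 5), b = c(1, 5), c = c(1, 5))
    ma <- maVersusRest(Y, 1)
    expect_equal(ma$table$M, c(2, 0))   # x = 3, y = 1 -> M = 2
    expect_equal(ma$table$A, c(2, 5))   # A = (3 + 1)/2 = 2
    expect_equal(ma$maxAbsM, 2)
    ## identical arrays: all M zero
    Yi <- cbind(Y[, 1], Y[, 1], Y[, 1])
    expect_equal(maVersusRest(Yi, 2)$table$M, c(0, 0))
    expect_error(maVersusRest(Y, 9), "out of range")
})

test_that("the weighted leave-one-out M identity telescopes to zero", {
    set.seed(91)
    Y <- matrix(rnorm(200 * 5, 8), 200, 5)
    J <- ncol(Y)
    Msum <- Reduce(`+`, lapply(seq_len(J), function(j)
        (J - 1) / J * maVersusRest(Y, j)$table$M))
    expect_lt(max(abs(Msum)), 1e-10)
})

test_that("missing M fractions equal the direct count after subtraction", {
    sim <- simulateArraySet(simDesign(nProteins = 400, nReplicateSpots = 1,
        controls = NULL, signalMean = 80), seed = 92)
    Y <- toLog2(bgCorrectSubtract(sim$arrays))$Y
    ma <- maVersusRest(Y, 1)
    expect_equal(ma$fracMissing, mean(is.na(Y[, 1]) |
        rowSums(!is.na(Y[, -1])) == 0))
})

test_that("control CVs are computed per control per array in percent", {
    Y <- log2(cbind(S1 = c(90, 100, 110, 50, 50),
        S2 = c(200, 200, 200, 80, 20)))
    probes <- data.frame(ID = c("ctl", "ctl", "ctl", "p1", "p1"),
        Category = c(rep("control", 3), "sample", "sample"))
    cv <- controlCV(Y, probes, "ctl")
    expect_equal(cv$cv[cv$SampleID == "S1"],
        100 * sd(c(90, 100, 110)) / 100)
    expect_equal(cv$cv[cv$SampleID == "S2"], 0)  # identical replicates
    expect_error(controlCV(Y, probes, "nope"), "unknown control")
    ## scale equivariance: multiplying linear intensities leaves CV alone
    cv2 <- controlCV(Y + log2(7), probes, "ctl")
    expect_equal(cv2$cv, cv$cv, tolerance = 1e-12)
    ## fewer than 2 finite replicates -> missing
    Y2 <- Y; Y2[1:2, 1] <- NA
    expect_true(is.na(controlCV(Y2, probes, "ctl")$cv[1]))
})

test_that("variance trends recover known residual variances and their scaling", {
    set.seed(93)
    tg <- data.frame(Condition = rep(c("A", "B"), each = 4))
    X <- conditionDesign(tg)
    Y <- matrix(rnorm(4000 * 8, 8, 0.5), 4000, 8)
    vt <- varianceTrend(Y, X)
    ## the probe-wise estimator is chi-square_6/6-distributed around the
    ## truth, so its median sits at 0.25 * qchisq(0.5, 6)/6 and its mean
    ## at 0.25
    expect_lt(abs(median(vt$table$sigma2) -
        0.25 * qchisq(0.5, 6) / 6) / 0.25, 0.05)
    expect_lt(abs(mean(vt$table$sigma2) - 0.25) / 0.25, 0.1)
    ## doubling the noise sd quadruples the variances
    vt2 <- varianceTrend(Y * 2 - 8, X)
    expect_lt(abs(median(vt2$table$sigma2) /
        median(vt$table$sigma2) - 4) / 4, 0.15)
    ## standardized A covers (0, 1) and the curve spans the observed range
    expect_true(all(vt$table$Astd > 0 & vt$table$Astd < 1))
    expect_gte(min(vt$curve$Astd), 0)
    expect_lte(max(vt$curve$Astd), 1)
    ## constant probes have zero residual variance
    Yc <- rbind(matrix(5, 5, 8), Y[1:20, ])
    vtc <- varianceTrend(Yc, X)
    expect_equal(vtc$table$sigma2[1:5], rep(0, 5))
})

test_that("normexp tracks per-array background levels in its mu estimates", {
    ## array-to-array background heterogeneity is what background
    ## correction exists to absorb: the per-array convolution fit should
    ## recover each array's background level through mu (fitted on
    ## fg - bg, whose background component is centred near zero but whose
    ## spread reflects the local-background measurement error)
    levels <- c(60, 90, 120, 150, 75, 105, 135, 165)
    sim <- simulateArraySet(simDesign(nProteins = 2000,
        nReplicateSpots = 1, controls = NULL, bgMean = levels,
        abundanceLog2Sd = 0), seed = 306)
    fits <- lapply(seq_along(levels), function(j)
        normexpFit(fgIntensity(sim$arrays)[, j]))
    mus <- vapply(fits, function(f) f@mu, numeric(1))
    expect_lt(max(abs(mus - levels)), 10)
    ## and correction therefore removes the between-array level shifts:
    ## corrected array means vary far less than raw array means
    corr <- bgCorrectNormexp(sim$arrays)
    expect_lt(sd(colMeans(fgIntensity(corr))),
        0.5 * sd(colMeans(fgIntensity(sim$arrays))))
})

test_that("the filtering comparison reports exactly three strategies", {
    sim <- simulateArraySet(simDesign(nProteins = 120,
        varianceFactors = c(4, 1, 1, 1, 1, 1, 1, 4)), seed = 94)
    norm <- normalizeSet(bgCorrectNormexp(sim$arrays), "cyclicloess")
    cons <- consolidate(norm$Y, probeInfo(norm$arrays))
    cmp <- compareFiltering(cons$E, arrayTargets(norm$arrays), "B-A")
    expect_named(cmp[c("equal", "weighted", "dropped")],
        c("equal", "weighted", "dropped"))
    expect_s4_class(cmp$weights, "ArrayWeights")
    expect_length(cmp$dropped$removed, 2L)
    for (s in c("equal", "weighted", "dropped"))
        expect_true(all(c("stats", "table", "summary") %in%
            names(cmp[[s]])))
    expect_equal(ncol(cmp$equal$stats@t), 1L)
})

test_that("well-behaved arrays give concordant calls across strategies", {
    sim <- simulateArraySet(simDesign(nProteins = 150), seed = 95)
    norm <- normalizeSet(bgCorrectNormexp(sim$arrays), "cyclicloess")
    cons <- consolidate(norm$Y, probeInfo(norm$arrays))
    cmp <- compareFiltering(cons$E, arrayTargets(norm$arrays), "B-A")
    sigE <- cmp$equal$table$significant[order(cmp$equal$table$ID)]
    sigW <- cmp$weighted$table$significant[order(cmp$weighted$table$ID)]
    expect_gte(mean(sigE == sigW), 0.95)
})

test_that("CV comparisons run ANOVA with Tukey contrasts and plots render", {
    set.seed(96)
    cvs <- c(rnorm(30, 20, 3), rnorm(30, 12, 3), rnorm(30, 19, 3))
    method <- rep(c("none", "cyclicloess", "scale"), each = 30)
    cmp <- compareCVs(cvs, method)
    expect_lt(cmp$p.value, 0.001)
    expect_equal(nrow(cmp$tukey), 3L)  # three pairwise contrasts
    ## the separated method drives the significant pairs
    sep <- grepl("cyclicloess", rownames(cmp$tukey))
    expect_true(all(cmp$tukey[sep, "p adj"] < 0.01))
    expect_error(compareCVs(cvs, rep("one", 90)), "two methods")
    ## plots render without error onto a null device
    png <- tempfile(fileext = ".png")
    grDevices::png(png)
    Y <- matrix(rnorm(400, 8), 100, 4)
    expect_no_error(plotMA(maVersusRest(Y, 1)))
    expect_no_error(plotControlCV(cvs, method))
    expect_no_error(plotArrayWeights(
        fitArrayWeights(Y, matrix(1, 4, 1))))
    expect_no_error(plotVarianceTrend(varianceTrend(Y,
        conditionDesign(data.frame(Condition = c("A", "A", "B", "B"))))))
    grDevices::dev.off()
    expect_true(file.exists(png))
})
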