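## Synthetic single-channel protein arrays with the statistical structure
## the pipeline assumes: normal background plus exponential signal per spot,
## log-normal protein abundances, per-array log2 distortions and
## residual-variance inflation factors.

#' Default control series for the 130-feature (CT100+-like) design
#'
#' Two negative controls (buffer only, relative intensity 0) and five
#' positive controls, three of which emulate a dilution series of
#' fluorophore-conjugated BSA at known concentrations.
#'
#' @return \code{data.frame} with \code{Name}, \code{relIntensity} (signal
#'   mean relative to the overall exponential signal mean) and
#'   \code{Category}.
#' @export
defaultControls <- function() {
    data.frame(
        Name = c("NEG-BUFFER-1", "NEG-BUFFER-2",
            "AF647-BSA-5ng", "AF647-BSA-10ng", "AF647-BSA-15ng",
            "POS-IGG-1", "POS-IGG-2"),
        relIntensity = c(0, 0, 1, 2, 3, 4, 4),
        Category = "control",
        stringsAsFactors = FALSE
    )
}

#' Design of a simulated single-channel array experiment
#'
#' Defaults emulate a 130-feature design: 123 distinct proteins plus 2
#' negative and 5 positive controls, printed in triplicate, hybridized in
#' two conditions of 4 arrays each.  Spot intensities follow the
#' normal+exponential convolution the background-correction model assumes:
#' background ~ Normal(bgMean, bgSd^2 * v_j) and signal ~ Exponential with
#' protein-specific mean (log-normal across proteins, sd 1 on log2).
#'
#' @param nProteins Number of distinct sample probes.
#' @param nReplicateSpots Spots per probe per array.
#' @param controls Control probes as from \code{\link{defaultControls}};
#'   may be a zero-row data frame.
#' @param nArraysPerCondition Named integer vector of arrays per condition.
#' @param bgMean Background normal mean (fluorescence units); a vector is
#'   recycled across arrays, emulating array-to-array background-level
#'   heterogeneity (washing/scanner effects) that background correction is
#'   meant to remove.
#' @param bgSd Background normal sd (fluorescence units).
#' @param bgShare Fraction of the per-spot background variance shared
#'   between the spot's true background and its recorded local-background
#'   estimate (both marginals stay Normal(bgMean, bgSd^2)); 0 makes the
#'   recorded background uninformative, 1 makes it exact.
#' @param signalMean Exponential signal mean (fluorescence units) for a
#'   protein of unit relative abundance.
#' @param abundanceLog2Sd Spread (sd, log2 scale) of the log-normal
#'   protein-specific relative abundances; 0 makes every sample probe draw
#'   its signal from the same Exponential(signalMean), so the spot
#'   population follows the normal+exponential convolution exactly.
#' @param arrayLog2Offsets Per-array additive log2 distortions (recycled).
#' @param arrayCurvature Per-array intensity-dependent log2 distortion
#'   coefficients (recycled).
#' @param varianceFactors Per-array background residual-variance
#'   multipliers v_j (recycled; >= 0).
#' @param deFraction Fraction of proteins truly differential.
#' @param deLog2FC Their log2 fold change (applied to the last condition).
#' @return A list of class \code{"SimDesign"}.
#' @export
simDesign <- function(nProteins = 123L,
                      nReplicateSpots = 3L,
                      controls = defaultControls(),
                      nArraysPerCondition = c(A = 4L, B = 4L),
                      bgMean = 100,
                      bgSd = 15,
                      bgShare = 0.8,
                      signalMean = 200,
                      abundanceLog2Sd = 1,
                      arrayLog2Offsets = 0,
                      arrayCurvature = 0,
                      varianceFactors = 1,
                      deFraction = 0,
                      deLog2FC = 0) {
    if (nProteins < 1L || nReplicateSpots < 1L ||
        any(nArraysPerCondition < 1L))
        stop("design counts must be positive")
    if (is.null(names(nArraysPerCondition)))
        names(nArraysPerCondition) <-
            LETTERS[seq_along(nArraysPerCondition)]
    if (bgSd <= 0 || signalMean <= 0)
        stop("bgSd and signalMean must be positive")
    if (any(bgMean < 0)) stop("bgMean must be >= 0")
    if (bgShare < 0 || bgShare > 1) stop("bgShare must be in [0, 1]")
    if (any(varianceFactors < 0)) stop("varianceFactors must be >= 0")
    if (deFraction < 0 || deFraction > 1)
        stop("deFraction must be in [0, 1]")
    J <- sum(nArraysPerCondition)
    structure(list(
        nProteins = as.integer(nProteins),
        nReplicateSpots = as.integer(nReplicateSpots),
        controls = controls,
        nArraysPerCondition = nArraysPerCondition,
        bgMean = rep_len(bgMean, J), bgSd = bgSd, bgShare = bgShare,
        signalMean = signalMean,
        abundanceLog2Sd = abundanceLog2Sd,
        arrayLog2Offsets = rep_len(arrayLog2Offsets, J),
        arrayCurvature = rep_len(arrayCurvature, J),
        varianceFactors = rep_len(varianceFactors, J),
        deFraction = deFraction, deLog2FC = deLog2FC
    ), class = "SimDesign")
}

## near-square spot lattice for one block
spotLattice <- function(n) {
    ncol <- ceiling(sqrt(n))
    nrow <- ceiling(n / ncol)
    idx <- seq_len(n) - 1L
    data.frame(Row = idx %/% ncol + 1L, Column = idx %% ncol + 1L)
}

#' Simulate an aligned single-channel array set
#'
#' Each spot draws fg = max(0, Normal(bgMean, bgSd^2 * v_j)) + Exponential
#' with mean \code{signalMean * relative abundance}; per-array distortions
#' are applied multiplicatively on the linear scale as
#' \code{2^(offset_j + curvature_j * (log2 fg - centre))} with centre
#' \code{log2(bgMean + signalMean)}; the background column is an
#' independent Normal(bgMean, bgSd^2) draw truncated at 0.  Differential
#' proteins have their abundance shifted by \code{deLog2FC} in the last
#' condition.  Replicate spots are laid out one block per replicate on a
#' near-square lattice.
#'
#' @param design A \code{SimDesign} from \code{\link{simDesign}}.
#' @param seed Integer seed; the result is deterministic given
#'   \code{design} and \code{seed}.
#' @return List with \code{arrays} (a linear-scale
#'   \linkS4class{ProteinArraySet}) and \code{truth} (per-protein signal
#'   means by condition, DE labels, variance factors and distortions --
#'   returned alongside the data, never written into files).
#' @export
#'
#' @examples
#' sim <- simulateArraySet(simDesign(), seed = 1)
#' sim$arrays
#' table(sim$truth$isDE)
simulateArraySet <- function(design, seed = 1L) {
    stopifnot(inherits(design, "SimDesign"))
    set.seed(as.integer(seed))
    P <- design$nProteins
    ctl <- design$controls
    nc <- if (is.null(ctl)) 0L else nrow(ctl)
    R <- design$nReplicateSpots
    conds <- rep(names(design$nArraysPerCondition),
        design$nArraysPerCondition)
    J <- length(conds)

    proteinNames <- sprintf("PROT%03d", seq_len(P))
    ## log-normal relative abundances (sd 1 on the log2 scale by default)
    relAbund <- 2^rnorm(P, mean = 0, sd = design$abundanceLog2Sd)
    nDE <- round(design$deFraction * P)
    isDE <- c(rep(TRUE, nDE), rep(FALSE, P - nDE))
    feat <- data.frame(
        ID = c(proteinNames, if (nc) ctl$Name),
        Name = c(proteinNames, if (nc) ctl$Name),
        Category = c(rep("sample", P), if (nc) ctl$Category),
        rel = c(relAbund, if (nc) ctl$relIntensity),
        de = c(isDE, if (nc) rep(FALSE, nc)),
        stringsAsFactors = FALSE
    )
    nFeat <- nrow(feat)
    lat <- spotLattice(nFeat)
    spots <- do.call(rbind, lapply(seq_len(R), function(b)
        data.frame(Block = b, Row = lat$Row, Column = lat$Column,
            ID = feat$ID, Name = feat$Name, Category = feat$Category,
            Flag = 0L, stringsAsFactors = FALSE)))
    relSpot <- rep(feat$rel, R)
    deSpot <- rep(feat$de, R)
    nSpot <- nrow(spots)

    lastCond <- names(design$nArraysPerCondition)[
        length(design$nArraysPerCondition)]
    centre <- log2(mean(design$bgMean) + design$signalMean)
    E <- B <- matrix(0, nSpot, J)
    sdSh <- design$bgSd * sqrt(design$bgShare)
    sdInd <- design$bgSd * sqrt(1 - design$bgShare)
    for (j in seq_len(J)) {
        v <- design$varianceFactors[j]
        ## the spot's true background and its recorded local-background
        ## estimate share a common component (local background is a
        ## measurement of the same region); each marginal is the stated
        ## normal
        u <- rnorm(nSpot, 0, sdSh)
        bgDraw <- pmax(0, design$bgMean[j] +
            sqrt(v) * (u + rnorm(nSpot, 0, sdInd)))
        mu <- design$signalMean * relSpot
        if (conds[j] == lastCond && design$deLog2FC != 0)
            mu[deSpot] <- mu[deSpot] * 2^design$deLog2FC
        ## spot signal: mean mu, variance mu^2 * v_j.  At v = 1 this is
        ## exactly Exponential(mean mu); v != 1 generalizes to a
        ## mean-preserving gamma so v acts as a residual-variance
        ## multiplier on the signal as well as the background.
        s <- if (v == 1) rexp(nSpot, rate = 1 / pmax(mu, 1e-12))
            else pmax(mu, 1e-12) *
                rgamma(nSpot, shape = 1 / v, scale = v)
        s[mu <= 0] <- 0
        fg <- bgDraw + s
        off <- design$arrayLog2Offsets[j]
        curv <- design$arrayCurvature[j]
        if (off != 0 || curv != 0) {
            pos <- fg > 0
            fg[pos] <- fg[pos] *
                2^(off + curv * (log2(fg[pos]) - centre))
        }
        E[, j] <- fg
        B[, j] <- pmax(0, design$bgMean[j] + u +
            rnorm(nSpot, 0, sdInd))
    }
    sampleIds <- sprintf("S%02d_%s", seq_len(J), conds)
    colnames(E) <- colnames(B) <- sampleIds
    targets <- data.frame(FileName = paste0(sampleIds, ".gpr"),
        SampleID = sampleIds, Condition = conds,
        stringsAsFactors = FALSE)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fg = E, bg = B),
        rowData = S4Vectors::DataFrame(spots),
        colData = S4Vectors::DataFrame(targets,
            row.names = targets$SampleID),
        metadata = list(logState = "linear",
            processing = sprintf("simulate:%d spots x %d arrays (seed %d)",
                nSpot, J, as.integer(seed)))
    )
    condLevels <- unique(conds)
    meanByCond <- sapply(condLevels, function(cc) {
        m <- feat$rel * design$signalMean
        if (cc == lastCond && design$deLog2FC != 0)
            m[feat$de] <- m[feat$de] * 2^design$deLog2FC
        m
    })
    rownames(meanByCond) <- feat$ID
    list(
        arrays = new("ProteinArraySet", se),
        truth = list(
            signalMeanByCondition = meanByCond,
            isDE = setNames(feat$de, feat$ID),
            varianceFactors = setNames(design$varianceFactors, sampleIds),
            log2Offsets = setNames(design$arrayLog2Offsets, sampleIds),
            curvature = setNames(design$arrayCurvature, sampleIds)
        )
    )
}

#' Write a simulated set as ATF-valid fixture GPR files
#'
#' Emits one GPR per array (columns \code{"F635 Median"} /
#' \code{"B635 Median"}, so auto column detection applies) plus a matching
#' \code{targets.tsv}; reading them back with \code{\link{readGPR}} and
#' \code{\link{assembleArraySet}} reproduces the set exactly.
#'
#' @param aset Linear-scale \linkS4class{ProteinArraySet}.
#' @param dir Output directory (created if needed).
#' @return List with \code{gpr} (file paths) and \code{targets} (path).
#' @export
writeFixtureGPRs <- function(aset, dir) {
    stopifnot(is(aset, "ProteinArraySet"))
    if (logState(aset) != "linear")
        stop("fixture GPRs require a linear-scale array set")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rd <- probeInfo(aset)
    tg <- arrayTargets(aset)
    E <- fgIntensity(aset)
    B <- bgIntensity(aset)
    fmt <- function(x) sprintf("%.17g", x)
    paths <- character(ncol(E))
    for (j in seq_len(ncol(E))) {
        path <- file.path(dir, tg$FileName[j])
        header <- c("ATF\t1.0", "2\t8",
            "\"Type=GenePix Results 3\"",
            sprintf("\"Wavelengths=635\""))
        cols <- paste(dQuote(c("Block", "Column", "Row", "Name", "ID",
            "F635 Median", "B635 Median", "Flags"), q = FALSE),
            collapse = "\t")
        body <- paste(rd$Block, rd$Column, rd$Row,
            paste0("\"", rd$Name, "\""), paste0("\"", rd$ID, "\""),
            fmt(E[, j]), fmt(B[, j]), rd$Flag, sep = "\t")
        writeLines(c(header, cols, body), path)
        paths[j] <- path
    }
    tpath <- file.path(dir, "targets.tsv")
    write.table(tg[, c("FileName", "SampleID", "Condition")], tpath,
        sep = "\t", quote = FALSE, row.names = FALSE)
    ## GPR files carry no category column; ship the non-sample categories
    ## as a probe-annotation list so a round trip can restore them
    apath <- file.path(dir, "probe_annotations.tsv")
    ann <- unique(rd[rd$Category != "sample", c("ID", "Category")])
    write.table(ann, apath, sep = "\t", quote = FALSE, row.names = FALSE)
    list(gpr = paths, targets = tpath, annotations = apath)
}
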