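## Spot filtering at the 2-SD background noise threshold and the
## non-model background-correction methods.

#' Filter noisy spots against the background noise threshold
#'
#' For each array j the noise threshold is T_j = median(B_j) + 2 sd(B_j),
#' computed over all spots of that array; foreground intensities below T_j
#' are set missing ("noisy" spots), preserving matrix shape.  Backgrounds
#' are unchanged and the operation is idempotent.
#'
#' @param aset Linear-scale \linkS4class{ProteinArraySet}.
#' @return List with \code{arrays} (filtered set) and \code{thresholds}
#'   (\code{data.frame} of per-array threshold and filtered-spot count).
#' @export
#'
#' @examples
#' sim <- simulateArraySet(simDesign(), seed = 1)
#' fl <- filterSpots(sim$arrays)
#' fl$thresholds
filterSpots <- function(aset) {
    stopifnot(is(aset, "ProteinArraySet"))
    if (logState(aset) != "linear")
        stop("spot filtering operates on linear intensities")
    E <- fgIntensity(aset)
    B <- bgIntensity(aset)
    if (nrow(E) < 3L)
        stop("need at least 3 spots per array to estimate the threshold")
    thr <- apply(B, 2, function(b) median(b) + 2 * sd(b))
    nFiltered <- integer(ncol(E))
    for (j in seq_len(ncol(E))) {
        noisy <- !is.na(E[, j]) & E[, j] < thr[j]
        nFiltered[j] <- sum(noisy)
        E[noisy, j] <- NA_real_
    }
    fgIntensity(aset) <- E
    aset <- recordStep(aset, sprintf("filter:2sd (%s filtered)",
        paste(nFiltered, collapse = "/")))
    list(arrays = aset,
        thresholds = data.frame(SampleID = colnames(E),
            threshold = unname(thr), nFiltered = nFiltered,
            stringsAsFactors = FALSE))
}

#' Background correction methods
#'
#' \code{bgCorrectNone} leaves foregrounds untouched (background treated as
#' zero).  \code{bgCorrectSubtract} subtracts the local background
#' estimate; non-positive results survive as non-positive values and
#' become missing at the log2 step.  \code{bgCorrectMovingMin} replaces
#' each spot's background by the minimum over its 3x3 within-block
#' neighbourhood (at block edges only existing neighbours) before
#' subtracting.  \code{bgCorrectNormexp} fits the normal+exponential
#' convolution model to fg - bg by maximum likelihood per array and
#' replaces each intensity by the expected signal given the observation,
#' which is always positive, plus the offset \code{k}.
#'
#' @param aset Linear-scale \linkS4class{ProteinArraySet}.
#' @return The corrected \linkS4class{ProteinArraySet}.
#'   \code{bgCorrectNormexp} additionally records the fitted
#'   \linkS4class{NormexpParams} per array in
#'   \code{metadata(aset)$normexp}.
#' @name background-correction
#' @export
bgCorrectNone <- function(aset) {
    stopifnot(is(aset, "ProteinArraySet"), logState(aset) == "linear")
    recordStep(aset, "background:none")
}

#' @rdname background-correction
#' @export
bgCorrectSubtract <- function(aset) {
    stopifnot(is(aset, "ProteinArraySet"), logState(aset) == "linear")
    E <- fgIntensity(aset) - bgIntensity(aset)
    nNonPos <- sum(E <= 0, na.rm = TRUE)
    fgIntensity(aset) <- E
    recordStep(aset, sprintf("background:subtract (%d non-positive)",
        nNonPos))
}

## minimum of bg over the 3x3 neighbourhood within one block
movingMinBlock <- function(spots, bg) {
    out <- bg
    rmax <- max(spots$Row); cmax <- max(spots$Column)
    grid <- matrix(NA_real_, rmax, cmax)
    grid[cbind(spots$Row, spots$Column)] <- bg
    for (i in seq_len(nrow(spots))) {
        rr <- max(1L, spots$Row[i] - 1L):min(rmax, spots$Row[i] + 1L)
        cc <- max(1L, spots$Column[i] - 1L):min(cmax, spots$Column[i] + 1L)
        out[i] <- min(grid[rr, cc], na.rm = TRUE)
    }
    out
}

#' @rdname background-correction
#' @export
bgCorrectMovingMin <- function(aset) {
    stopifnot(is(aset, "ProteinArraySet"), logState(aset) == "linear")
    rd <- probeInfo(aset)
    E <- fgIntensity(aset)
    B <- bgIntensity(aset)
    Bmin <- B
    for (b in unique(rd$Block)) {
        idx <- which(rd$Block == b)
        for (j in seq_len(ncol(B)))
            Bmin[idx, j] <- movingMinBlock(rd[idx, ], B[idx, j])
    }
    E <- E - Bmin
    nNonPos <- sum(E <= 0, na.rm = TRUE)
    fgIntensity(aset) <- E
    recordStep(aset, sprintf("background:movingmin (%d non-positive)",
        nNonPos))
}

#' @rdname background-correction
#' @param k Offset added to the corrected intensities (>= 0, default 0).
#' @export
bgCorrectNormexp <- function(aset, k = 0) {
    stopifnot(is(aset, "ProteinArraySet"), logState(aset) == "linear")
    if (k < 0) stop("offset k must be >= 0")
    E <- fgIntensity(aset)
    B <- bgIntensity(aset)
    params <- vector("list", ncol(E))
    names(params) <- colnames(E)
    for (j in seq_len(ncol(E))) {
        x <- E[, j] - B[, j]
        p <- normexpFit(x[is.finite(x)])
        p@offset <- k
        params[[j]] <- p
        ok <- is.finite(x)
        E[ok, j] <- normexpSignal(x[ok], p) + k
        E[!ok, j] <- NA_real_
    }
    fgIntensity(aset) <- E
    S4Vectors::metadata(aset)$normexp <- params
    recordStep(aset, sprintf("background:normexp (k=%g)", k))
}
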