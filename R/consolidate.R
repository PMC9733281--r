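## Replicate-spot consolidation: one mean log2 value per protein per
## array, with control/empty categories removed.

#' Consolidate replicate spots to one value per protein
#'
#' Per probe ID per array the value is the mean of the finite replicate
#' log2 intensities (missing when all replicates are missing).  Probes in
#' the dropped categories (default control and empty) are removed.  No
#' minimum-replicate rule is imposed; replicate counts per cell are
#' returned so users may filter downstream.
#'
#' @param Y Spot-level log2 matrix (spots x arrays).
#' @param probes Spot annotation \code{data.frame} with \code{ID} and
#'   \code{Category} rows aligned with \code{Y}.
#' @param drop Categories to remove (default \code{c("control","empty")}).
#' @return List with \code{E} (proteins x arrays mean log2 matrix),
#'   \code{counts} (finite replicate counts per cell) and \code{probes}
#'   (annotation of the retained proteins, one row each).
#' @export
#'
#' @examples
#' sim <- simulateArraySet(simDesign(), seed = 1)
#' norm <- normalizeSet(bgCorrectNormexp(sim$arrays), "cyclicloess")
#' cons <- consolidate(norm$Y, probeInfo(norm$arrays))
#' dim(cons$E)
consolidate <- function(Y, probes, drop = c("control", "empty")) {
    stopifnot(nrow(Y) == nrow(probes))
    keep <- !(probes$Category %in% drop)
    if (!any(keep))
        stop("no probes left after dropping categories: ",
            paste(drop, collapse = ", "))
    Y <- Y[keep, , drop = FALSE]
    probes <- probes[keep, , drop = FALSE]
    grp <- factor(probes$ID, levels = unique(probes$ID))
    fin <- is.finite(Y)
    Yz <- Y
    Yz[!fin] <- 0
    sums <- rowsum(Yz, grp)
    counts <- rowsum(fin + 0L, grp)
    E <- sums / counts
    E[counts == 0L] <- NA_real_
    first <- !duplicated(grp)
    ann <- probes[first, intersect(c("ID", "Name", "Category"),
        names(probes)), drop = FALSE]
    rownames(ann) <- ann$ID
    list(E = E, counts = counts, probes = ann)
}
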