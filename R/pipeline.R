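## End-to-end orchestration: extraction -> spot filtering -> background
## correction -> normalization -> array weights -> consolidation ->
## optional differential expression, with a machine-readable run report.

#' Default pipeline configuration
#'
#' The defaults reproduce the recommended pre-processing path: 2-SD spot
#' filtering, normexp background correction with offset 0, fast cyclic
#' loess normalization (span 0.7, 3 iterations), REML array weights,
#' consolidation dropping control and empty probes, and (when comparisons
#' are given) weighted moderated-t differential expression at alpha 0.05.
#'
#' @param ... Overrides of the default fields.
#' @return Named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(...) {
    cfg <- list(
        inputs = NULL,            # GPR/TXT file paths or a glob
        arrays = NULL,            # or a pre-assembled ProteinArraySet
        fgColumn = "auto",
        bgColumn = "auto",
        targets = NULL,           # targets file path or data.frame
        probeAnnotations = NULL,  # optional annotation file path
        dropCategories = c("control", "empty"),
        background = "normexp",   # none | subtract | movingmin | normexp
        offset = 0,
        offsetGrid = FALSE,       # select offset by max prior df
        normalization = "cyclicloess",  # none | scale | quantile | cyclicloess
        span = 0.7,
        iterations = 3L,
        weightStrategy = "weights",     # weights | equal | drop:<n>
        comparisons = NULL,
        alpha = 0.05,
        outDir = ".",
        seed = 1L,
        verbose = TRUE
    )
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    structure(cfg, class = "RunConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror \code{\link{runConfig}} fields.
#' @return A \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(runConfig, vals)
}

validateConfig <- function(cfg) {
    if (!cfg$background %in% c("none", "subtract", "movingmin", "normexp"))
        stop("unknown background method: ", cfg$background)
    if (!cfg$normalization %in% c("none", "scale", "quantile",
        "cyclicloess"))
        stop("unknown normalization method: ", cfg$normalization)
    if (!(identical(cfg$weightStrategy, "weights") ||
        identical(cfg$weightStrategy, "equal") ||
        grepl("^drop:[0-9]+$", cfg$weightStrategy)))
        stop("unknown weight strategy: ", cfg$weightStrategy)
    if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
    if (is.null(cfg$inputs) && is.null(cfg$arrays))
        stop("config must name input files")
    invisible(cfg)
}

applyBackground <- function(aset, method, k) {
    switch(method,
        none = bgCorrectNone(aset),
        subtract = bgCorrectSubtract(aset),
        movingmin = bgCorrectMovingMin(aset),
        normexp = bgCorrectNormexp(aset, k = k))
}

#' Run the full pre-processing (and optional DE) pipeline
#'
#' Reads and validates the inputs, filters spots at the 2-SD background
#' threshold, background-corrects, normalizes, estimates REML array
#' weights, consolidates replicates, and -- when comparisons are given --
#' runs the weighted moderated-t differential expression.  Writes the
#' consolidated expression matrix, the array weights, a per-stage YAML run
#' report and, when applicable, the DE results, all under
#' \code{cfg$outDir}.  Identical inputs, config and seed give identical
#' outputs; on error the partial outputs of this run are removed.
#'
#' @param cfg A \code{RunConfig} from \code{\link{runConfig}} (the
#'   \code{arrays} field may hold a pre-assembled
#'   \linkS4class{ProteinArraySet} in place of \code{inputs}/\code{targets}
#'   paths).
#' @return Invisibly, a list with the consolidated matrix, weights,
#'   thresholds, run report and (optionally) DE table, plus the paths
#'   written.
#' @export
runPipeline <- function(cfg) {
    set.seed(as.integer(cfg$seed))
    written <- character(0)
    on.exit(if (!is.null(attr(written, "failed")))
        unlink(written), add = TRUE)
    fail <- function(stage, e) {
        attr(written, "failed") <<- TRUE
        stop("pipeline stage '", stage, "': ", conditionMessage(e),
            call. = FALSE)
    }
    note <- function(...) if (isTRUE(cfg$verbose)) message(...)

    ## stage: configuration (before any file is read)
    tryCatch(validateConfig(cfg), error = function(e) fail("config", e))

    ## stage: read
    aset <- tryCatch({
        if (!is.null(cfg$arrays)) cfg$arrays
        else {
            paths <- cfg$inputs
            if (length(paths) == 1L && !file.exists(paths))
                paths <- Sys.glob(paths)
            if (!length(paths) || !all(file.exists(paths)))
                stop("input file(s) not found: ",
                    paste(cfg$inputs, collapse = ", "))
            if (is.null(cfg$targets)) stop("no targets table given")
            targets <- if (is.data.frame(cfg$targets)) cfg$targets
                else readTargets(cfg$targets)
            tables <- lapply(paths, readGPR, fgColumn = cfg$fgColumn,
                bgColumn = cfg$bgColumn)
            assembleArraySet(tables, targets)
        }
    }, error = function(e) fail("read", e))
    if (!is.null(cfg$probeAnnotations))
        aset <- tryCatch(applyProbeAnnotations(aset,
            readProbeAnnotations(cfg$probeAnnotations)),
            error = function(e) fail("annotate", e))
    note("read: ", nrow(aset), " spots x ", ncol(aset), " arrays")

    ## stage: spot filtering
    fl <- tryCatch(filterSpots(aset), error = function(e)
        fail("filter", e))
    aset <- fl$arrays

    ## stage: background correction
    design <- conditionDesign(arrayTargets(aset))
    k <- cfg$offset
    offsetTable <- NULL
    if (cfg$background == "normexp" && isTRUE(cfg$offsetGrid)) {
        sel <- tryCatch(selectOffset(aset, design, span = cfg$span,
            iterations = cfg$iterations),
            error = function(e) fail("offset", e))
        k <- sel$k
        offsetTable <- sel$table
        note("offset grid: k = ", k)
    }
    aset <- tryCatch(applyBackground(aset, cfg$background, k),
        error = function(e) fail("background", e))

    ## stage: normalization
    norm <- tryCatch(normalizeSet(aset, cfg$normalization,
        span = cfg$span, iterations = cfg$iterations),
        error = function(e) fail("normalize", e))

    ## stage: array weights
    weights <- tryCatch(fitArrayWeights(norm$Y, design),
        error = function(e) fail("weights", e))

    ## stage: consolidation
    cons <- tryCatch(consolidate(norm$Y, probeInfo(norm$arrays),
        drop = cfg$dropCategories), error = function(e)
        fail("consolidate", e))
    note("consolidated: ", nrow(cons$E), " proteins x ", ncol(cons$E),
        " arrays")

    ## stage: differential expression (optional)
    deTable <- NULL
    if (!is.null(cfg$comparisons)) {
        deTable <- tryCatch({
            tg <- arrayTargets(norm$arrays)
            E <- cons$E
            w <- weightValues(weights)
            if (identical(cfg$weightStrategy, "equal")) w <- NULL
            if (grepl("^drop:", cfg$weightStrategy)) {
                nDrop <- as.integer(sub("^drop:", "", cfg$weightStrategy))
                red <- dropLowestArrays(E, weights, nDrop, tg)
                E <- red$Y; tg <- red$targets; w <- NULL
            }
            X <- conditionDesign(tg)
            cm <- makeComparisons(tg, cfg$comparisons)
            st <- moderateStats(fitProbewise(E, X, w), cm)
            rankedTable(st, 1L, cfg$alpha)
        }, error = function(e) fail("diffexp", e))
    }

    ## outputs
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    outPath <- function(f) file.path(cfg$outDir, f)
    tryCatch({
        writeMatrix(cons$E, outPath("expression_matrix.tsv"))
        written <- c(written, outPath("expression_matrix.tsv"))
        wtab <- data.frame(SampleID = names(weightValues(weights)),
            weight = unname(weightValues(weights)))
        write.table(wtab, outPath("array_weights.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        written <- c(written, outPath("array_weights.tsv"))
        report <- list(
            config = unclass(cfg[setdiff(names(cfg),
                c("arrays", "targets", "verbose"))]),
            thresholds = fl$thresholds,
            processing = as.list(processingLog(norm$arrays)),
            normexp = if (!is.null(S4Vectors::metadata(aset)$normexp))
                lapply(S4Vectors::metadata(aset)$normexp, function(p)
                    list(mu = p@mu, sigma = p@sigma, alpha = p@alpha,
                        offset = p@offset)),
            offsetGrid = offsetTable,
            scaleFactors = norm$factors,
            weights = as.list(weightValues(weights)),
            consolidated = dim(cons$E),
            seed = cfg$seed)
        yaml::write_yaml(lapply(report, function(x)
            if (is.data.frame(x)) as.list(x) else x),
            outPath("run_report.yaml"))
        written <- c(written, outPath("run_report.yaml"))
        if (!is.null(deTable)) {
            write.table(deTable, outPath("de_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
            written <- c(written, outPath("de_results.tsv"))
        }
    }, error = function(e) fail("write", e))

    invisible(list(expression = cons$E, counts = cons$counts,
        weights = weights, thresholds = fl$thresholds,
        offsetTable = offsetTable, de = deTable,
        arrays = norm$arrays, paths = written))
}

#' Run the background x normalization and filtering comparison grids
#'
#' Executes every combination of the four background-correction and four
#' normalization methods on the inputs, recording per-cell evaluation
#' metrics (missing-M fraction and max |M| against the leave-one-out
#' average, control CVs, median residual log2 variance), plus the
#' three-strategy filtering comparison on the default-pipeline matrix.
#'
#' @param cfg A \code{RunConfig}; \code{comparisons} is required for the
#'   filtering block.
#' @param backgrounds,normalizations Method subsets to run.
#' @return List with \code{grid} (one report per background/normalization
#'   cell; failed cells carry the error message) and \code{filtering}
#'   (the \code{\link{compareFiltering}} result, when comparisons given).
#' @export
runCompare <- function(cfg,
                       backgrounds = c("none", "subtract", "movingmin",
                           "normexp"),
                       normalizations = c("none", "scale", "quantile",
                           "cyclicloess")) {
    set.seed(as.integer(cfg$seed))
    aset <- if (!is.null(cfg$arrays)) cfg$arrays else {
        targets <- if (is.data.frame(cfg$targets)) cfg$targets
            else readTargets(cfg$targets)
        tables <- lapply(cfg$inputs, readGPR, fgColumn = cfg$fgColumn,
            bgColumn = cfg$bgColumn)
        assembleArraySet(tables, targets)
    }
    fl <- filterSpots(aset)
    design <- conditionDesign(arrayTargets(aset))
    probes <- probeInfo(aset)
    controls <- unique(probes$ID[probes$Category == "control"])
    grid <- list()
    nFailed <- 0L
    for (bg in backgrounds) for (nm in normalizations) {
        key <- paste(bg, nm, sep = ".")
        grid[[key]] <- tryCatch({
            corr <- applyBackground(fl$arrays, bg, cfg$offset)
            norm <- normalizeSet(corr, nm, span = cfg$span,
                iterations = cfg$iterations)
            ma <- maVersusRest(norm$Y, 1L)
            vt <- varianceTrend(norm$Y, design)
            cvs <- if (length(controls))
                controlCV(norm$Y, probes, controls,
                    across = "arrays")$cv else NA_real_
            list(background = bg, normalization = nm,
                maxAbsM = ma$maxAbsM, fracMissingM = ma$fracMissing,
                meanControlCV = mean(cvs, na.rm = TRUE),
                medianLog2Var = median(vt$log2Var, na.rm = TRUE))
        }, error = function(e) {
            nFailed <<- nFailed + 1L
            list(background = bg, normalization = nm,
                error = conditionMessage(e))
        })
    }
    if (nFailed == length(grid))
        stop("every comparison cell failed")
    filtering <- NULL
    if (!is.null(cfg$comparisons)) {
        corr <- bgCorrectNormexp(fl$arrays, k = cfg$offset)
        norm <- normalizeSet(corr, "cyclicloess", span = cfg$span,
            iterations = cfg$iterations)
        cons <- consolidate(norm$Y, probeInfo(norm$arrays),
            drop = cfg$dropCategories)
        filtering <- compareFiltering(cons$E, arrayTargets(norm$arrays),
            cfg$comparisons, alpha = cfg$alpha)
    }
    list(grid = grid, filtering = filtering)
}
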