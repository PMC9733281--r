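## Reading GenePix GPR (ATF dialect) and Mapix-style tab-delimited
## extractions, targets metadata and probe annotation lists.

stripQuotes <- function(x) gsub('^"|"$', "", x)

## Locate the column-name line: ATF files carry "ATF <tab> 1.0" then a
## header-count line; plain TXT has the column names on line 1.
gprHeaderInfo <- function(path) {
    head4 <- readLines(path, n = 2L, warn = FALSE)
    if (!length(head4)) stop("empty file: ", path)
    first <- stripQuotes(strsplit(head4[1], "\t")[[1]])
    if (identical(toupper(first[1]), "ATF")) {
        if (length(head4) < 2L)
            stop("truncated ATF header in ", path)
        counts <- suppressWarnings(
            as.integer(stripQuotes(strsplit(head4[2], "\t")[[1]])))
        if (length(counts) < 1L || is.na(counts[1]))
            stop("malformed ATF header-count line in ", path)
        list(dialect = "atf", skip = 2L + counts[1])
    } else {
        list(dialect = "txt", skip = 0L)
    }
}

matchIntensityColumn <- function(columns, requested, pattern, what) {
    if (!identical(requested, "auto")) {
        if (!requested %in% columns)
            stop("requested ", what, " column '", requested,
                "' not found; available columns: ",
                paste(columns, collapse = ", "))
        return(requested)
    }
    hits <- grep(pattern, columns, value = TRUE)
    if (!length(hits))
        stop("no ", what, " intensity column matching '", pattern,
            "' found; available columns: ", paste(columns, collapse = ", "))
    ## tie-break: lowest wavelength
    wl <- as.integer(sub("^[FB](\\d+) Median$", "\\1", hits))
    hits[order(wl)][1]
}

pickColumn <- function(df, candidates, default = NULL) {
    hit <- intersect(candidates, names(df))
    if (length(hit)) df[[hit[1]]] else default
}

defaultCategory <- function(nm) {
    ifelse(is.na(nm) | nm == "" | tolower(nm) == "empty", "empty", "sample")
}

#' Read one GPR/ATF or tab-delimited spot extraction
#'
#' Parses a GenePix Results file (Axon Text File dialect: version line,
#' header-count line, header records, then a column-name line) or a generic
#' single-header tab-delimited export (e.g. Mapix).  The median foreground
#' and background columns are auto-detected from the GenePix naming scheme
#' (\code{"F<wavelength> Median"} / \code{"B<wavelength> Median"}; ties
#' broken by lowest wavelength) or may be named explicitly, as Mapix
#' exports lacking that scheme require.
#'
#' @param path Path to the file.
#' @param fgColumn,bgColumn Column names, or \code{"auto"} (default).
#' @param arrayId Label for the array; defaults to the file name.
#' @return A \linkS4class{SpotTable}.
#' @export
#'
#' @examples
#' d <- simulateArraySet(simDesign(nProteins = 5,
#'   nArraysPerCondition = c(A = 2, B = 2)), seed = 1)
#' paths <- writeFixtureGPRs(d$arrays, tempfile("gpr"))
#' readGPR(paths$gpr[1])
readGPR <- function(path, fgColumn = "auto", bgColumn = "auto",
                    arrayId = basename(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    info <- gprHeaderInfo(path)
    df <- read.delim(path, skip = info$skip, check.names = FALSE,
        quote = "\"", stringsAsFactors = FALSE)
    if (!nrow(df)) stop("no spot records in ", path)
    fgName <- matchIntensityColumn(names(df), fgColumn,
        "^F\\d+ Median$", "foreground")
    bgName <- matchIntensityColumn(names(df), bgColumn,
        "^B\\d+ Median$", "background")
    for (geo in c("Block", "Row", "Column"))
        if (!geo %in% names(df))
            stop("missing required column '", geo, "' in ", path)
    dataStart <- info$skip + 2L  # 1-based line number of first data row
    for (col in c(fgName, bgName)) {
        v <- df[[col]]
        if (!is.numeric(v)) {
            num <- suppressWarnings(as.numeric(v))
            bad <- which(is.na(num) & !is.na(v) & v != "NA")
            if (length(bad))
                stop("non-numeric value '", v[bad[1]], "' in column '",
                    col, "' at line ", dataStart + bad[1] - 1L,
                    " of ", path)
            df[[col]] <- num
        }
    }
    spots <- data.frame(
        Block = as.integer(df$Block),
        Row = as.integer(df$Row),
        Column = as.integer(df$Column),
        ID = as.character(pickColumn(df, c("ID", "Id"),
            default = rep("", nrow(df)))),
        Name = as.character(pickColumn(df, c("Name", "name"),
            default = rep("", nrow(df)))),
        Fg = df[[fgName]],
        Bg = df[[bgName]],
        Flag = as.integer(pickColumn(df, c("Flags", "Flag"),
            default = rep(0L, nrow(df)))),
        stringsAsFactors = FALSE
    )
    spots$ID[is.na(spots$ID)] <- ""
    spots$Name[is.na(spots$Name)] <- ""
    spots$Category <- defaultCategory(spots$Name)
    dup <- duplicated(spots[, c("Block", "Row", "Column")])
    if (any(dup))
        stop("duplicate spot coordinates (Block=", spots$Block[dup][1],
            ", Row=", spots$Row[dup][1], ", Column=",
            spots$Column[dup][1], ") in ", path)
    new("SpotTable", arrayId = arrayId, spots = spots,
        fgColumn = fgName, bgColumn = bgName)
}

#' Read a targets (metadata) table
#'
#' Tab-delimited with required headers \code{FileName}, \code{SampleID} and
#' \code{Condition}; extra columns are kept as covariates.
#'
#' @param path Path to the targets file.
#' @return A \code{data.frame}.
#' @export
readTargets <- function(path) {
    tg <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("FileName", "SampleID", "Condition")
    miss <- setdiff(need, names(tg))
    if (length(miss))
        stop("targets file missing required header(s): ",
            paste(miss, collapse = ", "))
    if (anyDuplicated(tg$FileName))
        stop("duplicate FileName entries in targets file")
    tg
}

#' Read a probe annotation (category) list
#'
#' Tab-delimited file with \code{ID} (probe identifier) and
#' \code{Category} columns; probes not listed default to category
#' \code{"sample"} when the map is applied.
#'
#' @param path Path to the annotation file.
#' @return Named character vector mapping probe ID to category; empty when
#'   the file has no rows.
#' @export
readProbeAnnotations <- function(path) {
    df <- tryCatch(
        read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
        error = function(e) data.frame())
    if (!nrow(df)) return(setNames(character(0), character(0)))
    idcol <- intersect(c("ID", "Probe", "probe_id"), names(df))[1]
    catcol <- intersect(c("Category", "category"), names(df))[1]
    if (is.na(idcol) || is.na(catcol))
        stop("probe annotation file needs ID and Category columns")
    ids <- as.character(df[[idcol]])
    cats <- tolower(as.character(df[[catcol]]))
    agg <- tapply(cats, ids, unique)
    bad <- names(agg)[vapply(agg, length, 1L) > 1L]
    if (length(bad))
        stop("conflicting categories for probe(s): ",
            paste(bad, collapse = ", "))
    setNames(vapply(agg, `[`, "", 1L), names(agg))
}

#' Apply a probe-category map to an array set
#'
#' @param aset A \linkS4class{ProteinArraySet}.
#' @param categories Named character vector (probe ID -> category), as from
#'   \code{\link{readProbeAnnotations}}.  Unlisted probes keep their
#'   current category.
#' @return The annotated \linkS4class{ProteinArraySet}.
#' @export
applyProbeAnnotations <- function(aset, categories) {
    if (!length(categories)) return(aset)
    rd <- SummarizedExperiment::rowData(aset)
    hit <- match(rd$ID, names(categories))
    upd <- !is.na(hit)
    rd$Category[upd] <- unname(categories[hit[upd]])
    SummarizedExperiment::rowData(aset) <- rd
    aset
}

#' Assemble aligned arrays into a ProteinArraySet
#'
#' All arrays must share identical spot geometry and probe annotation,
#' row by row; columns are ordered as in the targets table, matched by
#' \code{FileName} against each table's array ID.
#'
#' @param tables List of \linkS4class{SpotTable}s.
#' @param targets Targets \code{data.frame} with \code{FileName},
#'   \code{SampleID}, \code{Condition}.
#' @return A linear-scale \linkS4class{ProteinArraySet}.
#' @export
assembleArraySet <- function(tables, targets) {
    if (length(tables) < 2L) stop("need at least 2 arrays to assemble")
    ids <- vapply(tables, function(tb) tb@arrayId, "")
    hit <- match(targets$FileName, ids)
    if (anyNA(hit))
        stop("targets FileName(s) not among loaded arrays: ",
            paste(targets$FileName[is.na(hit)], collapse = ", "))
    if (length(hit) != length(tables))
        stop("loaded arrays without a targets entry: ",
            paste(setdiff(ids, targets$FileName), collapse = ", "))
    tables <- tables[hit]
    refSpots <- tables[[1]]@spots
    keyCols <- c("Block", "Row", "Column", "ID", "Name")
    for (i in seq_along(tables)[-1]) {
        sp <- tables[[i]]@spots
        if (nrow(sp) != nrow(refSpots))
            stop("array '", tables[[i]]@arrayId, "' has ", nrow(sp),
                " spots but '", tables[[1]]@arrayId, "' has ",
                nrow(refSpots))
        same <- vapply(seq_len(nrow(sp)), function(r)
            identical(unname(unlist(sp[r, keyCols])),
                unname(unlist(refSpots[r, keyCols]))), NA)
        if (!all(same))
            stop("spot annotation mismatch between '",
                tables[[i]]@arrayId, "' and '", tables[[1]]@arrayId,
                "' first at spot row ", which(!same)[1])
    }
    E <- vapply(tables, function(tb) tb@spots$Fg, numeric(nrow(refSpots)))
    B <- vapply(tables, function(tb) tb@spots$Bg, numeric(nrow(refSpots)))
    colnames(E) <- colnames(B) <- targets$SampleID
    rd <- S4Vectors::DataFrame(refSpots[, c("Block", "Row", "Column", "ID",
        "Name", "Category", "Flag")])
    cd <- S4Vectors::DataFrame(targets, row.names = targets$SampleID)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fg = E, bg = B), rowData = rd, colData = cd,
        metadata = list(logState = "linear",
            processing = paste0("read:", length(tables), " arrays (fg=",
                tables[[1]]@fgColumn, ", bg=", tables[[1]]@bgColumn, ")"))
    )
    new("ProteinArraySet", se)
}

#' Write a labelled matrix as tab-delimited text
#'
#' First column holds the row (probe) identifiers under the header
#' \code{"ID"}, the remaining header fields are the column (sample)
#' identifiers; missing values are written as \code{NA}.  The file
#' round-trips losslessly through \code{\link{readMatrix}}.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @export
writeMatrix <- function(m, path) {
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("matrix must have row and column labels")
    txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    df <- data.frame(ID = rownames(m), txt,
        check.names = FALSE, stringsAsFactors = FALSE)
    df[-1][is.na(m)] <- "NA"
    names(df) <- c("ID", colnames(m))
    ok <- tryCatch({
        write.table(df, path, sep = "\t", quote = FALSE,
            row.names = FALSE)
        TRUE
    }, error = function(e) stop("cannot write ", path, ": ",
        conditionMessage(e)))
    invisible(ok)
}

#' @rdname writeMatrix
#' @param check.names Passed to \code{read.delim}; kept \code{FALSE}.
#' @return \code{readMatrix}: the numeric matrix with labels restored.
#' @export
readMatrix <- function(path, check.names = FALSE) {
    df <- read.delim(path, check.names = check.names,
        stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1]]
    m
}
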