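test_that("ATF-dialect GPR files parse with automatic column detection", {
    path <- withr::local_tempfile(fileext = ".gpr")
    writeTinyGPR(path)
    st <- readGPR(path)
    expect_s4_class(st, "SpotTable")
    expect_equal(nrow(st@spots), 6L)
    expect_equal(st@fgColumn, "F635 Median")
    expect_equal(st@bgColumn, "B635 Median")
    expect_equal(st@spots$Fg, 200 + 10 * (1:6))
    expect_equal(st@spots$Bg, 90 + 1:6)
    expect_equal(st@spots$ID, sprintf("g%d", 1:6))
    expect_equal(st@spots$Category, rep("sample", 6))
})

test_that("parsing is insensitive to CRLF line endings and extra columns", {
    lf <- withr::local_tempfile(fileext = ".gpr")
    crlf <- withr::local_tempfile(fileext = ".gpr")
    writeTinyGPR(lf, extraChannel = TRUE)
    writeTinyGPR(crlf, extraChannel = TRUE, eol = "\r\n")
    a <- readGPR(lf, fgColumn = "F635 Median", bgColumn = "B635 Median")
    b <- readGPR(crlf, fgColumn = "F635 Median", bgColumn = "B635 Median")
    expect_equal(a@spots$Fg, b@spots$Fg)
    expect_equal(a@spots$Bg, b@spots$Bg)
})

test_that("auto mode breaks channel ties by the lowest wavelength", {
    path <- withr::local_tempfile(fileext = ".gpr")
    writeTinyGPR(path, extraChannel = TRUE)
    st <- readGPR(path)
    expect_equal(st@fgColumn, "F532 Median")
    expect_equal(st@bgColumn, "B532 Median")
})

test_that("missing or ambiguous intensity columns raise configuration errors", {
    path <- withr::local_tempfile(fileext = ".gpr")
    writeTinyGPR(path)
    expect_error(readGPR(path, fgColumn = "F532 Median"),
        "F532 Median.*available columns")
    ## plain tab-delimited file without the GenePix naming scheme
    txt <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("Block\tColumn\tRow\tID\tSignal\tNoise",
        "1\t1\t1\tg1\t100\t50"), txt)
    expect_error(readGPR(txt), "no foreground intensity column")
    st <- readGPR(txt, fgColumn = "Signal", bgColumn = "Noise")
    expect_equal(st@spots$Fg, 100)
})

test_that("malformed spot records are rejected with informative errors", {
    bad <- withr::local_tempfile(fileext = ".gpr")
    lines <- readLines(writeTinyGPR(withr::local_tempfile()))
    lines[8] <- sub("230", "oops", lines[8])  # third data row
    writeLines(lines, bad)
    expect_error(readGPR(bad), "non-numeric value 'oops'.*line 8")
    dup <- withr::local_tempfile(fileext = ".gpr")
    lines <- readLines(writeTinyGPR(withr::local_tempfile()))
    lines[7] <- lines[6]  # duplicate (Block,Row,Column)
    writeLines(lines, dup)
    expect_error(readGPR(dup), "duplicate spot coordinates")
})

test_that("limma reads the same intensities from our fixtures", {
    skip_if_not_installed("limma")
    sim <- simulateArraySet(simDesign(nProteins = 20,
        nArraysPerCondition = c(A = 2, B = 2)), seed = 4)
    dir <- withr::local_tempdir()
    fx <- writeFixtureGPRs(sim$arrays, dir)
    rg <- limma::read.maimages(fx$gpr, source = "generic",
        columns = list(G = "F635 Median", Gb = "B635 Median"),
        annotation = c("Block", "Row", "Column", "ID", "Name"),
        verbose = FALSE, green.only = TRUE)
    expect_equal(unname(rg$E), unname(fgIntensity(sim$arrays)),
        tolerance = 1e-12)
    expect_equal(unname(rg$Eb), unname(bgIntensity(sim$arrays)),
        tolerance = 1e-12)
})

test_that("aligned spot tables assemble into a ProteinArraySet", {
    dir <- withr::local_tempdir()
    paths <- vapply(1:4, function(i)
        writeTinyGPR(file.path(dir, sprintf("a%d.gpr", i))), "")
    tables <- lapply(paths, readGPR)
    targets <- data.frame(FileName = basename(paths),
        SampleID = sprintf("S%d", 1:4),
        Condition = rep(c("A", "B"), 2))
    aset <- assembleArraySet(tables, targets)
    expect_s4_class(aset, "ProteinArraySet")
    expect_equal(dim(aset), c(6L, 4L))
    expect_equal(logState(aset), "linear")
    expect_equal(colnames(fgIntensity(aset)), targets$SampleID)
    ## geometry mismatch
    short <- tables
    short[[2]]@spots <- short[[2]]@spots[-6, ]
    expect_error(assembleArraySet(short, targets), "has 5 spots")
    ## unmatched file name
    targets2 <- targets
    targets2$FileName[1] <- "missing.gpr"
    expect_error(assembleArraySet(tables, targets2), "missing.gpr")
})

test_that("probe annotation lists override default categories", {
    ann <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("ID\tCategory", "g1\tcontrol", "g2\tempty"), ann)
    cats <- readProbeAnnotations(ann)
    expect_equal(unname(cats[c("g1", "g2")]), c("control", "empty"))
    path <- withr::local_tempfile(fileext = ".gpr")
    writeTinyGPR(path)
    tables <- lapply(list(path, path), readGPR)
    tables[[2]]@arrayId <- "b.gpr"
    aset <- assembleArraySet(tables, data.frame(
        FileName = c(basename(path), "b.gpr"),
        SampleID = c("S1", "S2"), Condition = c("A", "B")))
    aset <- applyProbeAnnotations(aset, cats)
    expect_equal(probeInfo(aset)$Category[1:3],
        c("control", "empty", "sample"))
    ## empty annotation file leaves categories alone
    empty <- withr::local_tempfile(fileext = ".tsv")
    writeLines("ID\tCategory", empty)
    expect_length(readProbeAnnotations(empty), 0L)
    ## conflicting duplicate rejected
    conf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("ID\tCategory", "g1\tcontrol", "g1\tempty"), conf)
    expect_error(readProbeAnnotations(conf), "conflicting categories.*g1")
})

test_that("matrix output round-trips losslessly including missing values", {
    m <- matrix(c(1.25, NA, pi, -2.5e-3), 2, 2,
        dimnames = list(c("p1", "p2"), c("s1", "s2")))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeMatrix(m, path)
    txt <- readLines(path)
    expect_equal(sum(grepl("\tNA", txt)), 1L)
    back <- readMatrix(path)
    expect_equal(back, m, tolerance = 1e-15)
    ## duplicate probe labels preserved verbatim
    m2 <- matrix(1:4, 2, 2,
        dimnames = list(c("dup", "dup"), c("s1", "s2")))
    writeMatrix(m2, path)
    expect_equal(readLines(path)[2:3],
        c("dup\t1\t3", "dup\t2\t4"))
    expect_error(writeMatrix(unname(m), path), "labels")
})

test_that("read-assemble-write-read is an identity on intensities", {
    sim <- simulateArraySet(simDesign(nProteins = 15,
        nArraysPerCondition = c(A = 2, B = 2)), seed = 9)
    dir <- withr::local_tempdir()
    fx <- writeFixtureGPRs(sim$arrays, dir)
    tables <- lapply(fx$gpr, readGPR)
    aset <- assembleArraySet(tables, readTargets(fx$targets))
    expect_equal(fgIntensity(aset), fgIntensity(sim$arrays))
    expect_equal(bgIntensity(aset), bgIntensity(sim$arrays))
    path <- withr::local_tempfile(fileext = ".tsv")
    m <- fgIntensity(aset)
    rownames(m) <- probeInfo(aset)$ID
    ## duplicate IDs across replicate blocks are preserved at I/O level
    writeMatrix(m, path)
    back <- readMatrix(path)
    expect_equal(unname(back), unname(m), tolerance = 1e-15)
})
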