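# Confidential export archives: format contract, round-trip
# equivalence, audit soundness.

test_that("the archive contains exactly the three text members", {
    f <- withr::local_tempfile(fileext = ".qcm")
    exportConfidential(fixModel60(), f, originLabel = "A")
    expect_identical(sort(untar(f, list = TRUE, tar = "internal")),
                     sort(c("parameters.txt", "scaler.tsv",
                            "coefficients.tsv")))
})

test_that("exports are deterministic byte-for-byte", {
    f1 <- withr::local_tempfile(fileext = ".qcm")
    f2 <- withr::local_tempfile(fileext = ".qcm")
    exportConfidential(fixModel60(), f1)
    exportConfidential(fixModel60(), f2)
    expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                     readBin(f2, "raw", file.size(f2) + 10))
})

test_that("import(export(m)) predicts identically to the open model", {
    f <- withr::local_tempfile(fileext = ".qcm")
    exportConfidential(fixModel60(), f, originLabel = "B")
    cm <- importConfidential(f)
    expect_s4_class(cm, "ConfidentialModel")
    expect_identical(lockState(cm), "closed")
    expect_identical(lockState(fixModel60()), "open")
    expect_identical(cm@originLabel, "B")
    expect_identical(trainingSize(cm), trainingSize(fixModel60()))
    p1 <- predict(fixModel60(), fixTest100())
    p2 <- predictConfidential(cm, fixTest100())
    expect_identical(p1$call, p2$call)
    expect_lt(max(abs(p1$score - p2$score)), 1e-9)
})

test_that("the archive carries no trace of the training structures", {
    f <- withr::local_tempfile(fileext = ".qcm")
    exportConfidential(fixModel60(), f)
    ex <- withr::local_tempdir()
    untar(f, exdir = ex, tar = "internal")
    txt <- unlist(lapply(list.files(ex, full.names = TRUE), readLines))
    mols <- molecules(fixSeries60())
    for (smi in mols$smiles)
        expect_false(any(grepl(smi, txt, fixed = TRUE)))
    for (key in inchiKey(fixSeries60()))
        expect_false(any(grepl(key, txt, fixed = TRUE)))
    for (id in mols$record_id)
        expect_false(any(grepl(id, txt, fixed = TRUE)))
})

test_that("archive content depends on the model, not the training set size", {
    # two models with identical scaling/coefficients but different n
    # give archives differing only in the training_size line
    m1 <- fixModel60()
    m2 <- m1
    m2@trainingSize <- 999L
    f1 <- withr::local_tempfile(fileext = ".qcm")
    f2 <- withr::local_tempfile(fileext = ".qcm")
    ConfQSAR:::.writeQcm(m1, f1, "A")
    ConfQSAR:::.writeQcm(m2, f2, "A")
    ex1 <- withr::local_tempdir(); ex2 <- withr::local_tempdir()
    untar(f1, exdir = ex1, tar = "internal")
    untar(f2, exdir = ex2, tar = "internal")
    for (member in c("scaler.tsv", "coefficients.tsv"))
        expect_identical(readLines(file.path(ex1, member)),
                         readLines(file.path(ex2, member)))
    d <- setdiff(readLines(file.path(ex2, "parameters.txt")),
                 readLines(file.path(ex1, "parameters.txt")))
    expect_identical(d, "training_size = 999")
})

test_that("malformed archives give descriptive errors", {
    f <- withr::local_tempfile(fileext = ".qcm")
    exportConfidential(fixModel60(), f)
    rebuild <- function(mutate) {
        ex <- tempfile(); dir.create(ex)
        untar(f, exdir = ex, tar = "internal")
        mutate(ex)
        out <- tempfile(fileext = ".qcm")
        owd <- setwd(ex); on.exit(setwd(owd))
        tar(out, files = list.files(ex), compression = "gzip",
            tar = "internal")
        out
    }
    # truncated coefficients: intercept line lost
    trunc <- rebuild(function(ex) {
        p <- file.path(ex, "coefficients.tsv")
        lines <- readLines(p)
        writeLines(head(lines, -1), p)
    })
    expect_error(importConfidential(trunc), "coefficients.tsv.*intercept")
    # missing member
    miss <- rebuild(function(ex) unlink(file.path(ex, "scaler.tsv")))
    expect_error(importConfidential(miss), "scaler.tsv")
    # index mismatch between scaler and coefficients
    mism <- rebuild(function(ex) {
        p <- file.path(ex, "scaler.tsv")
        lines <- readLines(p)
        lines[2] <- sub("^[0-9]+", "9999", lines[2])
        writeLines(lines, p)
    })
    expect_error(importConfidential(mism), "indices")
    expect_error(importConfidential(tempfile()), "not found")
})

test_that("the audit passes clean exports and detects planted leaks", {
    f <- withr::local_tempfile(fileext = ".qcm")
    exportConfidential(fixModel60(), f)
    expect_true(auditArchive(f)$pass)
    rebuild <- function(mutate) {
        ex <- tempfile(); dir.create(ex)
        untar(f, exdir = ex, tar = "internal")
        mutate(ex)
        out <- tempfile(fileext = ".qcm")
        owd <- setwd(ex); on.exit(setwd(owd))
        tar(out, files = list.files(ex), compression = "gzip",
            tar = "internal")
        out
    }
    leaks <- list(
        smiles_in_parameters = function(ex)
            cat("note = CCOc1ccc(N)cc1\n",
                file = file.path(ex, "parameters.txt"), append = TRUE),
        inchikey_in_parameters = function(ex)
            cat("ref = LFQSCWFLJHTTHZ-UHFFFAOYSA-N\n",
                file = file.path(ex, "parameters.txt"), append = TRUE),
        molblock_in_scaler = function(ex)
            cat("  OpenBabel 2D\n$$$$\n",
                file = file.path(ex, "scaler.tsv"), append = TRUE),
        extra_member = function(ex)
            writeLines("c1ccccc1", file.path(ex, "training.smi")),
        index_mismatch = function(ex) {
            p <- file.path(ex, "scaler.tsv")
            lines <- readLines(p)
            lines[2] <- sub("^[0-9]+", "2047", lines[2])
            writeLines(lines, p)
        })
    for (nm in names(leaks)) {
        rep <- auditArchive(rebuild(leaks[[nm]]))
        expect_false(rep$pass, info = nm)
        expect_gt(length(rep$findings), 0)
    }
})

test_that("open models save to and load from a directory", {
    d <- withr::local_tempdir()
    saveLocalModel(fixModel60(), file.path(d, "m"))
    expect_true(file.exists(file.path(d, "m", "training_series.txt")))
    m2 <- loadLocalModel(file.path(d, "m"))
    expect_s4_class(m2, "LocalModel")
    expect_identical(m2@provenance, fixModel60()@provenance)
    p1 <- predict(fixModel60(), fixTest100())
    p2 <- predict(m2, fixTest100())
    expect_identical(p1$call, p2$call)
    expect_lt(max(abs(p1$score - p2$score)), 1e-9)
})
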