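# Reading, writing and standardizing annotated series.

test_that("SDF round-trip preserves ids, structures and labels", {
    s <- fixSeries60()
    f <- withr::local_tempfile(fileext = ".sdf")
    writeSeries(s, f, labelField = "activity")
    s2 <- readSeries(f, labelField = "activity")
    expect_identical(molecules(s2)$record_id, molecules(s)$record_id)
    expect_identical(molecules(s2)$smiles, molecules(s)$smiles)
    expect_identical(seriesLabels(s2), seriesLabels(s))
    # a second round trip is the identity
    f2 <- withr::local_tempfile(fileext = ".sdf")
    writeSeries(s2, f2, labelField = "activity")
    s3 <- readSeries(f2, labelField = "activity")
    expect_identical(molecules(s3), molecules(s2))
    expect_identical(seriesLabels(s3), seriesLabels(s2))
})

test_that("SMILES-table round-trip preserves every record", {
    s <- fixSeries60()
    for (ext in c(".csv", ".tsv")) {
        f <- withr::local_tempfile(fileext = ext)
        writeSeries(s, f, labelField = "label")
        s2 <- readSeries(f, labelField = "label")
        expect_identical(molecules(s2)$smiles, molecules(s)$smiles)
        expect_identical(seriesLabels(s2), seriesLabels(s))
    }
})

test_that("labels map from positive/negative text and 0/1", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,smiles,label", "a,CCO,positive", "b,CCN,Negative",
                 "c,CCC,1"), f)
    s <- readSeries(f, labelField = "label")
    expect_identical(seriesLabels(s), c(1L, 0L, 1L))
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,smiles,label", "a,CCO,maybe"), f2)
    expect_error(readSeries(f2, labelField = "label"), "maybe")
})

test_that("a corrupt mol block yields parse_ok = FALSE, not a crash", {
    s <- annotatedSeries(c("a", "b", "c"), c("CCO", "CCN", "CCC"),
                         c(1L, 0L, 1L))
    f <- withr::local_tempfile(fileext = ".sdf")
    writeSeries(s, f)
    lines <- readLines(f)
    # mangle the counts line of the second record
    ends <- which(trimws(lines) == "$$$$")
    lines[ends[1] + 4L] <- "not a counts line at all"
    writeLines(lines, f)
    expect_warning(s2 <- readSeries(f), "could not be parsed")
    expect_identical(sum(!molecules(s2)$parse_ok), 1L)
    expect_identical(length(s2), 3L)
    expect_false(molecules(s2)$parse_ok[2])
})

test_that("missing label field names the record in the error", {
    s <- annotatedSeries("only", "CCO", 1L)
    f <- withr::local_tempfile(fileext = ".sdf")
    writeSeries(s, f, labelField = "activity")
    expect_error(readSeries(f, labelField = "missing_field"),
                 "missing_field")
    expect_error(readSeries(file.path(tempdir(), "no-such-file.sdf")),
                 "cannot read")
})

test_that("standardization strips salts and neutralizes charges", {
    s <- annotatedSeries(c("salt", "plain", "cation"),
                         c("CC(=O)[O-].[Na+]", "CCO", "CC[NH3+]"),
                         c(1L, 0L, 0L))
    st <- standardizeSeries(s)
    expect_identical(molecules(st)$smiles[1], canonicalSmiles("CC(=O)O"))
    expect_identical(molecules(st)$smiles[2], canonicalSmiles("CCO"))
    expect_identical(molecules(st)$smiles[3], canonicalSmiles("CCN"))
    expect_identical(seriesLabels(st), seriesLabels(s))
})

test_that("standardization is idempotent and keeps zwitterionic nitro", {
    s <- standardizeSeries(fixSeries60())
    s2 <- standardizeSeries(s)
    expect_identical(molecules(s2)$smiles, molecules(s)$smiles)
    nb <- standardizeSeries(annotatedSeries("nb",
                                            "c1ccc(cc1)[N+](=O)[O-]", 1L))
    expect_true(grepl("N\\+", molecules(nb)$smiles[1]) ||
                grepl("\\[N\\+\\]", molecules(nb)$smiles[1]))
})

test_that("InChIKeys are well-formed and canonicalization-invariant", {
    k <- inchiKey(c("CCO", "OCC", "C(C)O"))
    expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", k)))
    expect_identical(k[1], k[2])
    expect_identical(k[1], k[3])
    # reference value from the standard InChI implementation
    expect_identical(unname(k[1]), "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
})

test_that("protonation states differ only in the InChIKey tail", {
    neutral <- inchiKey("CC(=O)O")
    anion <- inchiKey("CC(=O)[O-]")
    expect_false(identical(neutral, anion))
    expect_identical(substr(neutral, 1, 25), substr(anion, 1, 25))
})

test_that("series subsetting and accessors are consistent", {
    s <- fixSeries60()
    sub <- s[1:10]
    expect_identical(length(sub), 10L)
    expect_identical(seriesLabels(sub), seriesLabels(s)[1:10])
    expect_identical(molecules(sub)$record_id,
                     molecules(s)$record_id[1:10])
    expect_error(annotatedSeries(c("a", "a"), c("C", "C"), c(0L, 1L)),
                 "unique")
})
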