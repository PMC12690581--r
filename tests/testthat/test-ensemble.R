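# Ensembles: logical rules, trained combiners, cutouts.

test_that("the OR and majority rules reproduce the published truth table", {
    # all 16 four-member vectors, grouped by number of positives
    for (k in 0:4) {
        vs <- combn(4, k, function(pos) {
            v <- rep(0L, 4); v[pos] <- 1L; v
        })
        if (is.null(dim(vs))) vs <- matrix(vs, nrow = 4)
        for (j in seq_len(ncol(vs))) {
            v <- vs[, j]
            expect_identical(combineOr(v), as.integer(k >= 1))
            expect_identical(combineMajority(v), as.integer(k > 2))
        }
    }
})

test_that("rules generalize to other ensemble sizes and flag errors", {
    expect_identical(combineMajority(c(1, 1, 0)), 1L)
    expect_identical(combineMajority(c(1, 0, 0)), 0L)
    expect_identical(combineOr(c(0, 0, 0)), 0L)
    expect_error(combineOr(c(NA, NA)), "failed")
    expect_error(combineMajority(c(1, NA, 0)), "error flags")
})

test_that("a four-member metamodel sees at most 16 distinct inputs", {
    grid <- ConfQSAR:::.allPatterns(4)
    expect_identical(nrow(grid), 16L)
    expect_identical(anyDuplicated(rownames(grid)), 0L)
    expect_identical(nrow(ConfQSAR:::.allPatterns(3)), 8L)
})

test_that("all three combiners learn a consistent pattern mapping exactly", {
    grid <- ConfQSAR:::.allPatterns(4)
    # a consistent, realistic mapping: positive iff >= 2 members agree
    yPat <- as.integer(rowSums(grid) >= 2)
    P <- grid[rep(seq_len(16), 5), ]           # 5 copies per pattern
    y <- yPat[rep(seq_len(16), 5)]
    tables <- lapply(c("RF", "SVM", "XGBoost"), function(alg)
        ConfQSAR:::.fitCombiner(P, y, alg, seed = 5))
    for (tb in tables)
        expect_identical(unname(tb), yPat)     # zero training error
    expect_identical(tables[[1]], tables[[2]])
    expect_identical(tables[[1]], tables[[3]])
})

test_that("metamodel training and prediction run the full protocol", {
    e <- suppressWarnings(trainMetamodel(fixMembers(), fixEvalSeries(),
                                         "RF", seed = 2))
    expect_s4_class(e, "EnsembleModel")
    expect_identical(combinationRule(e), "METAMODEL")
    expect_identical(names(members(e)), LETTERS[1:4])
    pr <- predictEnsemble(e, fixEvalSeries())
    expect_identical(ncol(pr$memberCalls), 4L)
    expect_true(all(pr$predictions$call %in% c(0L, 1L)))
    # the ensemble call equals the stored truth table applied by hand
    key <- apply(pr$memberCalls, 1, paste, collapse = "")
    expect_identical(pr$predictions$call,
                     unname(e@combiner$table[key]))
    # determinism
    e2 <- suppressWarnings(trainMetamodel(fixMembers(), fixEvalSeries(),
                                          "RF", seed = 2))
    expect_identical(e@combiner$table, e2@combiner$table)
    expect_error(suppressWarnings(trainMetamodel(
        fixMembers(), fixEvalSeries()[seriesLabels(fixEvalSeries()) == 1],
        "RF")), "both classes")
})

test_that("OR dominates member sensitivity and is dominated in specificity", {
    members <- fixMembers()
    s <- fixEvalSeries()
    y <- seriesLabels(s)
    eOr <- buildEnsemble(members, "LOGICAL_OR")
    prOr <- predictEnsemble(eOr, s)$predictions$call
    ccOr <- confusionCounts(prOr, y)
    for (m in members) {
        cc <- confusionCounts(predictConfidential(m, s)$call, y)
        expect_gte(sensitivity(ccOr), sensitivity(cc))
        expect_lte(specificity(ccOr), specificity(cc))
    }
})

test_that("majority voting equals the members' call when they all agree", {
    members <- fixMembers()
    s <- fixEvalSeries()
    calls <- vapply(members, function(m) predictConfidential(m, s)$call,
                    integer(length(s)))
    agree <- rowSums(calls == 1L) %in% c(0L, 4L)
    skip_if(sum(agree) < 5)
    eMaj <- buildEnsemble(members, "MAJORITY")
    pr <- predictEnsemble(eMaj, s)$predictions$call
    expect_identical(pr[agree], calls[agree, 1])
})

test_that("cutout removes exactly one member and never consults it", {
    members <- fixMembers()
    e <- buildEnsemble(members, "MAJORITY")
    ce <- cutout(e, "B")
    expect_identical(length(members(ce)), 3L)
    expect_false("B" %in% names(members(ce)))
    # isolation: predictions equal an ensemble built without B
    eNoB <- buildEnsemble(members[-2], "MAJORITY")
    s <- fixEvalSeries()[1:40]
    expect_identical(predictEnsemble(ce, s)$predictions,
                     predictEnsemble(eNoB, s)$predictions)
    # 3-member majority has no ties
    pr <- predictEnsemble(ce, s)
    expect_false(anyNA(pr$predictions$call))
    expect_error(cutout(e, "Z"), "origin")
    two <- buildEnsemble(members[1:2], "MAJORITY")
    expect_error(cutout(two, "A"), "at least 3")
})

test_that("metamodel cutouts retrain on the stored training series", {
    e <- suppressWarnings(trainMetamodel(fixMembers(), fixEvalSeries(),
                                         "XGBoost", seed = 3))
    ce <- cutout(e, "D")
    expect_identical(combinationRule(ce), "METAMODEL")
    expect_identical(length(members(ce)), 3L)
    expect_identical(length(ce@combiner$table), 8L)
})

test_that("ensembles survive a save/load round trip", {
    d <- withr::local_tempdir()
    e <- suppressWarnings(trainMetamodel(fixMembers(), fixEvalSeries(),
                                         "SVM", seed = 4))
    saveEnsemble(e, file.path(d, "ens"))
    expect_true(file.exists(file.path(d, "ens", "ensemble.txt")))
    e2 <- loadEnsemble(file.path(d, "ens"))
    expect_identical(combinationRule(e2), "METAMODEL")
    expect_identical(e2@combiner$table, e@combiner$table)
    s <- fixEvalSeries()[1:30]
    expect_identical(predictEnsemble(e2, s)$predictions,
                     predictEnsemble(e, s)$predictions)
})
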