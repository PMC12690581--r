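# Fragment-grammar generator: construction guarantees, determinism,
# noise calibration, multi-partner partitions.

test_that("noise-free generation matches the requested composition", {
    s <- generateSeries(100, positiveFraction = 0.5, flipNoise = 0,
                        scaffoldPool = "benzenoid", seed = 21)
    expect_identical(length(s), 100L)
    expect_identical(sum(seriesLabels(s) == 1L), 50L)
    det <- hasActivatingNitro(molecules(s)$smiles)
    expect_identical(det, seriesLabels(s) == 1L)
    expect_identical(s@groundTruth$ruleLabels, seriesLabels(s))
})

test_that("every generated molecule parses and is standardizer-stable", {
    for (pool in c("benzenoid", "azines", "fivering", "fused",
                   "aliphatic")) {
        s <- generateSeries(40, if (pool == "aliphatic") 0 else 0.5, 0,
                            pool, seed = 31)
        expect_true(all(molecules(s)$parse_ok), info = pool)
        st <- standardizeSeries(s)
        expect_identical(molecules(st)$smiles, molecules(s)$smiles,
                         info = pool)
    }
})

test_that("aliphatic pools cannot express the aromatic-nitro signal", {
    expect_error(generateSeries(20, 0.5, 0, "aliphatic", seed = 1),
                 "positives")
    expect_error(generateSeries(20, 0.5, 0, "nosuchpool", seed = 1),
                 "unknown scaffold pool")
})

test_that("label flips follow the seeded binomial noise model", {
    s <- generateSeries(1000, 0.5, flipNoise = 0.1, seed = 5,
                        scaffoldPool = "azines")
    flips <- sum(seriesLabels(s) != s@groundTruth$ruleLabels)
    ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
    expect_gte(flips, ci[1])
    expect_lte(flips, ci[2])
    expect_identical(sort(s@groundTruth$flipped),
                     which(seriesLabels(s) != s@groundTruth$ruleLabels))
})

test_that("generation is deterministic per seed", {
    a <- generateSeries(50, 0.5, 0.1, "fivering", seed = 9)
    b <- generateSeries(50, 0.5, 0.1, "fivering", seed = 9)
    expect_identical(molecules(a), molecules(b))
    expect_identical(seriesLabels(a), seriesLabels(b))
    c <- generateSeries(50, 0.5, 0.1, "fivering", seed = 10)
    expect_false(identical(molecules(a)$smiles, molecules(c)$smiles))
})

test_that("deactivated-nitro decoys are rule-negative by construction", {
    s <- generateSeries(200, 0.5, 0, "benzenoid", seed = 41,
                        decoyFraction = 0.3)
    mols <- molecules(s)$smiles
    decoy <- hasAromaticNitro(mols) & !hasActivatingNitro(mols)
    expect_gt(sum(decoy), 0)
    expect_true(all(seriesLabels(s)[decoy] == 0L))
    # decoys can be disabled
    s0 <- generateSeries(100, 0.5, 0, "benzenoid", seed = 42,
                         decoyFraction = 0)
    expect_identical(sum(hasAromaticNitro(molecules(s0)$smiles) &
                         seriesLabels(s0) == 0L), 0L)
})

test_that("train and cvd halves of a grammar never share molecules", {
    tr <- generateSeries(150, 0.5, 0, "benzenoid", seed = 51,
                         comboHalf = "train")
    cv <- generateSeries(150, 0.5, 0, "benzenoid", seed = 52,
                         comboHalf = "cvd")
    expect_identical(intersect(molecules(tr)$smiles,
                               molecules(cv)$smiles), character(0))
})

fixPartition <- function()
    fixture("partition", function()
        generatePartnerPartition(4, sizes = rep(120L, 4), cvdSize = 200L,
                                 overlapWithCvd = c(10L, 5L, 0L, 2L),
                                 flipNoise = 0.05, seed = 61))

test_that("planted validation overlap is recovered by deduplication", {
    part <- fixPartition()
    planted <- part$cvd@groundTruth$planted
    expect_identical(nrow(planted), 17L)
    flags <- lapply(part$partners, function(p)
        flagDuplicates(part$cvd, p))
    # every planted copy is found by its own partner via InChIKey
    for (i in 1:4) {
        mine <- planted$cvd_record_id[planted$partner == LETTERS[i]]
        fl <- flags[[i]]
        hit <- fl[fl$cvd_record_id %in% mine, ]
        expect_true(all(hit$found), info = LETTERS[i])
        expect_true(all(hit$reason == "inchikey"), info = LETTERS[i])
    }
    cons <- consolidateFlags(flags, part$cvd)
    union <- unique(unlist(lapply(flags, function(f)
        f$cvd_record_id[f$found])))
    expect_identical(length(cons$series), length(part$cvd) - length(union))
    expect_true(all(planted$cvd_record_id %in% union))
})

test_that("zero overlap leaves the validation series untouched", {
    part <- generatePartnerPartition(2, sizes = c(60L, 60L),
                                     cvdSize = 80L,
                                     overlapWithCvd = c(0L, 0L),
                                     flipNoise = 0, seed = 71)
    expect_identical(nrow(part$cvd@groundTruth$planted), 0L)
    keys <- lapply(part$partners, function(p)
        substr(inchiKey(p), 1, 25))
    cvdKeys <- substr(inchiKey(part$cvd), 1, 25)
    expect_identical(intersect(cvdKeys, unlist(keys)), character(0))
    expect_error(generatePartnerPartition(
        2, c(60L, 60L), cvdSize = 10L, overlapWithCvd = c(8L, 8L),
        seed = 1), "larger than")
})

test_that("models transfer poorly to other partners' scaffold regions", {
    own <- generateSeries(150, 0.5, 0.05, "benzenoid", seed = 81,
                          comboHalf = "cvd")
    other <- generateSeries(150, 0.5, 0.05, "azines", seed = 82,
                            comboHalf = "cvd")
    train <- generateSeries(200, 0.5, 0.05, "benzenoid", seed = 83,
                            comboHalf = "train")
    m <- suppressWarnings(fitPLSDA(train, modelConfig(seed = 83)))
    mccOn <- function(s) suppressWarnings(
        mcc(confusionCounts(predict(m, s)$call, seriesLabels(s))))
    expect_gt(mccOn(own), mccOn(other))
})
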