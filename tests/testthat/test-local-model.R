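# Undersampling, scaling, selection, PLS-DA fitting and metrics.

test_that("undersampling balances to the minority-class size", {
    s <- generateSeries(206, positiveFraction = 41 / 206, flipNoise = 0,
                        scaffoldPool = "benzenoid", seed = 7)
    expect_identical(as.vector(table(seriesLabels(s))), c(165L, 41L))
    b <- undersample(s, seed = 7)
    expect_identical(as.vector(table(seriesLabels(b))), c(41L, 41L))
    # no-op on balanced input
    bal <- b
    expect_identical(undersample(bal, seed = 1), bal)
    # deterministic per seed, different across seeds
    expect_identical(molecules(undersample(s, 3))$record_id,
                     molecules(undersample(s, 3))$record_id)
    expect_false(identical(molecules(undersample(s, 3))$record_id,
                           molecules(undersample(s, 4))$record_id))
})

test_that("undersampling handles extreme imbalance and rejects one class", {
    s <- fixSeries60()
    idx <- c(which(seriesLabels(s) == 1L)[1], which(seriesLabels(s) == 0L))
    tiny <- s[idx]
    b <- undersample(tiny, seed = 1)
    expect_identical(as.vector(table(seriesLabels(b))), c(1L, 1L))
    expect_error(undersample(s[seriesLabels(s) == 1L], 1), "both classes")
})

test_that("the scaler records population statistics and scales to z-scores", {
    X <- cbind(a = c(0, 0, 0, 0), b = c(1, 0, 1, 0), c = c(1, 1, 1, 0))
    sc <- fitScaler(X, bitIndex = c(10L, 20L, 30L))
    expect_identical(sc$bit_index, c(10L, 20L, 30L))
    expect_equal(sc$mean, c(0, 0.5, 0.75))
    expect_equal(sc$sd[1], 0)
    expect_equal(sc$sd[2], 0.5)
    Z <- ConfQSAR:::.applyScaler(X, sc)
    expect_equal(unname(colMeans(Z)), c(0, 0, 0), tolerance = 1e-12)
    expect_equal(unname(apply(Z[, 2:3], 2, function(z)
        sqrt(mean(z^2)))), c(1, 1), tolerance = 1e-9)
    expect_equal(unname(Z[, 1]), rep(0, 4))   # sd = 0 column scales to 0
    expect_error(fitScaler(X[0, , drop = FALSE]), "empty|2 rows")
})

test_that("top-K selection finds the label-aligned bit first", {
    set.seed(33)
    n <- 60
    y <- rep(c(1L, 0L), n / 2)
    X <- matrix(rbinom(n * 40, 1, 0.4), n, 40)
    X[, 17] <- y   # perfectly informative bit
    # brute-force oracle: one-way ANOVA F per column
    f <- apply(X, 2, function(col) suppressWarnings({
        fit <- stats::anova(stats::lm(col ~ factor(y)))
        fit$`F value`[1]
    }))
    f[apply(X, 2, function(c) all(c == c[1]))] <- -Inf
    expect_identical(selectTopK(X, y, 1L), 16L)   # 0-based
    expect_identical(sort(selectTopK(X, y, 5L)),
                     sort(order(-f, seq_along(f))[1:5] - 1L))
    # saturation: k >= number of non-constant features
    expect_warning(all40 <- selectTopK(X, y, 500L), "non-constant")
    expect_true(length(all40) <= 40L)
    # invariance under row permutation
    p <- sample(n)
    expect_identical(selectTopK(X, y, 10L), selectTopK(X[p, ], y[p], 10L))
    expect_error(selectTopK(X, rep(1L, n), 5L), "both classes")
})

test_that("confusion counts and quality metrics follow their definitions", {
    expect_identical(confusionCounts(c(1, 0, 1, 0), c(1, 0, 1, 0)),
                     c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
    expect_identical(confusionCounts(c(0, 1, 0, 1), c(1, 0, 1, 0)),
                     c(TP = 0L, TN = 0L, FP = 2L, FN = 2L))
    expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "equal length")
    set.seed(9)
    calls <- rbinom(20, 1, 0.5); truth <- rbinom(20, 1, 0.5)
    cc <- confusionCounts(calls, truth)
    expect_identical(unname(cc["TP"]), sum(calls == 1 & truth == 1))
    expect_identical(sum(cc), 20L)
    expect_equal(mcc(c(TP = 10, TN = 10, FP = 0, FN = 0)), 1)
    expect_equal(mcc(c(TP = 0, TN = 0, FP = 10, FN = 10)), -1)
    expect_equal(mcc(c(TP = 3, TN = 4, FP = 1, FN = 2)), 10 / sqrt(600))
    expect_warning(z <- mcc(c(TP = 0, TN = 5, FP = 0, FN = 0)),
                   "denominator")
    expect_identical(z, 0)
    expect_equal(sensitivity(c(TP = 3, TN = 4, FP = 1, FN = 2)), 0.6)
    expect_equal(specificity(c(TP = 3, TN = 4, FP = 1, FN = 2)), 0.8)
})

test_that("metrics stay in range on random confusion counts", {
    set.seed(4)
    for (i in 1:50) {
        cc <- c(TP = rpois(1, 5), TN = rpois(1, 5),
                FP = rpois(1, 5), FN = rpois(1, 5))
        m <- suppressWarnings(mcc(cc))
        expect_true(m >= -1 && m <= 1)
        sn <- suppressWarnings(sensitivity(cc))
        sp <- suppressWarnings(specificity(cc))
        expect_true(is.na(sn) || (sn >= 0 && sn <= 1))
        expect_true(is.na(sp) || (sp >= 0 && sp <= 1))
    }
})

test_that("prediction equals the explicit linear form", {
    m <- fixModel60()
    s <- fixTest100()
    p <- predict(m, s)
    fp <- morganFingerprints(s)
    sc <- scalingStats(m)
    X <- fp@bits[, sc$bit_index + 1L, drop = FALSE]
    # independent dot-product oracle
    for (i in c(1, 25, 100)) {
        z <- (X[i, ] - sc$mean) / ifelse(sc$sd == 0, Inf, sc$sd)
        expect_equal(p$score[i],
                     sum(coef(m) * z) + m@intercept, tolerance = 1e-9)
    }
    expect_identical(p$call, as.integer(p$score >= decisionThreshold(m)))
})

test_that("the fitted model reproduces its training-time calls", {
    m <- fixModel60()
    bal <- undersample(fixSeries60(), modelConfigOf(m)@seed)
    p <- predict(m, bal)
    expect_true(all(p$ok))
    expect_identical(trainingSize(m), length(bal))
    expect_true(m@nLatent %in% modelConfigOf(m)@lvGrid)
    expect_true(decisionThreshold(m) %in% modelConfigOf(m)@thresholdGrid)
})

test_that("PLS1 agrees with an established PLS implementation", {
    skip_if_not_installed("mixOmics")
    set.seed(42)
    n <- 50; k <- 20
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("v", 1:k)))
    y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n) > 0)
    Z <- scale(X)
    fit <- ConfQSAR:::.pls1(Z, y, 4)
    mo <- mixOmics::pls(Z, matrix(y, ncol = 1,
                                  dimnames = list(NULL, "y")),
                        ncomp = 4, mode = "regression", scale = FALSE)
    for (h in c(1, 4)) {
        ours <- as.numeric(Z %*% fit$B[[h]]) + fit$intercept
        theirs <- predict(mo, Z)$predict[, 1, h]
        expect_equal(ours, unname(theirs), tolerance = 1e-8)
    }
})

test_that("cross-validation metrics are consistent with per-fold counts", {
    cv <- suppressWarnings(crossValidate(fixSeries60(), fastConfig()))
    expect_identical(nrow(cv$perFold), 5L)
    expect_true(all(cv$perFold$mcc >= -1 & cv$perFold$mcc <= 1))
    expect_equal(unname(cv$mean["mcc"]), mean(cv$perFold$mcc))
    expect_true(cv$nLatent %in% fastConfig()@lvGrid)
    expect_true(cv$threshold %in% fastConfig()@thresholdGrid)
    # determinism
    cv2 <- suppressWarnings(crossValidate(fixSeries60(), fastConfig()))
    expect_identical(cv, cv2)
})

test_that("retraining from a seed model reuses only the configuration", {
    seedModel <- fixModel60()
    other <- generateSeries(60, 0.5, 0, "azines", seed = 55)
    m2 <- suppressWarnings(retrainFromSeed(seedModel, other))
    expect_identical(modelConfigOf(m2), modelConfigOf(seedModel))
    expect_false(identical(coef(m2), coef(seedModel)))
    expect_identical(m2@provenance, seriesName(other))
    # retraining on the same series with the same config is a refit
    m3 <- suppressWarnings(retrainFromSeed(seedModel, fixSeries60()))
    expect_equal(coef(m3), coef(seedModel))
    expect_error(retrainFromSeed("not a model", other), "ModelConfig")
})
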