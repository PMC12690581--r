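# Company-local PLS-DA models on circular fingerprints.
#
# Protocol: random undersampling of the majority class, fingerprinting,
# autoscaling (mean 0 / sd 1), univariate top-K feature selection, PLS1
# regression on the 0/1 class code, and a grid search over latent
# variables and decision thresholds scored by mean 5-fold CV MCC. The
# fitted model collapses to one coefficient per selected feature plus an
# intercept, applied to autoscaled bits.

# run expr with a private, restored RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
    expr
}

#' Balance a series by random undersampling
#'
#' Randomly subsamples the majority class, without replacement, down to
#' the minority-class size. The retained records keep their original
#' order. Deterministic for a given seed.
#'
#' @param series an \code{\linkS4class{AnnotatedSeries}} with both
#'   classes present
#' @param seed integer seed
#' @return the balanced series
#' @export
undersample <- function(series, seed = 1L) {
    stopifnot(is(series, "AnnotatedSeries"))
    y <- seriesLabels(series)
    nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
    if (nPos == 0L || nNeg == 0L)
        stop("undersampling requires both classes present", call. = FALSE)
    if (nPos == nNeg) return(series)
    majority <- if (nPos > nNeg) 1L else 0L
    majIdx <- which(y == majority)
    keepMaj <- .withSeed(seed, sample(majIdx, min(nPos, nNeg)))
    series[sort(c(which(y != majority), keepMaj))]
}

#' Per-feature scaling statistics
#'
#' Records the mean and standard deviation (denominator n, matching the
#' convention of autoscaling a fitted population of descriptors) of each
#' candidate feature. Constant features are recorded with \code{sd = 0};
#' at prediction time their scaled value is defined as 0.
#'
#' @param X numeric/integer matrix (rows = compounds)
#' @param bitIndex 0-based bit indices labelling the columns
#' @return data.frame with columns \code{bit_index}, \code{mean},
#'   \code{sd}
#' @export
fitScaler <- function(X, bitIndex = seq_len(ncol(X)) - 1L) {
    if (!nrow(X) || !ncol(X)) stop("empty matrix", call. = FALSE)
    if (nrow(X) < 2L) stop("at least 2 rows required", call. = FALSE)
    m <- colMeans(X)
    s <- sqrt(colMeans(sweep(X, 2, m)^2))
    data.frame(bit_index = as.integer(bitIndex), mean = as.numeric(m),
               sd = as.numeric(s))
}

# apply scaling stats to a matrix of raw bits (columns aligned to the
# stats rows); sd = 0 columns scale to 0
.applyScaler <- function(X, stats) {
    Z <- sweep(X, 2, stats$mean)
    sd <- stats$sd
    sd[sd == 0] <- Inf
    sweep(Z, 2, sd, "/")
}

#' Univariate top-K feature selection
#'
#' Ranks features by an ANOVA-F class-separation score (one-way F
#' statistic of the feature between the two classes) and returns the
#' 0-based indices of the K best, sorted. Ties are broken in favor of
#' the lower bit index. Constant features never qualify; if fewer than K
#' non-constant features exist, all of them are returned with a warning.
#'
#' @param X matrix of descriptors (rows = compounds, all 2048 bits)
#' @param y 0/1 labels
#' @param k number of features to keep
#' @return sorted integer vector of 0-based column indices
#' @export
selectTopK <- function(X, y, k = 500L) {
    stopifnot(k >= 1L, nrow(X) == length(y))
    if (length(unique(y)) < 2L)
        stop("feature selection requires both classes", call. = FALSE)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L); n <- n1 + n0
    m1 <- colMeans(X[y == 1L, , drop = FALSE])
    m0 <- colMeans(X[y == 0L, , drop = FALSE])
    m <- colMeans(X)
    ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
    # within-group sum of squares, computed per class
    ssw <- colSums((X - matrix(ifelse(y == 1L, 1, 0)) %*% rbind(m1) -
                    matrix(ifelse(y == 0L, 1, 0)) %*% rbind(m0))^2)
    f <- (ssb / 1) / (ssw / (n - 2))
    constant <- apply(X, 2, function(col) all(col == col[1]))
    f[constant] <- -Inf
    f[!constant & !is.finite(f)] <- Inf   # perfect separators, ssw = 0
    nonconst <- sum(!constant)
    kEff <- min(k, nonconst)
    if (kEff < k)
        warning("only ", nonconst, " non-constant features available; ",
                "returning all of them")
    ord <- order(-f, seq_along(f))
    sort(ord[seq_len(kEff)]) - 1L
}

# ---- PLS1 (NIPALS) --------------------------------------------------------

# Fit PLS1 regression of centered y on column-scaled X; returns the
# collapsed regression vectors for every number of components 1..ncomp
# (list B with one k-vector per H, possibly fewer if the residual
# vanishes) plus the intercept (mean of y, X being centered).
.pls1 <- function(Z, y, ncomp) {
    n <- nrow(Z); k <- ncol(Z)
    ybar <- mean(y)
    y0 <- y - ybar
    X0 <- Z
    W <- matrix(0, k, 0); P <- matrix(0, k, 0); q <- numeric(0)
    for (h in seq_len(ncomp)) {
        w <- crossprod(X0, y0)
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) break
        w <- w / nw
        t <- X0 %*% w
        tt <- sum(t^2)
        if (tt < 1e-12) break
        p <- crossprod(X0, t) / tt
        qh <- sum(y0 * t) / tt
        X0 <- X0 - t %*% t(p)
        y0 <- y0 - qh * t
        W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qh)
    }
    H <- length(q)
    B <- vector("list", H)
    for (h in seq_len(H)) {
        Wh <- W[, seq_len(h), drop = FALSE]
        Ph <- P[, seq_len(h), drop = FALSE]
        B[[h]] <- as.numeric(Wh %*% solve(crossprod(Ph, Wh), q[seq_len(h)]))
    }
    list(B = B, intercept = ybar, ncomp = H)
}

# ---- confusion counts and quality metrics ---------------------------------

#' Confusion counts
#'
#' @param calls 0/1 predicted calls
#' @param truth 0/1 true labels
#' @return named integer vector with elements TP, TN, FP, FN
#' @export
confusionCounts <- function(calls, truth) {
    if (length(calls) != length(truth))
        stop("calls and truth must have equal length", call. = FALSE)
    keep <- !is.na(calls) & !is.na(truth)
    calls <- calls[keep]; truth <- truth[keep]
    c(TP = sum(calls == 1L & truth == 1L),
      TN = sum(calls == 0L & truth == 0L),
      FP = sum(calls == 1L & truth == 0L),
      FN = sum(calls == 0L & truth == 1L))
}

#' Classification quality metrics
#'
#' Sensitivity = TP/(TP+FN); specificity = TN/(TN+FP); MCC =
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Degenerate
#' denominators give NA (sensitivity/specificity) or 0 (MCC), with a
#' warning.
#'
#' @param counts a named vector as returned by
#'   \code{\link{confusionCounts}}
#' @return a number
#' @export
sensitivity <- function(counts) {
    d <- counts[["TP"]] + counts[["FN"]]
    if (d == 0) { warning("no positives in truth"); return(NA_real_) }
    counts[["TP"]] / d
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
    d <- counts[["TN"]] + counts[["FP"]]
    if (d == 0) { warning("no negatives in truth"); return(NA_real_) }
    counts[["TN"]] / d
}

#' @rdname sensitivity
#' @export
mcc <- function(counts) {
    TP <- as.numeric(counts[["TP"]]); TN <- as.numeric(counts[["TN"]])
    FP <- as.numeric(counts[["FP"]]); FN <- as.numeric(counts[["FN"]])
    den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    if (den == 0) {
        warning("MCC denominator is 0; returning 0")
        return(0)
    }
    (TP * TN - FP * FN) / sqrt(den)
}

# ---- grid-search cross-validation core ------------------------------------

# stratified fold assignment, deterministic for a seed
.stratifiedFolds <- function(y, k, seed) {
    folds <- integer(length(y))
    .withSeed(seed, {
        for (cls in unique(y)) {
            idx <- sample(which(y == cls))
            folds[idx] <- rep_len(seq_len(k), length(idx))
        }
    })
    folds
}

# Full-pipeline CV over the (latent variables x threshold) grid.
# X: raw bit matrix (all bits); y: labels. Returns mean CV MCC per grid
# cell, the selected (nLatent, threshold), and per-fold metrics at the
# selected cell.
.gridCV <- function(X, y, config) {
    kcv <- config@cvFolds
    lvG <- config@lvGrid
    thG <- config@thresholdGrid
    folds <- .stratifiedFolds(y, kcv, config@seed)
    maxLV <- max(lvG)
    scoreMat <- array(NA_real_, c(length(y), maxLV))  # CV score per compound/H
    for (f in seq_len(kcv)) {
        tr <- folds != f; te <- !tr
        ytr <- y[tr]
        if (length(unique(ytr)) < 2L || length(unique(y[te])) < 2L)
            stop("a CV fold lost one of the classes; use fewer folds or ",
                 "more data", call. = FALSE)
        sel <- selectTopK(X[tr, , drop = FALSE], ytr, config@kSelected)
        sc <- fitScaler(X[tr, sel + 1L, drop = FALSE], sel)
        Ztr <- .applyScaler(X[tr, sel + 1L, drop = FALSE], sc)
        Zte <- .applyScaler(X[te, sel + 1L, drop = FALSE], sc)
        fit <- .pls1(Ztr, ytr, maxLV)
        for (h in seq_len(maxLV)) {
            hh <- min(h, fit$ncomp)
            scoreMat[te, h] <- as.numeric(Zte %*% fit$B[[hh]]) +
                fit$intercept
        }
    }
    meanMCC <- matrix(NA_real_, length(lvG), length(thG),
                      dimnames = list(lvG, thG))
    for (a in seq_along(lvG)) for (b in seq_along(thG)) {
        perFold <- vapply(seq_len(kcv), function(f) {
            te <- folds == f
            calls <- as.integer(scoreMat[te, lvG[a]] >= thG[b])
            suppressWarnings(mcc(confusionCounts(calls, y[te])))
        }, numeric(1))
        meanMCC[a, b] <- mean(perFold)
    }
    # best cell: max mean MCC, ties to fewer latent variables then lower
    # threshold (row-major scan order does exactly that)
    best <- which(t(meanMCC) == max(meanMCC))[1] - 1L
    ai <- best %/% length(thG) + 1L
    bi <- best %% length(thG) + 1L
    nLatent <- lvG[ai]; threshold <- thG[bi]
    perFold <- do.call(rbind, lapply(seq_len(kcv), function(f) {
        te <- folds == f
        calls <- as.integer(scoreMat[te, nLatent] >= threshold)
        cc <- confusionCounts(calls, y[te])
        data.frame(fold = f,
                   sensitivity = suppressWarnings(sensitivity(cc)),
                   specificity = suppressWarnings(specificity(cc)),
                   mcc = suppressWarnings(mcc(cc)))
    }))
    list(meanMCC = meanMCC, nLatent = nLatent, threshold = threshold,
         perFold = perFold, cvMCC = meanMCC[ai, bi])
}

# ---- model fitting --------------------------------------------------------

#' Fit a local PLS-DA model
#'
#' Runs the full protocol: undersample the majority class, compute
#' circular fingerprints, autoscale, keep the top-K features by ANOVA-F,
#' and fit PLS1 on the 0/1 class code. The number of latent variables
#' and the decision threshold are chosen by maximizing the mean MCC in a
#' stratified 5-fold CV grid search (ties: fewer latent variables, then
#' lower threshold); the final model is refit on all balanced data.
#'
#' @param series training \code{\linkS4class{AnnotatedSeries}} (raw;
#'   balancing is applied internally)
#' @param config a \code{\linkS4class{ModelConfig}}
#' @return a \code{\linkS4class{LocalModel}} (open lock)
#' @export
fitPLSDA <- function(series, config = modelConfig()) {
    stopifnot(is(series, "AnnotatedSeries"), is(config, "ModelConfig"))
    validObject(config)
    bal <- undersample(series, config@seed)
    bal <- bal[molecules(bal)$parse_ok]
    y <- seriesLabels(bal)
    if (min(table(y)) < config@cvFolds)
        stop("need at least cvFolds compounds per class after balancing",
             call. = FALSE)
    fp <- morganFingerprints(bal, nBits = config@nBits,
                             radius = config@radius)
    X <- fp@bits
    cv <- .gridCV(X, y, config)
    sel <- selectTopK(X, y, config@kSelected)
    sc <- fitScaler(X[, sel + 1L, drop = FALSE], sel)
    Z <- .applyScaler(X[, sel + 1L, drop = FALSE], sc)
    fit <- .pls1(Z, y, cv$nLatent)
    H <- min(cv$nLatent, fit$ncomp)
    new("LocalModel",
        config = config, scaling = sc,
        coefficients = fit$B[[H]], intercept = fit$intercept,
        threshold = cv$threshold, nLatent = as.integer(cv$nLatent),
        trainingSize = length(y), provenance = seriesName(series),
        cvSummary = cv$perFold)
}

#' Cross-validated quality of the modeling protocol
#'
#' Runs the stratified k-fold grid-search CV on a series (after
#' undersampling), refitting selection and scaling inside every fold,
#' and reports per-fold and mean sensitivity, specificity and MCC at
#' the grid-optimal latent-variable count and threshold.
#'
#' @inheritParams fitPLSDA
#' @return list with elements \code{perFold} (data.frame),
#'   \code{mean} (named vector), \code{nLatent}, \code{threshold}
#' @export
crossValidate <- function(series, config = modelConfig()) {
    stopifnot(is(series, "AnnotatedSeries"))
    bal <- undersample(series, config@seed)
    bal <- bal[molecules(bal)$parse_ok]
    y <- seriesLabels(bal)
    fp <- morganFingerprints(bal, nBits = config@nBits,
                             radius = config@radius)
    cv <- .gridCV(fp@bits, y, config)
    list(perFold = cv$perFold,
         mean = c(sensitivity = mean(cv$perFold$sensitivity),
                  specificity = mean(cv$perFold$specificity),
                  mcc = mean(cv$perFold$mcc)),
         nLatent = cv$nLatent, threshold = cv$threshold)
}

#' Retrain a seed model on a new series
#'
#' Reuses only the configuration of the seed (its coefficients are
#' discarded) and refits the full protocol on the new series, exactly
#' as the model-exchange workflow prescribes.
#'
#' @param seed a \code{\linkS4class{LocalModel}},
#'   \code{\linkS4class{ConfidentialModel}} or
#'   \code{\linkS4class{ModelConfig}}
#' @param series the new training series
#' @return a \code{\linkS4class{LocalModel}}
#' @export
retrainFromSeed <- function(seed, series) {
    config <- if (is(seed, "PLSLinearModel")) modelConfigOf(seed)
              else if (is(seed, "ModelConfig")) seed
              else stop("seed must be a model or a ModelConfig",
                        call. = FALSE)
    fitPLSDA(series, config)
}

# ---- prediction -----------------------------------------------------------

# score + call for any collapsed linear model
.predictLinear <- function(object, series) {
    stopifnot(is(series, "AnnotatedSeries"))
    mols <- molecules(series)
    cfg <- object@config
    fp <- morganFingerprints(series, nBits = cfg@nBits,
                             radius = cfg@radius)
    sc <- object@scaling
    score <- rep(NA_real_, nrow(mols))
    ok <- rep(FALSE, nrow(mols))
    if (nrow(fp@bits)) {
        Z <- .applyScaler(fp@bits[, sc$bit_index + 1L, drop = FALSE], sc)
        s <- as.numeric(Z %*% object@coefficients) + object@intercept
        rows <- match(fp@recordIds, mols$record_id)
        score[rows] <- s
        ok[rows] <- TRUE
    }
    data.frame(record_id = mols$record_id,
               score = score,
               call = ifelse(ok, as.integer(score >= object@threshold),
                             NA_integer_),
               ok = ok,
               stringsAsFactors = FALSE)
}

#' Predict a series with a fitted model
#'
#' Returns one row per record: the raw PLS score
#' (sum of coefficient times autoscaled bit, plus intercept) and the
#' binary call (\code{score >= threshold}). Unparseable records get
#' \code{ok = FALSE} and NA score/call rather than an error.
#'
#' @param object a \code{\linkS4class{LocalModel}} or
#'   \code{\linkS4class{ConfidentialModel}}
#' @param newdata an \code{\linkS4class{AnnotatedSeries}}
#' @param ... ignored
#' @return data.frame with columns record_id, score, call, ok
#' @export
setMethod("predict", "PLSLinearModel",
          function(object, newdata, ...) .predictLinear(object, newdata))
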