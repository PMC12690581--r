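# Ensembles of confidential models: logical OR, majority voting, and
# trained metamodels (RF / SVM / XGBoost) on the members' binary calls.
#
# A trained combiner is collapsed at training time into its complete
# truth table over all 2^m member-call patterns (there are at most 16
# for four members), which makes it deterministic, auditable and
# serializable as plain text without loss.

#' Logical-OR combination
#'
#' Positive when any member call is positive, negative otherwise.
#'
#' @param v 0/1 member calls for one compound (member-ordered)
#' @return 0 or 1
#' @export
combineOr <- function(v) {
    if (all(is.na(v)))
        stop("all member predictions failed for this compound",
             call. = FALSE)
    if (anyNA(v))
        stop("unresolved member error flags; resolve or drop the compound",
             call. = FALSE)
    as.integer(any(v == 1L))
}

#' Majority-voting combination
#'
#' Positive only when strictly more members call positive than
#' negative; ties are negative (for four members, 2 of 4 positives is a
#' negative call).
#'
#' @inheritParams combineOr
#' @return 0 or 1
#' @export
combineMajority <- function(v) {
    if (all(is.na(v)))
        stop("all member predictions failed for this compound",
             call. = FALSE)
    if (anyNA(v))
        stop("unresolved member error flags; resolve or drop the compound",
             call. = FALSE)
    as.integer(sum(v == 1L) > sum(v == 0L))
}

#' Build a rule-based ensemble
#'
#' @param members list of \code{\linkS4class{ConfidentialModel}}s; names
#'   default to the members' origin labels
#' @param rule \code{"LOGICAL_OR"} or \code{"MAJORITY"} (use
#'   \code{\link{trainMetamodel}} for trained combiners)
#' @return an \code{\linkS4class{EnsembleModel}}
#' @export
buildEnsemble <- function(members, rule = c("LOGICAL_OR", "MAJORITY")) {
    rule <- match.arg(rule)
    members <- .nameMembers(members)
    new("EnsembleModel", members = members, rule = rule,
        combinerAlgorithm = NA_character_, combiner = NULL, seed = 0L)
}

.nameMembers <- function(members) {
    stopifnot(is.list(members))
    if (is.null(names(members)) || !all(nzchar(names(members))))
        names(members) <- vapply(members, function(m) m@originLabel,
                                 character(1))
    members
}

# all 2^m call patterns as a matrix (rows ordered by positive count,
# then binary value) with rownames "0101"-style keys
.allPatterns <- function(m) {
    grid <- as.matrix(expand.grid(rep(list(0:1), m))[, m:1, drop = FALSE])
    colnames(grid) <- NULL
    grid <- grid[order(rowSums(grid), apply(grid, 1, paste, collapse = "")),
                 , drop = FALSE]
    rownames(grid) <- apply(grid, 1, paste, collapse = "")
    grid
}

.patternKey <- function(mat) apply(mat, 1, paste, collapse = "")

# fit one combiner on pattern matrix P (n x m, 0/1) and labels y (0/1),
# then collapse it to a truth table over all 2^m patterns
.fitCombiner <- function(P, y, algorithm, seed) {
    m <- ncol(P)
    grid <- .allPatterns(m)
    yf <- factor(y, levels = c(0, 1))
    Pf <- as.data.frame(lapply(as.data.frame(P), factor,
                               levels = c(0, 1)))
    names(Pf) <- paste0("m", seq_len(m))
    gridF <- as.data.frame(lapply(as.data.frame(grid), factor,
                                  levels = c(0, 1)))
    names(gridF) <- names(Pf)
    table <- .withSeed(seed, switch(algorithm,
        RF = {
            fit <- randomForest::randomForest(Pf, yf)
            as.integer(as.character(predict(fit, gridF)))
        },
        SVM = {
            fit <- e1071::svm(x = P, y = yf, scale = FALSE)
            as.integer(as.character(predict(fit, grid)))
        },
        XGBoost = {
            fit <- xgboost::xgb.train(
                params = list(objective = "binary:logistic",
                              nthread = 1),
                data = xgboost::xgb.DMatrix(P, label = y),
                nrounds = 50, verbose = 0)
            as.integer(predict(fit, xgboost::xgb.DMatrix(grid)) >= 0.5)
        },
        stop("unknown combiner algorithm: ", algorithm, call. = FALSE)))
    stats::setNames(table, rownames(grid))
}

#' Train a metamodel ensemble
#'
#' Predicts the training series with every member, uses the binary
#' member calls as the only predictors, and trains the requested
#' combiner (library defaults, seeded). The fitted combiner is stored
#' as its complete truth table over the 2^m member-call patterns.
#' Compounds for which any member prediction failed are dropped from
#' combiner training with a warning. The training series should be
#' disjoint from the members' training compounds (see
#' \code{\link{flagDuplicates}}).
#'
#' @param members list of \code{\linkS4class{ConfidentialModel}}s
#' @param trainingSeries labeled \code{\linkS4class{AnnotatedSeries}}
#' @param algorithm one of \code{"RF"}, \code{"SVM"}, \code{"XGBoost"}
#' @param seed integer seed for the combiner library
#' @return an \code{\linkS4class{EnsembleModel}} with rule
#'   \code{"METAMODEL"}
#' @export
trainMetamodel <- function(members, trainingSeries,
                           algorithm = c("RF", "SVM", "XGBoost"),
                           seed = 1L) {
    algorithm <- match.arg(algorithm)
    members <- .nameMembers(members)
    y <- seriesLabels(trainingSeries)
    if (length(unique(y)) < 2L)
        stop("metamodel training requires both classes", call. = FALSE)
    P <- .memberCallMatrix(members, trainingSeries)
    okRow <- stats::complete.cases(P)
    if (!all(okRow))
        warning(sum(!okRow), " compound(s) dropped from combiner ",
                "training (member prediction failures)")
    table <- .fitCombiner(P[okRow, , drop = FALSE], y[okRow], algorithm,
                          seed)
    e <- new("EnsembleModel", members = members, rule = "METAMODEL",
             combinerAlgorithm = algorithm,
             combiner = list(algorithm = algorithm, table = table),
             seed = as.integer(seed))
    attr(e@combiner, "trainingSeries") <- trainingSeries
    e
}

# binary member-call matrix for a series (NA where a member failed)
.memberCallMatrix <- function(members, series) {
    calls <- vapply(members, function(m) .predictLinear(m, series)$call,
                    integer(length(series)))
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1)
    colnames(calls) <- names(members)
    rownames(calls) <- molecules(series)$record_id
    calls
}

#' Predict a series with an ensemble
#'
#' Member predictions are computed once; the rule or the trained
#' combiner is applied per compound. Compounds where one or more member
#' predictions failed are excluded (NA call, \code{ok = FALSE}) and
#' reported, never imputed. The full member-call matrix is returned for
#' transparency.
#'
#' @param ensemble an \code{\linkS4class{EnsembleModel}}
#' @param series an \code{\linkS4class{AnnotatedSeries}}
#' @return list with \code{predictions} (data.frame record_id, call,
#'   ok) and \code{memberCalls} (n x m 0/1 matrix)
#' @export
predictEnsemble <- function(ensemble, series) {
    stopifnot(is(ensemble, "EnsembleModel"))
    P <- .memberCallMatrix(ensemble@members, series)
    ok <- stats::complete.cases(P)
    call <- rep(NA_integer_, nrow(P))
    if (any(ok)) {
        Pok <- P[ok, , drop = FALSE]
        call[ok] <- switch(ensemble@rule,
            LOGICAL_OR = as.integer(rowSums(Pok == 1L) >= 1L),
            MAJORITY = as.integer(rowSums(Pok == 1L) >
                                  rowSums(Pok == 0L)),
            METAMODEL = unname(
                ensemble@combiner$table[.patternKey(Pok)]))
    }
    if (any(!ok))
        warning(sum(!ok), " compound(s) excluded: member prediction ",
                "failures")
    list(predictions = data.frame(record_id = rownames(P),
                                  call = call, ok = ok,
                                  stringsAsFactors = FALSE),
         memberCalls = P)
}

#' Leave-one-partner-out ("cutout") ensemble
#'
#' Removes the member with the given origin label. Rule-based ensembles
#' keep their rule; metamodel combiners are retrained on the same
#' training series, restricted to the remaining members.
#'
#' @param ensemble an \code{\linkS4class{EnsembleModel}} with at least 3
#'   members
#' @param excludedOrigin origin label of the member to drop
#' @return an \code{\linkS4class{EnsembleModel}} without that member
#' @export
cutout <- function(ensemble, excludedOrigin) {
    stopifnot(is(ensemble, "EnsembleModel"))
    if (length(ensemble@members) < 3L)
        stop("cutout requires at least 3 members", call. = FALSE)
    if (!excludedOrigin %in% names(ensemble@members))
        stop("no member with origin label '", excludedOrigin, "'",
             call. = FALSE)
    keep <- ensemble@members[names(ensemble@members) != excludedOrigin]
    if (ensemble@rule == "METAMODEL") {
        ts <- attr(ensemble@combiner, "trainingSeries")
        if (is.null(ts))
            stop("metamodel cutout requires the stored training series",
                 call. = FALSE)
        trainMetamodel(keep, ts, ensemble@combinerAlgorithm,
                       seed = ensemble@seed)
    } else {
        new("EnsembleModel", members = keep, rule = ensemble@rule,
            combinerAlgorithm = NA_character_, combiner = NULL,
            seed = ensemble@seed)
    }
}

# ---- on-disk format -------------------------------------------------------

#' Save / load an ensemble directory
#'
#' An ensemble is stored as a directory of member \code{.qcm} archives
#' plus \code{ensemble.txt} (rule, member order, seed, and, for
#' metamodels, the combiner truth table) — text only.
#'
#' @param ensemble an \code{\linkS4class{EnsembleModel}}
#' @param dir directory to create
#' @return invisibly, \code{dir}
#' @export
saveEnsemble <- function(ensemble, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(ensemble@members)) {
        m <- ensemble@members[[nm]]
        lm <- new("LocalModel", config = m@config, scaling = m@scaling,
                  coefficients = m@coefficients, intercept = m@intercept,
                  threshold = m@threshold, nLatent = m@nLatent,
                  trainingSize = m@trainingSize, provenance = "",
                  cvSummary = data.frame())
        .writeQcm(lm, file.path(dir, paste0(nm, ".qcm")),
                  originLabel = nm)
    }
    lines <- c(paste("rule =", ensemble@rule),
               paste("members =", paste(names(ensemble@members),
                                        collapse = ",")),
               paste("seed =", ensemble@seed))
    if (ensemble@rule == "METAMODEL") {
        lines <- c(lines,
                   paste("algorithm =", ensemble@combinerAlgorithm),
                   paste0("pattern ", names(ensemble@combiner$table),
                          " = ", ensemble@combiner$table))
    }
    writeLines(lines, file.path(dir, "ensemble.txt"))
    invisible(dir)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(dir) {
    cfgPath <- file.path(dir, "ensemble.txt")
    if (!file.exists(cfgPath))
        stop("not an ensemble directory (ensemble.txt missing): ", dir,
             call. = FALSE)
    lines <- readLines(cfgPath)
    getVal <- function(key) {
        ln <- grep(paste0("^", key, " = "), lines, value = TRUE)
        if (!length(ln)) stop("ensemble.txt is missing '", key, "'",
                              call. = FALSE)
        sub(paste0("^", key, " = "), "", ln[1])
    }
    memberNames <- strsplit(getVal("members"), ",")[[1]]
    members <- stats::setNames(lapply(memberNames, function(nm)
        importConfidential(file.path(dir, paste0(nm, ".qcm")))),
        memberNames)
    rule <- getVal("rule")
    seed <- as.integer(getVal("seed"))
    if (rule == "METAMODEL") {
        pat <- grep("^pattern ", lines, value = TRUE)
        keys <- sub("^pattern ([01]+) = .*$", "\\1", pat)
        vals <- as.integer(sub("^pattern [01]+ = ", "", pat))
        new("EnsembleModel", members = members, rule = rule,
            combinerAlgorithm = getVal("algorithm"),
            combiner = list(algorithm = getVal("algorithm"),
                            table = stats::setNames(vals, keys)),
            seed = seed)
    } else {
        new("EnsembleModel", members = members, rule = rule,
            combinerAlgorithm = NA_character_, combiner = NULL,
            seed = seed)
    }
}
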