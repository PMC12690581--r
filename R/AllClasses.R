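#' @import methods
NULL

#' Annotated chemical series
#'
#' The unit of training and validation data: an ordered set of molecules,
#' each with a binary activity label (1 = positive, e.g. mutagenic;
#' 0 = negative). Molecules that failed to parse are retained as records
#' (with \code{parse_ok = FALSE}) so that nothing is silently dropped, but
#' they are excluded from descriptor matrices.
#'
#' @slot name series name (used as provenance in models trained on it)
#' @slot molecules data.frame with columns \code{record_id} (unique),
#'   \code{smiles} (canonical SMILES, \code{NA} if unparseable),
#'   \code{parse_ok} (logical) and \code{failure_reason} (character,
#'   \code{NA} unless \code{parse_ok} is \code{FALSE})
#' @slot labels integer vector of 0/1 activity labels, one per molecule
#' @slot groundTruth list of generator-side ground truth (rule labels
#'   before noise flips, planted duplicate ids); empty for data read from
#'   files
#' @export
setClass("AnnotatedSeries",
    representation(
        name = "character",
        molecules = "data.frame",
        labels = "integer",
        groundTruth = "list"
    ),
    prototype(
        name = "series",
        molecules = data.frame(
            record_id = character(), smiles = character(),
            parse_ok = logical(), failure_reason = character(),
            stringsAsFactors = FALSE
        ),
        labels = integer(),
        groundTruth = list()
    )
)

setValidity("AnnotatedSeries", function(object) {
    msg <- character()
    req <- c("record_id", "smiles", "parse_ok", "failure_reason")
    if (!all(req %in% names(object@molecules)))
        msg <- c(msg, paste("molecules must have columns:",
                            paste(req, collapse = ", ")))
    else {
        if (anyDuplicated(object@molecules$record_id))
            msg <- c(msg, "record_id values must be unique within a series")
        if (nrow(object@molecules) != length(object@labels))
            msg <- c(msg, "one label per molecule required")
        bad <- !is.na(object@labels) & !(object@labels %in% c(0L, 1L))
        if (any(bad))
            msg <- c(msg, "labels must be 0 or 1")
    }
    if (length(object@name) != 1L)
        msg <- c(msg, "name must be a single string")
    if (length(msg)) msg else TRUE
})

#' Binary fingerprint matrix aligned to a series
#'
#' Row i holds the folded circular fingerprint of the i-th retained
#' molecule of the series it was computed from. Molecules with
#' \code{parse_ok = FALSE} are excluded and their positions (in the
#' original series order) recorded in \code{excluded}.
#'
#' @slot bits integer matrix with entries in \{0, 1\}; one column per
#'   folded bit (2048 by default)
#' @slot recordIds record ids of the retained molecules, row-aligned
#' @slot excluded integer positions (in series order) of excluded records
#' @export
setClass("FingerprintMatrix",
    representation(
        bits = "matrix",
        recordIds = "character",
        excluded = "integer"
    )
)

setValidity("FingerprintMatrix", function(object) {
    msg <- character()
    if (!is.integer(object@bits))
        msg <- c(msg, "bits must be an integer matrix")
    else if (length(object@bits) && !all(object@bits %in% c(0L, 1L)))
        msg <- c(msg, "fingerprint entries must be 0 or 1")
    if (nrow(object@bits) != length(object@recordIds))
        msg <- c(msg, "one record id per fingerprint row required")
    if (length(msg)) msg else TRUE
})

#' Modeling configuration
#'
#' Hyperparameters of the local-model protocol: descriptor settings,
#' the number of top features retained by univariate selection, and the
#' cross-validated grid over PLS latent variables and decision thresholds.
#'
#' @slot nBits folded fingerprint length (2048)
#' @slot radius circular fingerprint radius (2)
#' @slot kSelected number of features kept by univariate selection (500)
#' @slot cvFolds number of stratified CV folds (5)
#' @slot lvGrid candidate numbers of PLS latent variables
#' @slot thresholdGrid candidate decision thresholds on the PLS score scale
#' @slot seed integer seed driving undersampling and fold assignment
#' @export
setClass("ModelConfig",
    representation(
        nBits = "integer", radius = "integer", kSelected = "integer",
        cvFolds = "integer", lvGrid = "integer", thresholdGrid = "numeric",
        seed = "integer"
    ),
    prototype(
        nBits = 2048L, radius = 2L, kSelected = 500L, cvFolds = 5L,
        lvGrid = 2:8, thresholdGrid = seq(0.2, 0.8, by = 0.05), seed = 1L
    )
)

setValidity("ModelConfig", function(object) {
    msg <- character()
    if (object@kSelected > object@nBits)
        msg <- c(msg, "kSelected must not exceed nBits")
    if (object@cvFolds < 2L)
        msg <- c(msg, "cvFolds must be at least 2")
    if (!length(object@lvGrid) || !length(object@thresholdGrid))
        msg <- c(msg, "lvGrid and thresholdGrid must be non-empty")
    if (any(object@lvGrid < 1L))
        msg <- c(msg, "latent-variable counts must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname ModelConfig-class
#' @param nBits,radius,kSelected,cvFolds,lvGrid,thresholdGrid,seed see slots
#' @return a \code{ModelConfig}
#' @export
modelConfig <- function(nBits = 2048L, radius = 2L, kSelected = 500L,
                        cvFolds = 5L, lvGrid = 2:8,
                        thresholdGrid = seq(0.2, 0.8, by = 0.05),
                        seed = 1L) {
    new("ModelConfig", nBits = as.integer(nBits), radius = as.integer(radius),
        kSelected = as.integer(kSelected), cvFolds = as.integer(cvFolds),
        lvGrid = as.integer(lvGrid), thresholdGrid = as.numeric(thresholdGrid),
        seed = as.integer(seed))
}

# Shared representation of a fitted PLS-DA model collapsed to its linear
# form: one coefficient per selected feature (applied to autoscaled bits)
# plus an intercept and a decision threshold. This is the complete
# information needed to predict, and exactly what a confidential export
# carries.
#' @export
setClass("PLSLinearModel",
    representation(
        "VIRTUAL",
        config = "ModelConfig",
        scaling = "data.frame",     # bit_index, mean, sd (sorted, unique)
        coefficients = "numeric",   # aligned to scaling rows
        intercept = "numeric",
        threshold = "numeric",
        nLatent = "integer",
        trainingSize = "integer"
    )
)

.validLinearModel <- function(object) {
    msg <- character()
    sc <- object@scaling
    if (!all(c("bit_index", "mean", "sd") %in% names(sc)))
        msg <- c(msg, "scaling must have columns bit_index, mean, sd")
    else {
        if (is.unsorted(sc$bit_index, strictly = TRUE))
            msg <- c(msg, "scaling bit indices must be unique and sorted")
        if (any(sc$bit_index < 0L | sc$bit_index >= object@config@nBits))
            msg <- c(msg, "scaling bit indices out of range")
        if (any(sc$sd < 0))
            msg <- c(msg, "scaling sd must be non-negative")
        if (length(object@coefficients) != nrow(sc))
            msg <- c(msg, "one coefficient per selected feature required")
    }
    if (length(object@trainingSize) && object@trainingSize < 1L)
        msg <- c(msg, "trainingSize must be at least 1")
    if (length(msg)) msg else TRUE
}

#' Company-local PLS-DA model (open lock)
#'
#' A model fitted locally on a training series the owner can see. Open
#' models retain the name of their training series as provenance and can
#' be exported as confidential archives.
#'
#' @slot provenance name of the training series
#' @slot cvSummary data.frame of per-fold CV metrics recorded at fit time
#' @export
setClass("LocalModel",
    contains = "PLSLinearModel",
    representation(provenance = "character", cvSummary = "data.frame")
)
setValidity("LocalModel", .validLinearModel)

#' Confidential (locked) model
#'
#' A model reconstructed from an export archive. It carries only the
#' information in the archive: configuration, per-feature scaling
#' statistics, coefficients, threshold and the training-series size —
#' no structures, identifiers or provenance beyond an anonymized origin
#' label. Its lock state is permanently "closed".
#'
#' @slot originLabel anonymized origin token (e.g. "A")
#' @export
setClass("ConfidentialModel",
    contains = "PLSLinearModel",
    representation(originLabel = "character")
)
setValidity("ConfidentialModel", function(object) {
    v <- .validLinearModel(object)
    if (!isTRUE(v)) return(v)
    if (length(object@originLabel) != 1L || !nzchar(object@originLabel))
        return("originLabel must be a non-empty string")
    TRUE
})

#' Ensemble of confidential models
#'
#' An ordered collection of locked member models plus a combination
#' rule. \code{LOGICAL_OR} and \code{MAJORITY} need no training;
#' \code{METAMODEL} wraps a classifier (RF, SVM or XGBoost) trained on
#' the members' binary prediction vectors.
#'
#' @slot members named list of \code{ConfidentialModel}s (names = origin
#'   labels, order immutable)
#' @slot rule one of \code{"LOGICAL_OR"}, \code{"MAJORITY"},
#'   \code{"METAMODEL"}
#' @slot combinerAlgorithm one of \code{"RF"}, \code{"SVM"},
#'   \code{"XGBoost"} when rule is \code{"METAMODEL"}
#' @slot combiner the fitted combiner object (empty list otherwise)
#' @slot seed seed used when training the combiner
#' @export
setClass("EnsembleModel",
    representation(
        members = "list",
        rule = "character",
        combinerAlgorithm = "character",
        combiner = "ANY",
        seed = "integer"
    ),
    prototype(combinerAlgorithm = NA_character_, combiner = NULL, seed = 1L)
)

setValidity("EnsembleModel", function(object) {
    msg <- character()
    if (length(object@members) < 2L)
        msg <- c(msg, "an ensemble requires at least 2 members")
    if (!all(vapply(object@members, is, logical(1), "ConfidentialModel")))
        msg <- c(msg, "all members must be ConfidentialModel objects")
    if (is.null(names(object@members)) ||
        anyDuplicated(names(object@members)))
        msg <- c(msg, "members must be uniquely named by origin label")
    if (!object@rule %in% c("LOGICAL_OR", "MAJORITY", "METAMODEL"))
        msg <- c(msg, "rule must be LOGICAL_OR, MAJORITY or METAMODEL")
    if (object@rule == "METAMODEL") {
        if (is.null(object@combiner))
            msg <- c(msg, "METAMODEL ensembles require a trained combiner")
        if (!object@combinerAlgorithm %in% c("RF", "SVM", "XGBoost"))
            msg <- c(msg, "combinerAlgorithm must be RF, SVM or XGBoost")
    } else if (!is.null(object@combiner)) {
        msg <- c(msg, "only METAMODEL ensembles carry a combiner")
    }
    if (length(msg)) msg else TRUE
})
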