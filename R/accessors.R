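#' @rdname AnnotatedSeries-class
#' @export
setMethod("seriesName", "AnnotatedSeries", function(object) object@name)

#' @rdname AnnotatedSeries-class
#' @export
setMethod("molecules", "AnnotatedSeries", function(object) object@molecules)

#' @rdname AnnotatedSeries-class
#' @export
setMethod("seriesLabels", "AnnotatedSeries", function(object) object@labels)

#' @rdname AnnotatedSeries-class
#' @export
setMethod("length", "AnnotatedSeries",
          function(x) nrow(x@molecules))

#' Subset a series by position
#' @rdname AnnotatedSeries-class
#' @param i integer or logical index
#' @param j,drop,... ignored
#' @export
setMethod("[", "AnnotatedSeries", function(x, i, j, ..., drop = FALSE) {
    new("AnnotatedSeries", name = x@name,
        molecules = x@molecules[i, , drop = FALSE],
        labels = x@labels[i],
        groundTruth = x@groundTruth)
})

#' @rdname AnnotatedSeries-class
#' @export
setMethod("show", "AnnotatedSeries", function(object) {
    n <- length(object)
    npos <- sum(object@labels == 1L, na.rm = TRUE)
    nbad <- sum(!object@molecules$parse_ok)
    cat("AnnotatedSeries \"", object@name, "\": ", n, " molecules (",
        npos, " positive, ", n - npos, " negative)",
        if (nbad) paste0(", ", nbad, " unparseable") else "", "\n", sep = "")
})

#' @rdname FingerprintMatrix-class
#' @param object,x a FingerprintMatrix
#' @export
setMethod("dim", "FingerprintMatrix", function(x) dim(x@bits))

#' @rdname FingerprintMatrix-class
#' @export
setMethod("show", "FingerprintMatrix", function(object) {
    cat("FingerprintMatrix: ", nrow(object@bits), " molecules x ",
        ncol(object@bits), " bits; ", length(object@excluded),
        " record(s) excluded\n", sep = "")
})

#' Bit matrix of a FingerprintMatrix
#' @param x a FingerprintMatrix
#' @return the integer 0/1 matrix, rownames = record ids
#' @export
fpBits <- function(x) {
    stopifnot(is(x, "FingerprintMatrix"))
    m <- x@bits
    rownames(m) <- x@recordIds
    m
}

#' @rdname PLSLinearModel-class
#' @export
setMethod("scalingStats", "PLSLinearModel", function(object) object@scaling)

#' @rdname PLSLinearModel-class
#' @export
setMethod("decisionThreshold", "PLSLinearModel",
          function(object) object@threshold)

#' @rdname PLSLinearModel-class
#' @export
setMethod("modelConfigOf", "PLSLinearModel", function(object) object@config)

#' @rdname PLSLinearModel-class
#' @export
setMethod("trainingSize", "PLSLinearModel",
          function(object) object@trainingSize)

#' @rdname PLSLinearModel-class
#' @export
setMethod("lockState", "LocalModel", function(object) "open")

#' @rdname PLSLinearModel-class
#' @export
setMethod("lockState", "ConfidentialModel", function(object) "closed")

#' @rdname PLSLinearModel-class
#' @param ... ignored
#' @export
setMethod("coef", "PLSLinearModel", function(object, ...) {
    cf <- object@coefficients
    names(cf) <- object@scaling$bit_index
    cf
})

.showLinearModel <- function(object, kind, extra) {
    cat(kind, " (", lockState(object), " lock): ",
        nrow(object@scaling), " features, ", object@nLatent,
        " latent variable(s), threshold ", format(object@threshold),
        ", trained on ", object@trainingSize, " compounds", extra,
        "\n", sep = "")
}

#' @rdname PLSLinearModel-class
#' @export
setMethod("show", "LocalModel", function(object)
    .showLinearModel(object, "LocalModel",
                     paste0(" [series: ", object@provenance, "]")))

#' @rdname PLSLinearModel-class
#' @export
setMethod("show", "ConfidentialModel", function(object)
    .showLinearModel(object, "ConfidentialModel",
                     paste0(" [origin: ", object@originLabel, "]")))

#' @rdname EnsembleModel-class
#' @export
setMethod("members", "EnsembleModel", function(object) object@members)

#' @rdname EnsembleModel-class
#' @export
setMethod("combinationRule", "EnsembleModel", function(object) object@rule)

#' @rdname EnsembleModel-class
#' @export
setMethod("show", "EnsembleModel", function(object) {
    cat("EnsembleModel: rule ", object@rule,
        if (object@rule == "METAMODEL")
            paste0(" (", object@combinerAlgorithm, ")") else "",
        ", ", length(object@members), " members: ",
        paste(names(object@members), collapse = ", "), "\n", sep = "")
})
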