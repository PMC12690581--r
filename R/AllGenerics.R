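#' @rdname AnnotatedSeries-class
#' @param object,x an object
#' @export
setGeneric("seriesName", function(object) standardGeneric("seriesName"))

#' @rdname AnnotatedSeries-class
#' @export
setGeneric("molecules", function(object) standardGeneric("molecules"))

#' @rdname AnnotatedSeries-class
#' @export
setGeneric("seriesLabels", function(object) standardGeneric("seriesLabels"))

#' @rdname PLSLinearModel-class
#' @param object a model
#' @export
setGeneric("scalingStats", function(object) standardGeneric("scalingStats"))

#' @rdname PLSLinearModel-class
#' @export
setGeneric("decisionThreshold",
           function(object) standardGeneric("decisionThreshold"))

#' @rdname PLSLinearModel-class
#' @export
setGeneric("lockState", function(object) standardGeneric("lockState"))

#' @rdname PLSLinearModel-class
#' @export
setGeneric("modelConfigOf", function(object) standardGeneric("modelConfigOf"))

#' @rdname PLSLinearModel-class
#' @export
setGeneric("trainingSize", function(object) standardGeneric("trainingSize"))

#' @rdname EnsembleModel-class
#' @param object an ensemble
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname EnsembleModel-class
#' @export
setGeneric("combinationRule",
           function(object) standardGeneric("combinationRule"))
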