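#' @rdname InhibitionMatrix-class
#' @param object,x an object.
#' @export
setGeneric("residualActivity", function(x) standardGeneric("residualActivity"))

#' @rdname InhibitionMatrix-class
#' @export
setGeneric("assayConcentration",
           function(x) standardGeneric("assayConcentration"))

#' @rdname InhibitionMatrix-class
#' @export
setGeneric("inhibitorIds", function(x) standardGeneric("inhibitorIds"))

#' @rdname InhibitionMatrix-class
#' @export
setGeneric("kinaseIds", function(x) standardGeneric("kinaseIds"))

#' @rdname ProliferationScreen-class
#' @export
setGeneric("nucleiCounts", function(x) standardGeneric("nucleiCounts"))

#' @rdname ProliferationScreen-class
#' @export
setGeneric("deadCounts", function(x) standardGeneric("deadCounts"))

#' @rdname ProliferationScreen-class
#' @export
setGeneric("timesHours", function(x) standardGeneric("timesHours"))

#' @rdname ProliferationScreen-class
#' @export
setGeneric("plateMap", function(x) standardGeneric("plateMap"))

#' @rdname estimateRates
#' @export
setGeneric("estimateRates",
  function(x, window = NULL, convention = c("mean", "sum"), ...)
    standardGeneric("estimateRates"))

#' @rdname instantaneousRates
#' @export
setGeneric("instantaneousRates",
  function(x, smooth_hours = 10, ...) standardGeneric("instantaneousRates"))
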