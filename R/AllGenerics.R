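#' @rdname DEResult-class
#' @param object,x an object.
#' @param ... further arguments.
#' @export
setGeneric("deTable", function(object, ...) standardGeneric("deTable"))

#' @rdname DEResult-class
#' @export
setGeneric("degStatus", function(object, ...) standardGeneric("degStatus"))

#' @rdname DEResult-class
#' @export
setGeneric("degSet", function(object, ...) standardGeneric("degSet"))

#' @rdname SetReport-class
#' @export
setGeneric("setCounts", function(object, ...) standardGeneric("setCounts"))

#' @rdname SetReport-class
#' @export
setGeneric("setPercentages",
           function(object, ...) standardGeneric("setPercentages"))

#' @rdname ProteomeCollection-class
#' @export
setGeneric("organisms", function(object, ...) standardGeneric("organisms"))

#' @rdname ProteomeCollection-class
#' @export
setGeneric("cladeOf", function(object, ...) standardGeneric("cladeOf"))

#' @rdname ConservationProfile-class
#' @export
setGeneric("conservationScores",
           function(object, ...) standardGeneric("conservationScores"))

#' @rdname ConservationProfile-class
#' @export
setGeneric("selfBits", function(object, ...) standardGeneric("selfBits"))
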