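#' @import methods
NULL

#' @export
setGeneric("dosage", function(x, ...) standardGeneric("dosage"))

#' @export
setGeneric("ancestry", function(x, ...) standardGeneric("ancestry"))

#' @export
setGeneric("markerInfo", function(x, ...) standardGeneric("markerInfo"))

#' @export
setGeneric("cohort", function(x, ...) standardGeneric("cohort"))

#' @export
setGeneric("scanStats", function(x, ...) standardGeneric("scanStats"))

#' @export
setGeneric("meff", function(x, ...) standardGeneric("meff"))

#' @export
setGeneric("sigThreshold", function(x, ...) standardGeneric("sigThreshold"))

#' @export
setGeneric("mediation", function(x, ...) standardGeneric("mediation"))

#' @export
setGeneric("globalAncestry", function(x, ...) standardGeneric("globalAncestry"))

#' @export
setGeneric("switchPoints", function(x, ...) standardGeneric("switchPoints"))
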