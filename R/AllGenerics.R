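#' @rdname ItemPanel-class
#' @param object,x an object.
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))

#' @rdname ItemPanel-class
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))

#' @rdname ItemPanel-class
#' @export
setGeneric("nItems", function(object) standardGeneric("nItems"))

#' @rdname ItemPanel-class
#' @export
setGeneric("nOccasions", function(object) standardGeneric("nOccasions"))

#' @rdname ItemPanel-class
#' @export
setGeneric("occasionCounts", function(object) standardGeneric("occasionCounts"))

#' @rdname ModelSpec-class
#' @export
setGeneric("freeParameters", function(object) standardGeneric("freeParameters"))

#' @rdname SemFit-class
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' Model degrees of freedom
#' @param object a [ModelSpec-class] or [SemFit-class].
#' @export
setGeneric("dfModel", function(object) standardGeneric("dfModel"))

#' @rdname StatMap-class
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
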