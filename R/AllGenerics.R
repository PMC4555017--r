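#' @rdname ModuleSession-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname ModuleSession-accessors
#' @export
setGeneric("sampleIndex", function(x) standardGeneric("sampleIndex"))

#' @rdname ModuleSession-accessors
#' @export
setGeneric("chipLive", function(x) standardGeneric("chipLive"))

#' @rdname ModuleSession-accessors
#' @export
setGeneric("neuralData", function(x) standardGeneric("neuralData"))

#' @rdname ModuleSession-accessors
#' @export
setGeneric("auxData", function(x) standardGeneric("auxData"))

#' @rdname ModuleSession-accessors
#' @export
setGeneric("experimentId", function(x) standardGeneric("experimentId"))

#' @rdname ModuleSession-accessors
#' @export
setGeneric("moduleId", function(x) standardGeneric("moduleId"))

#' @rdname ModuleSession-accessors
#' @export
setGeneric("layoutOf", function(x) standardGeneric("layoutOf"))

#' @rdname ValidationReport-accessors
#' @export
setGeneric("passed", function(x) standardGeneric("passed"))

#' @rdname ValidationReport-accessors
#' @export
setGeneric("validationErrors", function(x) standardGeneric("validationErrors"))
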