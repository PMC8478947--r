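#' @rdname encode
#' @export
setGeneric("encode", function(model, data, ...) standardGeneric("encode"))

#' @rdname decode
#' @export
setGeneric("decode", function(model, Z, ...) standardGeneric("decode"))

#' @rdname gmvActivities
#' @export
setGeneric("gmvActivities", function(model, data, ...)
    standardGeneric("gmvActivities"))

#' @rdname reconstructExpression
#' @export
setGeneric("reconstructExpression", function(model, data, ...)
    standardGeneric("reconstructExpression"))

#' @rdname moduleNames
#' @export
setGeneric("moduleNames", function(x) standardGeneric("moduleNames"))

#' @rdname moduleSizes
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname latentNames
#' @export
setGeneric("latentNames", function(x) standardGeneric("latentNames"))

#' @rdname nodeKinds
#' @export
setGeneric("nodeKinds", function(x) standardGeneric("nodeKinds"))
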