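#' @name mrchain-accessors
#' @title Accessor generics
#' @description Accessors for the core classes; always prefer these over
#'   direct slot access.
#' @param x,object an mrchain object.
#' @param ... passed to methods.
NULL

#' @rdname mrchain-accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname mrchain-accessors
#' @export
setGeneric("traitLabel", function(x) standardGeneric("traitLabel"))

#' @rdname mrchain-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname mrchain-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname mrchain-accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname mrchain-accessors
#' @export
setGeneric("betaExp", function(x) standardGeneric("betaExp"))

#' @rdname mrchain-accessors
#' @export
setGeneric("seExp", function(x) standardGeneric("seExp"))

#' @rdname mrchain-accessors
#' @export
setGeneric("betaOut", function(x) standardGeneric("betaOut"))

#' @rdname mrchain-accessors
#' @export
setGeneric("seOut", function(x) standardGeneric("seOut"))

#' @rdname mrchain-accessors
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))

#' @rdname mrchain-accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))

#' @rdname mrchain-accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' @rdname mrchain-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname mrchain-accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname mrchain-accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname mrchain-accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname mrchain-accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname mrchain-accessors
#' @export
setGeneric("mrExtra", function(x) standardGeneric("mrExtra"))

#' @rdname mrchain-accessors
#' @export
setGeneric("outlierIndices", function(x) standardGeneric("outlierIndices"))

#' @rdname mrchain-accessors
#' @export
setGeneric("mediatedProportion", function(x) standardGeneric("mediatedProportion"))
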