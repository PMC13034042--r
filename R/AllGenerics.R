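#' @rdname intensities
#' @export
setGeneric("intensities", function(x, ...) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setGeneric("normIntensities",
           function(x, ...) standardGeneric("normIntensities"))

#' @rdname intensities
#' @export
setGeneric("imputedMask", function(x, ...) standardGeneric("imputedMask"))

#' @rdname runMeta
#' @export
setGeneric("runMeta", function(x, ...) standardGeneric("runMeta"))

#' @rdname filterProteins
#' @export
setGeneric("filterProteins", function(x, ...) standardGeneric("filterProteins"))

#' @rdname medianNormalize
#' @export
setGeneric("medianNormalize",
           function(x, ...) standardGeneric("medianNormalize"))

#' @rdname imputeMissing
#' @export
setGeneric("imputeMissing", function(x, ...) standardGeneric("imputeMissing"))

#' @rdname normalizeProfiles
#' @export
setGeneric("normalizeProfiles",
           function(x, ...) standardGeneric("normalizeProfiles"))
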