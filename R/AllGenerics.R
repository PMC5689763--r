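#' @rdname SectionImage-class
#' @param object an object.
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))

#' @rdname SectionImage-class
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname SectionImage-class
#' @export
setGeneric("depthUm", function(object) standardGeneric("depthUm"))

#' @rdname SectionImage-class
#' @export
setGeneric("slideId", function(object) standardGeneric("slideId"))

#' @rdname SectionImage-class
#' @export
setGeneric("stainKind", function(object) standardGeneric("stainKind"))

#' @rdname StainVectors-class
#' @export
setGeneric("stainMatrix", function(object) standardGeneric("stainMatrix"))

#' @rdname StainVectors-class
#' @export
setGeneric("stainNames", function(object) standardGeneric("stainNames"))

#' @rdname ODImage-class
#' @export
setGeneric("odArray", function(object) standardGeneric("odArray"))

#' @rdname BinaryMask-class
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname BinaryMask-class
#' @export
setGeneric("maskLabel", function(object) standardGeneric("maskLabel"))
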