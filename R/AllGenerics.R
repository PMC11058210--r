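#' @include AllClasses.R
NULL

#' Accessors for occlumap classes
#'
#' Small accessor generics so slots are never touched directly:
#' \code{vertices}/\code{faces}/\code{vertexNormals} for meshes,
#' \code{pixels} for depth maps and images, \code{maskMatrix} for masks,
#' \code{calibration} for the mm-per-intensity factor.
#'
#' @param x an occlumap object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("vertexNormals", function(x) standardGeneric("vertexNormals"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' Generator contract generics
#'
#' \code{generateImage} evaluates a generator on an nRes x 512 latent
#' matrix; \code{generatorGradient} returns the latent-shaped
#' vector-Jacobian product for an image-shaped upstream sensitivity;
#' \code{latentMean} returns the generator's latent prior mean;
#' \code{outputWidth} the output resolution.
#'
#' @param G a \linkS4class{ToothGenerator}.
#' @param w latent matrix, nRes x 512.
#' @param sensitivity image-sized matrix of upstream derivatives.
#' @name generator-contract
NULL

#' @rdname generator-contract
#' @export
setGeneric("generateImage", function(G, w) standardGeneric("generateImage"))
#' @rdname generator-contract
#' @export
setGeneric("generatorGradient", function(G, w, sensitivity)
    standardGeneric("generatorGradient"))
#' @rdname generator-contract
#' @export
setGeneric("latentMean", function(G) standardGeneric("latentMean"))
#' @rdname generator-contract
#' @export
setGeneric("outputWidth", function(G) standardGeneric("outputWidth"))
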