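#' @import methods
NULL

#' ToothMesh: a triangle mesh of a single molar crown (mm units)
#'
#' Vertices are stored in millimetres; faces are 1-based vertex index
#' triples with outward-consistent winding. Per-vertex normals are
#' area-weighted averages of incident face normals. The \code{metadata}
#' list carries optional annotations: \code{buccal} (3-vector, the
#' cheek-facing direction carried along under rigid transforms),
#' \code{params} (the generating shape parameters for synthetic teeth)
#' and \code{heightfield} (the analytic occlusal heightfield function of
#' a synthetic tooth, defined in its intrinsic frame).
#'
#' @slot vertices n x 3 numeric matrix, mm.
#' @slot faces m x 3 integer matrix of vertex indices.
#' @slot normals n x 3 numeric matrix of unit vertex normals.
#' @slot metadata list of optional annotations.
#' @export
setClass("ToothMesh", representation(
    vertices = "matrix", faces = "matrix", normals = "matrix",
    metadata = "list"))

setValidity("ToothMesh", function(object) {
    v <- object@vertices; f <- object@faces
    if (!is.numeric(v) || ncol(v) != 3L) return("vertices must be n x 3 numeric")
    if (ncol(f) != 3L) return("faces must be m x 3")
    if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
        return("face indices out of range")
    if (nrow(object@normals) > 0 && ncol(object@normals) != 3L)
        return("normals must be n x 3")
    TRUE
})

#' OrientedPointCloud: surface samples with unit normals
#'
#' @slot points n x 3 numeric matrix, mm.
#' @slot normals n x 3 numeric matrix of unit normals.
#' @export
setClass("OrientedPointCloud", representation(
    points = "matrix", normals = "matrix"))

setValidity("OrientedPointCloud", function(object) {
    p <- object@points; n <- object@normals
    if (ncol(p) != 3L || ncol(n) != 3L) return("points/normals must be n x 3")
    if (nrow(p) != nrow(n)) return("points and normals disagree in length")
    if (nrow(n) > 0) {
        len <- sqrt(rowSums(n^2))
        if (max(abs(len - 1)) > 1e-5) return("normals must be unit length")
    }
    TRUE
})

#' ProjectionConfig: calibration of the occlusal depth-map projection
#'
#' The projection plane is quadratic with side \code{planeSize} mm and the
#' resolution must be a power of two (the generator's resolution schedule
#' requires it). \code{zNorm} is the global depth window: the highest
#' surface point maps to intensity 255 and anything more than \code{zNorm}
#' below it falls out of the map. One intensity unit corresponds to
#' \code{zNorm/255} mm.
#'
#' @slot resolution image width = height in pixels.
#' @slot planeSize side of the projection plane, mm.
#' @slot zNorm depth window, mm.
#' @slot nSample point-cloud size used when projecting meshes.
#' @slot contourOffset margin kept between tooth contour and image border, mm.
#' @export
setClass("ProjectionConfig", representation(
    resolution = "integer", planeSize = "numeric", zNorm = "numeric",
    nSample = "numeric", contourOffset = "numeric"))

setValidity("ProjectionConfig", function(object) {
    w <- object@resolution
    if (length(w) != 1L || w < 2L) return("resolution must be a single integer >= 2")
    if (abs(log2(w) - round(log2(w))) > 1e-9)
        return("resolution must be a power of two")
    if (object@zNorm <= 0) return("zNorm must be positive")
    if (object@planeSize <= 0) return("planeSize must be positive")
    TRUE
})

#' DepthMap: calibrated 8-bit occlusal heightfield
#'
#' Pixel values live in [0, 255]; the background is exactly 0 and every
#' tooth pixel is positive. Values are held as continuous numbers and only
#' quantized to 8 bits on export, avoiding double-quantization bias.
#' Row 1 is the top of the image; the buccal side sits in the bottom half
#' after canonicalization.
#'
#' @slot pixels h x w numeric matrix in [0, 255].
#' @slot config the \linkS4class{ProjectionConfig} used.
#' @slot provenance free-form tag describing how the map was produced.
#' @export
setClass("DepthMap", representation(
    pixels = "matrix", config = "ProjectionConfig", provenance = "character"))

setValidity("DepthMap", function(object) {
    p <- object@pixels
    if (nrow(p) != ncol(p)) return("depth maps are square")
    if (nrow(p) != object@config@resolution)
        return("pixel matrix does not match config resolution")
    if (any(!is.finite(p))) return("non-finite pixel values")
    if (min(p) < 0 || max(p) > 255) return("pixel values must lie in [0,255]")
    TRUE
})

#' BinaryMask: keep/remove map for the corruption operator
#'
#' Value 1 marks retained pixels (white), 0 the removed preparation area
#' (black). Serialized to PNG as {0, 255}.
#'
#' @slot mask h x w matrix in {0,1}.
#' @slot source one of "extracted", "ground_truth", "manual", "synthetic".
#' @export
setClass("BinaryMask", representation(mask = "matrix", source = "character"))

setValidity("BinaryMask", function(object) {
    m <- object@mask
    if (!all(m %in% c(0, 1))) return("mask values must be 0 or 1")
    TRUE
})

#' BoundaryMask: ring of retained pixels hugging the preparation edge
#'
#' Selects the retained (mask = 1) pixels within \code{ringWidth} of the
#' removed region under 8-connectivity; the boundary loss is evaluated on
#' exactly these pixels.
#'
#' @slot mask h x w matrix in {0,1}; 1 marks ring pixels.
#' @slot ringWidth ring width in pixels.
#' @export
setClass("BoundaryMask", representation(mask = "matrix", ringWidth = "integer"))

#' ToothGenerator: contract for latent-to-image generators
#'
#' Virtual class. A conforming generator maps an nRes x 512 latent matrix
#' deterministically to a real-valued image in [0, 255] and exposes an
#' analytic adjoint (vector-Jacobian product) for optimization. nRes is
#' tied to the output width by nRes = 2 (log2(width) - 1).
#'
#' @export
setClass("ToothGenerator", representation("VIRTUAL"))

#' LinearToothGenerator: desk-scale PCA generator of occlusal depth maps
#'
#' image = clip(meanImage + B %*% fold(w), 0, 255), where fold averages the
#' nRes latent rows into one 512-vector and keeps its first \code{rank}
#' entries, and the columns of B are singular-value-scaled principal
#' components of the training depth maps (so latents are O(1)). It is the
#' in-package stand-in for a trained style-based generator; external
#' generators plug in through the same contract.
#'
#' @slot meanImage h x w matrix.
#' @slot components (h*w) x rank matrix of scaled principal components.
#' @slot width output resolution.
#' @slot rank number of latent entries actually used.
#' @slot latentMean nRes x 512 matrix (zero for this generator).
#' @export
setClass("LinearToothGenerator", contains = "ToothGenerator", representation(
    meanImage = "matrix", components = "matrix", width = "integer",
    rank = "integer", latentMean = "matrix"))

#' ReconstructionResult: outcome of a latent-inversion run
#'
#' @slot w optimized latent matrix (best restart).
#' @slot xClean generated clean image G(w*).
#' @slot xCor corrupted input image.
#' @slot xMerge merged image: corrupted input outside the mask, generated
#'   fill inside it.
#' @slot traces list of per-restart loss traces.
#' @slot finalLosses final loss per restart.
#' @slot chosenRestart index of the restart with minimal final loss.
#' @slot nDr step index of the point of diminishing returns for the chosen
#'   restart.
#' @export
setClass("ReconstructionResult", representation(
    w = "matrix", xClean = "matrix", xCor = "matrix", xMerge = "matrix",
    traces = "list", finalLosses = "numeric", chosenRestart = "integer",
    nDr = "integer"))
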