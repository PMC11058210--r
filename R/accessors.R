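#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("vertices", "ToothMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("faces", "ToothMesh", function(x) x@faces)
#' @rdname accessors
setMethod("vertexNormals", "ToothMesh", function(x) x@normals)
#' @rdname accessors
setMethod("pixels", "DepthMap", function(x) x@pixels)
#' @rdname accessors
setMethod("maskMatrix", "BinaryMask", function(x) x@mask)
#' @rdname accessors
setMethod("maskMatrix", "BoundaryMask", function(x) x@mask)

#' @rdname accessors
setMethod("calibration", "ProjectionConfig", function(x) x@zNorm / 255)
#' @rdname accessors
setMethod("calibration", "DepthMap", function(x) calibration(x@config))

setMethod("show", "ToothMesh", function(object) {
    v <- object@vertices
    ext <- if (nrow(v)) apply(v, 2L, function(z) diff(range(z))) else c(0, 0, 0)
    cat(sprintf("ToothMesh: %d vertices, %d faces\n",
                nrow(v), nrow(object@faces)))
    cat(sprintf("  extent (mm): %.2f x %.2f x %.2f\n", ext[1L], ext[2L], ext[3L]))
    if (!is.null(object@metadata$buccal))
        cat(sprintf("  buccal direction: [%s]\n",
                    paste(sprintf("%.2f", object@metadata$buccal), collapse = ", ")))
})

setMethod("show", "OrientedPointCloud", function(object) {
    cat(sprintf("OrientedPointCloud: %d points with unit normals\n",
                nrow(object@points)))
})

setMethod("show", "DepthMap", function(object) {
    p <- object@pixels
    cat(sprintf("DepthMap: %dx%d, zNorm = %.3g mm (%.4g mm per intensity unit)\n",
                nrow(p), ncol(p), object@config@zNorm, calibration(object)))
    cat(sprintf("  foreground: %d px (%.1f%%), max intensity %.1f\n",
                sum(p > 0), 100 * mean(p > 0), max(p)))
    cat(sprintf("  provenance: %s\n", object@provenance))
})

setMethod("show", "BinaryMask", function(object) {
    m <- object@mask
    cat(sprintf("BinaryMask [%s]: %dx%d, removed (0) pixels: %d\n",
                object@source, nrow(m), ncol(m), sum(m == 0)))
})

setMethod("show", "BoundaryMask", function(object) {
    cat(sprintf("BoundaryMask: ring width %d px, %d ring pixels\n",
                object@ringWidth, sum(object@mask == 1)))
})

setMethod("show", "LinearToothGenerator", function(object) {
    cat(sprintf("LinearToothGenerator: %dx%d output, rank %d, nRes %d\n",
                object@width, object@width, object@rank, nrow(object@latentMean)))
})

setMethod("show", "ReconstructionResult", function(object) {
    cat(sprintf("ReconstructionResult: %d restart(s), chosen #%d\n",
                length(object@finalLosses), object@chosenRestart))
    cat(sprintf("  final loss %.6g after %d steps; diminishing returns at step %d\n",
                object@finalLosses[object@chosenRestart],
                length(object@traces[[object@chosenRestart]]), object@nDr))
})
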