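#' @include AllClasses.R
NULL

#' Mask-extraction thresholds
#'
#' The preparation area is removed from the point cloud by a two-part
#' heuristic: cavity walls are far steeper than the occlusal surface, so
#' their normals fail the normal-z threshold, and the cavity floor sits
#' below the height threshold. Both are empirical per-preparation values;
#' defaults suit the synthetic fixtures.
#'
#' @param nzT normal-z threshold in (0, 1), default 0.9.
#' @param zT height threshold in the z-normalized frame, mm.
#' @export
maskThresholds <- function(nzT = 0.9, zT = 0) {
    stopifnot(nzT > 0, nzT < 1)
    list(nzT = nzT, zT = zT)
}

#' Retain occlusal points of a prepared tooth
#'
#' Keeps exactly the points with normal z-component above \code{nzT} and
#' height above \code{zT}: the occlusal remainder. Cavity walls (steep)
#' and floor (low) drop out.
#'
#' @param cloud normalized, z-normalized \linkS4class{OrientedPointCloud}.
#' @param th thresholds from \code{\link{maskThresholds}}.
#' @export
extractRetainedPoints <- function(cloud, th) {
    keep <- cloud@normals[, 3L] > th$nzT & cloud@points[, 3L] > th$zT
    if (!any(keep))
        stop("no points retained; thresholds remove the whole surface")
    new("OrientedPointCloud", points = cloud@points[keep, , drop = FALSE],
        normals = cloud@normals[keep, , drop = FALSE])
}

#' Binarize a depth map
#'
#' Every nonzero pixel maps to 1 (retained/white), zero stays 0.
#'
#' @param dmap \linkS4class{DepthMap}.
#' @return raw \linkS4class{BinaryMask}.
#' @export
binarizeDepthMap <- function(dmap) {
    new("BinaryMask", mask = (dmap@pixels != 0) * 1, source = "extracted")
}

## connected components of a logical matrix (8-connectivity via EBImage)
labelComponents <- function(lgl) {
    asPlainMatrix(EBImage::bwlabel(matrix(as.numeric(lgl), nrow(lgl),
                                          ncol(lgl))))
}

asPlainMatrix <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

#' Finalize a raw preparation mask
#'
#' Automates the gap-filling that raw projected masks need: the
#' background outside the tooth silhouette is whitened, the removed
#' (black) region is morphologically closed so pinhole artifacts inside
#' it vanish, isolated black speckles below \code{minComponent} pixels in
#' the retained region are dropped, and small white holes fully inside
#' the black region are filled. Artifacts never touch the preparation
#' edge, so none of these steps moves the mask boundary. Idempotent.
#'
#' @param raw raw \linkS4class{BinaryMask} from
#'   \code{\link{binarizeDepthMap}}.
#' @param foreground logical matrix of tooth silhouette pixels (from the
#'   prepared tooth's depth map); if NULL, the black region touching the
#'   image border is treated as background.
#' @param minComponent speckle/hole size threshold, px.
#' @param closeRadius closing radius applied to the black region, px.
#' @return enclosed \linkS4class{BinaryMask} with white background.
#' @export
finalizeMask <- function(raw, foreground = NULL, minComponent = 10L,
                         closeRadius = 1L) {
    m <- raw@mask
    if (is.null(foreground)) {
        lab <- labelComponents(m == 0)
        border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                           lab[, ncol(lab)]))
        border <- border[border > 0]
        black <- lab > 0 & !(lab %in% border)
    } else {
        black <- m == 0 & foreground
    }
    if (all(black))
        stop("preparation region fills the whole image")
    ## thin black arcs hugging the outer contour are sampling artifacts
    ## (silhouette-tangent pixels hold almost no occlusal area): whiten
    ## black components that never reach deeper than 2 px into the tooth.
    ## Real contour-opening cavities extend far inward and are kept.
    if (!is.null(foreground)) {
        dbg <- asPlainMatrix(EBImage::distmap(matrix(as.numeric(foreground),
                                                     nrow(foreground))))
        lab <- labelComponents(black)
        if (max(lab) > 0) {
            depth <- vapply(seq_len(max(lab)), function(k)
                max(dbg[lab == k]), numeric(1L))
            black[black][depth[lab[lab > 0]] <= 2] <- FALSE
        }
    }
    ## drop isolated black speckles
    lab <- labelComponents(black)
    if (max(lab) > 0) {
        sizes <- tabulate(lab[lab > 0])
        black[black][sizes[lab[lab > 0]] < minComponent] <- FALSE
    }
    ## gentle closing of the removed region: fills the single-pixel white
    ## notches that partial occlusal slivers leave along the preparation
    ## edge; at radius 1 a straight boundary is preserved and the edge
    ## moves by at most one pixel toward the touched-by-removal bracket
    if (closeRadius > 0) {
        kern <- EBImage::makeBrush(2L * closeRadius + 1L, shape = "box")
        black <- asPlainMatrix(EBImage::closing(
            matrix(as.numeric(black), nrow(black)), kern)) > 0.5
        if (!is.null(foreground)) black <- black & foreground
    }
    ## fill small enclosed white holes
    lab <- labelComponents(!black)
    if (max(lab) > 0) {
        border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                           lab[, ncol(lab)]))
        sizes <- tabulate(lab[lab > 0])
        hole <- lab > 0 & !(lab %in% border) & sizes[pmax(lab, 1L)] < minComponent
        black[hole] <- TRUE
    }
    new("BinaryMask", mask = 1 - black * 1, source = raw@source)
}

#' Boundary ring of a binary mask
#'
#' Selects the retained (mask = 1) pixels within \code{ringWidth} of the
#' removed region under 8-connectivity; the boundary loss is evaluated on
#' these pixels to pin the restoration to the preparation edge. Contact
#' with plain background (outside the tooth) is excluded when a
#' foreground silhouette is supplied.
#'
#' @param M \linkS4class{BinaryMask} with nonempty black region.
#' @param ringWidth ring width in pixels (default 1).
#' @param foreground optional logical tooth-silhouette matrix.
#' @return a \linkS4class{BoundaryMask}.
#' @export
boundaryMask <- function(M, ringWidth = 1L, foreground = NULL) {
    m <- M@mask
    black <- m == 0
    if (!is.null(foreground)) black <- black & foreground
    if (!any(black)) stop("mask has no removed region")
    kern <- EBImage::makeBrush(2L * ringWidth + 1L, shape = "box")
    dil <- asPlainMatrix(EBImage::dilate(matrix(as.numeric(black), nrow(m)),
                                         kern)) > 0.5
    ring <- dil & m == 1
    if (!is.null(foreground)) ring <- ring & foreground
    new("BoundaryMask", mask = ring * 1, ringWidth = as.integer(ringWidth))
}

#' Extract the preparation mask from a prepared tooth mesh
#'
#' Full mask pipeline on a common pixel grid: the prepared tooth is
#' projected once (providing the silhouette and the posed cloud), the
#' retained occlusal points are selected by the normal/height heuristic
#' and projected onto the same grid, binarized, and finalized into the
#' enclosed preparation mask.
#'
#' @param mesh orientation-normalized prepared \linkS4class{ToothMesh}.
#' @param config \linkS4class{ProjectionConfig}.
#' @param th \code{\link{maskThresholds}}; \code{zT} is interpreted in
#'   the z-normalized frame of the projection.
#' @param seed sampling seed (shared with the depth-map projection).
#' @param override optional \linkS4class{BinaryMask} honored verbatim in
#'   place of the automatic finalization.
#' @param sampleFactor oversampling factor of the mask pass relative to
#'   \code{config@nSample}. Binarization flags every empty pixel as
#'   removed, so the mask pass needs the per-pixel sample density of the
#'   full-scale configuration (about 50 per foreground pixel) even when
#'   depth maps are drawn at desk-scale density; the default restores it.
#' @return list: \code{mask} (\linkS4class{BinaryMask}), \code{map}
#'   (the prepared tooth's \linkS4class{DepthMap}), \code{boundary}
#'   (\linkS4class{BoundaryMask}, ring width 1).
#' @export
extractPreparationMask <- function(mesh, config, th = maskThresholds(),
                                   seed = 0L, override = NULL,
                                   sampleFactor = 8) {
    pr <- projectTooth(mesh, config, seed = seed, returnCloud = TRUE,
                       normalMode = "face")
    if (!is.null(override)) {
        fg <- pr$map@pixels > 0
        return(list(mask = override, map = pr$map,
                    boundary = boundaryMask(override, 1L, foreground = fg)))
    }
    dense <- sampleSurface(mesh, ceiling(sampleFactor * config@nSample),
                           seed = seed + 1L, normalMode = "face")
    dense <- normalizeZ(dense, config@zNorm)
    aa <- -pr$pose$angleDeg * pi / 180
    Rot <- matrix(c(cos(aa), sin(aa), -sin(aa), cos(aa)), 2L, 2L)
    xy <- sweep(dense@points[, 1:2], 2L, pr$pose$center) %*% t(Rot)
    dense <- new("OrientedPointCloud",
                 points = cbind(xy, dense@points[, 3L]),
                 normals = cbind(dense@normals[, 1:2] %*% t(Rot),
                                 dense@normals[, 3L]))
    kept <- extractRetainedPoints(dense, th)
    rawMap <- projectDepth(kept, config, center = c(0, 0),
                           provenance = "retained-points")
    raw <- binarizeDepthMap(rawMap)
    fg <- pr$map@pixels > 0
    mask <- finalizeMask(raw, foreground = fg)
    boundary <- if (any(mask@mask == 0))
        boundaryMask(mask, 1L, foreground = fg) else NULL
    list(mask = mask, map = pr$map, boundary = boundary)
}

#' Interior circle mask of a given relative area
#'
#' A filled circle centered on the tooth's largest-inscribed-circle
#' center, sized so the removed pixels equal \code{areaFraction} of the
#' tooth's nonzero pixels (exact to one pixel), and constrained to stay
#' strictly inside the outer contour.
#'
#' @param dmap \linkS4class{DepthMap} of the (unprepared) tooth.
#' @param areaFraction target removed fraction in (0, max feasible].
#' @return \linkS4class{BinaryMask} (source "synthetic").
#' @export
circleMask <- function(dmap, areaFraction) {
    fg <- dmap@pixels > 0
    if (!any(fg)) stop("empty tooth")
    if (areaFraction <= 0)
        return(new("BinaryMask", mask = matrix(1, nrow(fg), ncol(fg)),
                   source = "synthetic"))
    dm <- asPlainMatrix(EBImage::distmap(matrix(as.numeric(fg), nrow(fg))))
    ctr <- which(dm == max(dm), arr.ind = TRUE)[1L, ]
    rmax <- max(dm)
    nfg <- sum(fg)
    k <- round(areaFraction * nfg)
    rows <- matrix(rep(seq_len(nrow(fg)), ncol(fg)), nrow(fg))
    cols <- matrix(rep(seq_len(ncol(fg)), each = nrow(fg)), nrow(fg))
    d <- sqrt((rows - ctr[1L])^2 + (cols - ctr[2L])^2)
    dv <- sort(d[fg])
    if (k > length(dv)) stop("infeasible area fraction")
    r <- dv[k]
    if (r >= rmax - 1)
        stop(sprintf("area fraction %.2f infeasible: circle would touch the contour (max ~%.2f)",
                     areaFraction, mean(dv < rmax - 1)))
    m <- matrix(1, nrow(fg), ncol(fg))
    m[fg & d <= r] <- 0
    new("BinaryMask", mask = m, source = "synthetic")
}

#' Contour-cutting mask of a given relative area
#'
#' Removes the same number of tooth pixels as \code{\link{circleMask}}
#' at the same fraction, but centered on the outer contour of the
#' requested side, so the black region intersects the tooth's silhouette
#' boundary — the configuration under which reconstruction loses the
#' contour information.
#'
#' @param dmap \linkS4class{DepthMap} of the tooth.
#' @param areaFraction target removed fraction.
#' @param side which contour to cut: "top", "bottom", "left" or "right".
#' @return \linkS4class{BinaryMask} (source "synthetic").
#' @export
boundaryCutMask <- function(dmap, areaFraction,
                            side = c("top", "bottom", "left", "right")) {
    side <- match.arg(side)
    fg <- dmap@pixels > 0
    if (!any(fg)) stop("empty tooth")
    nfg <- sum(fg)
    k <- round(areaFraction * nfg)
    if (k < 1 || k > nfg) stop("infeasible area fraction")
    idx <- which(fg, arr.ind = TRUE)
    ctr <- switch(side,
        top = idx[order(idx[, 1L], abs(idx[, 2L] - mean(idx[, 2L])))[1L], ],
        bottom = idx[order(-idx[, 1L], abs(idx[, 2L] - mean(idx[, 2L])))[1L], ],
        left = idx[order(idx[, 2L], abs(idx[, 1L] - mean(idx[, 1L])))[1L], ],
        right = idx[order(-idx[, 2L], abs(idx[, 1L] - mean(idx[, 1L])))[1L], ])
    rows <- matrix(rep(seq_len(nrow(fg)), ncol(fg)), nrow(fg))
    cols <- matrix(rep(seq_len(ncol(fg)), each = nrow(fg)), nrow(fg))
    d <- sqrt((rows - ctr[1L])^2 + (cols - ctr[2L])^2)
    dv <- sort(d[fg])
    r <- dv[k]
    m <- matrix(1, nrow(fg), ncol(fg))
    m[fg & d <= r] <- 0
    new("BinaryMask", mask = m, source = "synthetic")
}

#' Relative removed area of a mask over a tooth
#'
#' Fraction of the tooth's nonzero pixels removed by the mask.
#'
#' @param M \linkS4class{BinaryMask}.
#' @param dmap tooth \linkS4class{DepthMap} defining the silhouette.
#' @export
relativeMaskArea <- function(M, dmap) {
    fg <- dmap@pixels > 0
    if (!any(fg)) stop("empty tooth")
    sum(M@mask == 0 & fg) / sum(fg)
}

#' Serialize masks and depth maps as PNG
#'
#' Depth maps are quantized to 8 bits; masks use the {0, 255} convention.
#' Calibration metadata travels in a JSON sidecar with the same basename.
#'
#' @param x \linkS4class{DepthMap} or \linkS4class{BinaryMask}.
#' @param path output PNG path.
#' @name png-io
NULL

#' @rdname png-io
#' @export
writeDepthMapPng <- function(x, path) {
    q <- floor(x@pixels + 0.5) / 255
    png::writePNG(q, path)
    side <- sub("\\.png$", ".json", path)
    jsonlite::write_json(list(zNorm = x@config@zNorm,
                              planeSize = x@config@planeSize,
                              cPixMm = calibration(x),
                              resolution = x@config@resolution,
                              provenance = x@provenance),
                         side, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname png-io
#' @export
readDepthMapPng <- function(path) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    side <- sub("\\.png$", ".json", path)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    cfg <- projectionConfig(resolution = meta$resolution,
                            planeSize = meta$planeSize, zNorm = meta$zNorm)
    new("DepthMap", pixels = round(img * 255), config = cfg,
        provenance = paste0("read:", path))
}

#' @rdname png-io
#' @export
writeMaskPng <- function(x, path) {
    png::writePNG(x@mask, path)
    invisible(path)
}

#' @rdname png-io
#' @export
readMaskPng <- function(path) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    new("BinaryMask", mask = (img > 0.5) * 1, source = "manual")
}
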