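#' @include AllClasses.R
NULL

#' Projection configuration constructor
#'
#' @param resolution image width = height, a power of two. Default 128:
#'   the desk-scale resolution used throughout the package's tests and
#'   examples (256 is the clinical-scale choice).
#' @param planeSize side of the quadratic projection plane, mm; must cover
#'   the dataset's largest xy extent plus twice \code{contourOffset}.
#' @param zNorm global depth window in mm; one intensity unit equals
#'   \code{zNorm/255} mm. The default covers the occlusal relief of the
#'   synthetic population (cusp tip to preparation floor) with a small
#'   margin: a window just large enough maximizes depth resolution and
#'   lets the silhouette fade to zero at the cervical fall-off, as in
#'   scanned crown maps, instead of cutting a tall intensity cliff at
#'   the contour.
#' @param nSample points sampled from a mesh per projection.
#' @param contourOffset margin between tooth contour and image border, mm.
#' @export
projectionConfig <- function(resolution = 128L, planeSize = 16, zNorm = 4.5,
                             nSample = 1e5, contourOffset = 1) {
    new("ProjectionConfig", resolution = as.integer(resolution),
        planeSize = planeSize, zNorm = zNorm, nSample = nSample,
        contourOffset = contourOffset)
}

#' Shift a point cloud so its top reaches the depth window
#'
#' Translates all points along z so the maximum z equals \code{zNorm},
#' placing the projection plane at the object's highest point for maximal
#' spatial resolution; xy coordinates are untouched.
#'
#' @param points n x 3 matrix or \linkS4class{OrientedPointCloud}.
#' @param zNorm depth window, mm.
#' @export
normalizeZ <- function(points, zNorm) {
    if (is(points, "OrientedPointCloud")) {
        p <- points@points
        p[, 3L] <- p[, 3L] + (zNorm - max(p[, 3L]))
        return(new("OrientedPointCloud", points = p, normals = points@normals))
    }
    if (nrow(points) == 0L) stop("empty cloud")
    points[, 3L] <- points[, 3L] + (zNorm - max(points[, 3L]))
    points
}

#' Rasterize a z-normalized point cloud into a depth map
#'
#' Per pixel the maximum sampled z in the pixel footprint is kept (the
#' projection captures the top surface and ignores deeper geometry) and
#' scaled linearly: intensity = 255 z / zNorm for z in (0, zNorm]; pixels
#' with no sample, or whose top sample lies below the depth window
#' (z <= 0), are exactly 0. Intensities are kept continuous; quantization
#' to 8 bits happens on export.
#'
#' @param points n x 3 matrix or \linkS4class{OrientedPointCloud},
#'   already z-normalized.
#' @param config \linkS4class{ProjectionConfig}.
#' @param center xy position of the plane center, mm. Default centers the
#'   bounding box of the points; pass an explicit center to keep several
#'   projections of the same tooth on a common pixel grid.
#' @param provenance tag recorded on the map.
#' @return a \linkS4class{DepthMap}.
#' @export
projectDepth <- function(points, config, center = NULL,
                         provenance = "projected") {
    p <- if (is(points, "OrientedPointCloud")) points@points else points
    if (nrow(p) == 0L) stop("empty cloud")
    w <- config@resolution
    pix <- config@planeSize / w
    if (is.null(center))
        center <- c(mean(range(p[, 1L])), mean(range(p[, 2L])))
    x0 <- center[1L] - config@planeSize / 2
    y1 <- center[2L] + config@planeSize / 2
    col <- floor((p[, 1L] - x0) / pix) + 1L
    row <- floor((y1 - p[, 2L]) / pix) + 1L
    if (any(col < 1L | col > w | row < 1L | row > w))
        stop("points fall outside the projection plane; increase planeSize")
    z <- p[, 3L]
    img <- matrix(0, w, w)
    ord <- order(z)                     # last write wins: max z per pixel
    img[cbind(row[ord], col[ord])] <- z[ord]
    img[img <= 0] <- 0
    img <- 255 * img / config@zNorm
    img[img > 255] <- 255
    new("DepthMap", pixels = img, config = config,
        provenance = provenance)
}

#' Fill isolated sampling dropouts in a depth map
#'
#' At desk-scale sampling densities a foreground pixel occasionally
#' receives no sample from the top surface, so its value falls to the
#' geometry underneath (or to 0) — a single-pixel rasterization artifact
#' that full-scale sampling densities do not show. A pixel is treated as
#' a dropout when all 8 neighbours are occupied and even the lowest
#' neighbour exceeds it by more than \code{minStep} intensity units: no
#' anatomical or preparation feature of the occlusal surface drops that
#' steeply in a single pixel relative to its entire neighbourhood (a
#' cavity-floor pixel at a preparation edge always keeps floor-level
#' neighbours: a straight edge leaves at most 5 higher neighbours and a
#' corner at most 5, so requiring at least 7 never touches true edges,
#' while isolated and paired dropouts are caught). Dropouts take the
#' median of their higher neighbours; the filter is iterated so dropout
#' pairs resolve.
#'
#' @param dmap \linkS4class{DepthMap}.
#' @param minStep minimal neighbourhood step identifying a dropout,
#'   intensity units (default 50, about 0.9 mm at the default window).
#' @param maxIter filter passes.
#' @return corrected \linkS4class{DepthMap}; the number of filled pixels
#'   is appended to the provenance tag.
#' @export
fillSamplingDropouts <- function(dmap, minStep = 50, maxIter = 3L) {
    m <- dmap@pixels
    h <- nrow(m); w <- ncol(m)
    totalFilled <- 0L
    for (it in seq_len(maxIter)) {
        pad <- matrix(0, h + 2L, w + 2L)
        pad[2:(h + 1L), 2:(w + 1L)] <- m
        nb <- array(0, dim = c(h, w, 8L))
        k <- 0L
        for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0L && dc == 0L) next
            k <- k + 1L
            nb[, , k] <- pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
        }
        high <- nb > array(rep(m + minStep, 8L), dim = dim(nb))
        cnt <- apply(high, c(1L, 2L), sum)
        drop <- cnt >= 7L
        if (!any(drop)) break
        nbHigh <- nb
        nbHigh[!high] <- NA_real_
        med <- apply(nbHigh, c(1L, 2L), stats::median, na.rm = TRUE)
        m[drop] <- med[drop]
        totalFilled <- totalFilled + sum(drop)
    }
    new("DepthMap", pixels = m, config = dmap@config,
        provenance = sprintf("%s;dropoutsFilled=%d", dmap@provenance,
                             totalFilled))
}

#' Quantize a depth map to 8-bit integers
#'
#' Round-half-away-from-zero, applied once at export.
#'
#' @param dmap \linkS4class{DepthMap}.
#' @export
quantizeDepthMap <- function(dmap) {
    q <- floor(dmap@pixels + 0.5)
    new("DepthMap", pixels = q, config = dmap@config,
        provenance = paste0(dmap@provenance, ";quantized"))
}

#' Canonicalize the in-plane pose of a depth map
#'
#' Rotates and shifts the map so the minimum-area bounding rectangle of
#' the tooth silhouette is axis-parallel with its center on the image
#' center. The rectangle fixes the angle only modulo 90 degrees; the
#' buccal hint (an image-frame 2D direction, rows increasing downwards)
#' picks the quadrant that puts the buccal side in the bottom half.
#'
#' @param dmap \linkS4class{DepthMap}.
#' @param buccalHint length-2 vector (dx across columns, dy down rows) or
#'   NULL to keep the angle in (-45, 45].
#' @return list: \code{map} (canonical \linkS4class{DepthMap}),
#'   \code{pose} with \code{angleDeg} and \code{translationPx}.
#' @export
canonicalizeInplane <- function(dmap, buccalHint = NULL) {
    m <- dmap@pixels
    fg <- which(m > 0, arr.ind = TRUE)
    if (nrow(fg) == 0L) stop("empty foreground")
    ## image coords: x = col, y = row (downwards)
    rect <- minAreaRect(cbind(fg[, 2L], fg[, 1L]))
    ang <- rect$angleDeg
    if (!is.null(buccalHint)) {
        ## after rotating the image by -ang+k*90 the hint rotates by the
        ## same amount; pick k so it points down (positive row direction)
        best <- NULL
        for (k in 0:3) {
            aa <- (-ang + 90 * k) * pi / 180
            ## rotation of direction (dx, dy) in image coords
            dy2 <- -sin(aa) * buccalHint[1L] + cos(aa) * buccalHint[2L]
            if (is.null(best) || dy2 > best$dy) best <- list(k = k, dy = dy2)
        }
        ang <- ang - 90 * best$k
    }
    ctr <- (dim(m) + 1) / 2
    shift <- c(ctr[1L] - rect$center[2L], ctr[2L] - rect$center[1L])
    out <- affineResampleImage(m, -ang, shift = shift)
    out[out < 0] <- 0
    out[out > 255] <- 255
    list(map = new("DepthMap", pixels = out, config = dmap@config,
                   provenance = paste0(dmap@provenance, ";canonicalized")),
         pose = list(angleDeg = ang, translationPx = shift))
}

#' Projection repeatability in millimetres
#'
#' Full-image RMSE between two depth maps on the same calibration, scaled
#' by the mm-per-intensity factor. Also reports the per-nonzero-pixel
#' variant (pixels nonzero in either map), for which
#' rmse_full = rmse_nonzero * sqrt(fraction nonzero) holds exactly.
#'
#' @param x0,xi \linkS4class{DepthMap}s with identical resolution and
#'   calibration.
#' @return named numeric: \code{rmseMm} (background included),
#'   \code{rmseMmNonzero} (background excluded).
#' @export
projectionRmseMm <- function(x0, xi) {
    if (x0@config@resolution != xi@config@resolution ||
        abs(x0@config@zNorm - xi@config@zNorm) > 1e-12)
        stop("resolution/calibration mismatch")
    d2 <- (x0@pixels - xi@pixels)^2
    nz <- (x0@pixels > 0) | (xi@pixels > 0)
    c(rmseMm = sqrt(mean(d2)) * calibration(x0),
      rmseMmNonzero = if (any(nz)) sqrt(mean(d2[nz])) * calibration(x0) else 0)
}

#' Project a normalized tooth mesh to a canonical depth map
#'
#' End-to-end projection: surface sampling, z-window alignment, in-plane
#' canonicalization (minimum-area rectangle of the sampled footprint,
#' quadrant resolved by the buccal annotation) applied to the point cloud
#' itself so no image resampling is involved, then rasterization centered
#' on the plane.
#'
#' @param mesh orientation-normalized \linkS4class{ToothMesh}.
#' @param config \linkS4class{ProjectionConfig}.
#' @param seed sampling seed.
#' @param buccal optional 3-vector buccal annotation (defaults to mesh
#'   metadata).
#' @param returnCloud also return the posed point cloud (used by mask
#'   extraction to stay on the same pixel grid).
#' @param normalMode normal interpolation mode passed to
#'   \code{\link{sampleSurface}}.
#' @return \linkS4class{DepthMap}, or a list \code{(map, cloud, pose)} if
#'   \code{returnCloud}.
#' @export
projectTooth <- function(mesh, config, seed = 0L, buccal = NULL,
                         returnCloud = FALSE, normalMode = "interpolated") {
    if (is.null(buccal)) buccal <- mesh@metadata$buccal
    cloud <- sampleSurface(mesh, config@nSample, seed, normalMode = normalMode)
    cloud <- normalizeZ(cloud, config@zNorm)
    p <- cloud@points
    ## the bounding rectangle comes from the mesh's own silhouette, not
    ## from the sampled cloud: the pose is then deterministic and the
    ## sampling seed perturbs only the rasterization
    ip <- inplaneCanonicalAngle(mesh@vertices[, 1:2, drop = FALSE],
                                if (is.null(buccal)) NULL else buccal[1:2])
    ang <- ip$angleDeg
    aa <- -ang * pi / 180
    Rot <- matrix(c(cos(aa), sin(aa), -sin(aa), cos(aa)), 2L, 2L)
    xy <- sweep(p[, 1:2], 2L, ip$center) %*% t(Rot)
    p2 <- cbind(xy, p[, 3L])
    n2 <- cbind(cloud@normals[, 1:2] %*% t(Rot), cloud@normals[, 3L])
    posed <- new("OrientedPointCloud", points = p2, normals = n2)
    map <- projectDepth(posed, config, center = c(0, 0),
                        provenance = sprintf("projectTooth(seed=%d)", seed))
    map <- fillSamplingDropouts(map)
    if (returnCloud)
        list(map = map, cloud = posed,
             pose = list(angleDeg = ang, center = ip$center))
    else map
}

#' Sampling repeatability confidence interval
#'
#' Projects the same mesh \code{nRep} times with distinct sampling seeds,
#' computes the mm RMSE of each projection against the first (the
#' reference), and returns the 95 percent t confidence interval of the
#' mean RMSE.
#'
#' @param mesh normalized \linkS4class{ToothMesh}.
#' @param config \linkS4class{ProjectionConfig}.
#' @param nRep number of repetitions (>= 2).
#' @param seed base seed; repetition i uses seed + i - 1.
#' @return list with \code{low}, \code{high} (mm), \code{rmses} (mm per
#'   repetition) .
#' @export
repeatabilityCi <- function(mesh, config, nRep = 20L, seed = 1L) {
    stopifnot(nRep >= 2L)
    maps <- lapply(seq_len(nRep), function(i)
        projectTooth(mesh, config, seed = as.integer(seed) + i - 1L))
    rmses <- vapply(maps[-1L], function(m)
        projectionRmseMm(maps[[1L]], m)[["rmseMm"]], numeric(1L))
    n <- length(rmses)
    mu <- mean(rmses)
    se <- stats::sd(rmses) / sqrt(n)
    if (!is.finite(se) || se == 0) return(list(low = mu, high = mu, rmses = rmses))
    tq <- stats::qt(0.975, n - 1L)
    list(low = mu - tq * se, high = mu + tq * se, rmses = rmses)
}

#' Back-project a depth map to a heightfield mesh
#'
#' One vertex per nonzero pixel at z = intensity times the mm-per-unit
#' calibration, triangulated over 4-neighbour adjacency (two triangles per
#' fully nonzero 2x2 pixel block). Re-projecting the mesh reproduces the
#' map up to quantization.
#'
#' @param dmap \linkS4class{DepthMap}.
#' @param config optional \linkS4class{ProjectionConfig} (defaults to the
#'   map's own).
#' @return an open-surface \linkS4class{ToothMesh}.
#' @export
backproject <- function(dmap, config = dmap@config) {
    m <- dmap@pixels
    if (all(m == 0)) stop("all-zero depth map")
    w <- config@resolution
    pix <- config@planeSize / w
    nzi <- which(m > 0)
    vid <- matrix(0L, nrow(m), ncol(m))
    vid[nzi] <- seq_along(nzi)
    rows <- ((nzi - 1L) %% nrow(m)) + 1L
    cols <- ((nzi - 1L) %/% nrow(m)) + 1L
    ## pixel centers; image center at origin, +y up (row 1 = top)
    x <- (cols - 0.5 - w / 2) * pix
    y <- (w / 2 - rows + 0.5) * pix
    z <- m[nzi] * calibration(dmap)
    verts <- cbind(x, y, z)
    f <- list()
    h <- nrow(m)
    a <- vid[-h, -ncol(m)]; b <- vid[-h, -1L]
    cc <- vid[-1L, -ncol(m)]; d <- vid[-1L, -1L]
    quad <- a > 0 & b > 0 & cc > 0 & d > 0
    f1 <- cbind(a[quad], cc[quad], b[quad])
    f2 <- cbind(b[quad], cc[quad], d[quad])
    fmat <- rbind(f1, f2)
    new("ToothMesh", vertices = verts, faces = fmat,
        normals = computeVertexNormals(verts, fmat),
        metadata = list(provenance = "backprojected"))
}
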