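#' @include AllClasses.R
NULL

## Directional extreme points: for a set of quasi-uniform sphere directions
## take the farthest point each way; the result is a small subset of convex
## hull vertices sufficient for bounding-box candidate enumeration.
extremePointSubset <- function(pts, maxKeep = 26L) {
    n <- nrow(pts)
    if (n <= maxKeep) return(unique(pts))
    gold <- pi * (3 - sqrt(5))
    k <- 160L
    i <- seq_len(k) - 0.5
    z <- 1 - 2 * i / k
    r <- sqrt(pmax(0, 1 - z^2))
    dirs <- cbind(r * cos(gold * i), r * sin(gold * i), z)
    proj <- pts %*% t(dirs)
    idx <- unique(apply(proj, 2L, which.max))
    sub <- unique(pts[idx, , drop = FALSE])
    if (nrow(sub) > maxKeep) {
        ## keep the points most often extreme first
        tab <- sort(table(apply(proj, 2L, which.max)), decreasing = TRUE)
        sub <- unique(pts[as.integer(names(tab))[seq_len(maxKeep)], ,
                          drop = FALSE])
    }
    sub
}

## Box volume and extents for a rotation candidate, measured on all points.
boxForRotation <- function(pts, R) {
    q <- pts %*% R
    lo <- apply(q, 2L, min); hi <- apply(q, 2L, max)
    list(R = R, extents = hi - lo, volume = prod(hi - lo),
         center = as.numeric(R %*% ((lo + hi) / 2)))
}

## Complete a unit normal into a rotation whose third column is the normal,
## with the in-plane axes chosen by 2D rotating calipers for minimal area.
rotationFromNormal <- function(pts, nrm) {
    nrm <- nrm / vnorm(nrm)
    ref <- if (abs(nrm[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * nrm) * nrm
    u <- u / vnorm(u)
    v <- c(nrm[2L] * u[3L] - nrm[3L] * u[2L],
           nrm[3L] * u[1L] - nrm[1L] * u[3L],
           nrm[1L] * u[2L] - nrm[2L] * u[1L])
    xy <- pts %*% cbind(u, v)
    rect <- minAreaRect(xy)
    a <- rect$angleDeg * pi / 180
    u2 <- cos(a) * u + sin(a) * v
    v2 <- -sin(a) * u + cos(a) * v
    cbind(u2, v2, nrm)
}

#' Minimum-volume oriented bounding box
#'
#' Searches candidate box orientations (face normals enumerated from
#' triples of a directional-extreme-point subset, the PCA frame and the
#' identity), closing each candidate with a minimum-area rectangle in the
#' face plane; extents are always measured over the full cloud so the
#' returned box contains every point, and the identity candidate
#' guarantees the volume never exceeds the axis-aligned box. Exact for
#' small clouds whose optimal box is flush with a hull face (e.g. boxes,
#' cuboids).
#'
#' The returned frame is canonicalized: axes ordered by extent descending
#' and, when the cloud carries orientation cues (see
#' \code{\link{normalizeOrientation}}), signs fixed there.
#'
#' @param cloud an \linkS4class{OrientedPointCloud} or an n x 3 matrix.
#' @return list with \code{rotation} (columns are box axes, det +1),
#'   \code{extents} (descending, mm), \code{center} and \code{volume}.
#' @export
fitBoundingBox <- function(cloud) {
    pts <- if (is(cloud, "OrientedPointCloud")) cloud@points else cloud
    if (nrow(pts) < 4L) stop("need at least 4 points")
    ctr <- colMeans(pts)
    pc <- sweep(pts, 2L, ctr)
    sv <- svd(pc, nu = 0L)
    if (sv$d[3L] < 1e-12 * max(sv$d[1L], 1))
        stop("degenerate (coplanar) point cloud")
    sub <- extremePointSubset(pc)
    cands <- list(diag(3L))
    ## PCA frame
    cands[[2L]] <- sv$v
    ns <- nrow(sub)
    if (ns >= 3L) {
        tri <- utils::combn(ns, 3L)
        keepNorms <- matrix(numeric(0), 0L, 3L)
        for (t in seq_len(ncol(tri))) {
            e1 <- sub[tri[2L, t], ] - sub[tri[1L, t], ]
            e2 <- sub[tri[3L, t], ] - sub[tri[1L, t], ]
            nn <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
                    e1[3L] * e2[1L] - e1[1L] * e2[3L],
                    e1[1L] * e2[2L] - e1[2L] * e2[1L])
            L <- vnorm(nn)
            if (L < 1e-12) next
            nn <- nn / L
            if (nn[3L] < 0 || (nn[3L] == 0 && nn[1L] < 0)) nn <- -nn
            if (nrow(keepNorms) > 0 &&
                any(abs(keepNorms %*% nn) > 1 - 1e-9)) next
            keepNorms <- rbind(keepNorms, nn)
        }
        ## rank candidate normals quickly on the subset, refine the best
        if (nrow(keepNorms) > 0) {
            vols <- vapply(seq_len(nrow(keepNorms)), function(i) {
                R <- rotationFromNormal(sub, keepNorms[i, ])
                boxForRotation(sub, R)$volume
            }, numeric(1L))
            topk <- order(vols)[seq_len(min(30L, length(vols)))]
            for (i in topk)
                cands[[length(cands) + 1L]] <-
                    rotationFromNormal(pc, keepNorms[i, ])
        }
    }
    boxes <- lapply(cands, function(R) boxForRotation(pc, R))
    best <- boxes[[which.min(vapply(boxes, `[[`, numeric(1L), "volume"))]]
    ## order axes by extent descending, keep det +1
    ord <- order(best$extents, decreasing = TRUE)
    R <- unname(best$R[, ord, drop = FALSE])
    if (det(R) < 0) R[, 3L] <- -R[, 3L]
    b <- boxForRotation(pc, R)
    list(rotation = R, extents = unname(b$extents), volume = b$volume,
         center = unname(ctr + b$center))
}

#' Derotate a point cloud by its bounding-box frame
#'
#' Applies the inverse box rotation to points and normals so the box axes
#' align with the coordinate axes; refitting a box on the output yields an
#' identity rotation up to box symmetry.
#'
#' @param cloud \linkS4class{OrientedPointCloud}.
#' @param frame result of \code{\link{fitBoundingBox}} (or any list with a
#'   \code{rotation} element).
#' @export
derotateByBox <- function(cloud, frame) {
    R <- frame$rotation
    if (!isRotationMatrix(R, tol = 1e-6)) stop("frame rotation is not orthonormal")
    new("OrientedPointCloud", points = cloud@points %*% R,
        normals = cloud@normals %*% R)
}

#' Select the occlusal point subset by normal direction
#'
#' After box derotation the occlusal surface normals point towards +z;
#' keeping the points whose normal z-component exceeds \code{nzT} isolates
#' cusp tops and fossa bottoms, the features that define the occlusal
#' plane. The default threshold 0.9 follows the reported best value.
#'
#' @param cloud box-derotated \linkS4class{OrientedPointCloud}.
#' @param nzT threshold in (0, 1).
#' @export
selectOcclusalSubset <- function(cloud, nzT = 0.9) {
    keep <- cloud@normals[, 3L] > nzT
    if (!any(keep))
        stop("occlusal subset empty; lower the normal-z threshold nzT")
    new("OrientedPointCloud", points = cloud@points[keep, , drop = FALSE],
        normals = cloud@normals[keep, , drop = FALSE])
}

#' PCA plane fit of the occlusal subset
#'
#' The two leading eigenvectors of the subset covariance span the plane;
#' the smallest-eigenvalue eigenvector is the plane normal, sign-fixed to
#' a positive z-component. Equivalent to the total-least-squares (SVD)
#' plane.
#'
#' @param subset \linkS4class{OrientedPointCloud} (or n x 3 matrix) of at
#'   least 3 non-collinear points.
#' @return list with unit vectors \code{v1}, \code{v2}, \code{normal},
#'   centroid \code{mu} and the eigenvalues.
#' @export
fitPlanePCA <- function(subset) {
    pts <- if (is(subset, "OrientedPointCloud")) subset@points else subset
    if (nrow(pts) < 3L) stop("need at least 3 points")
    mu <- colMeans(pts)
    K <- stats::cov(pts)
    e <- eigen(K, symmetric = TRUE)
    if (e$values[2L] < 1e-14 * max(e$values[1L], 1))
        stop("collinear points: plane undefined")
    v3 <- e$vectors[, 3L]
    if (v3[3L] < 0) v3 <- -v3
    list(v1 = e$vectors[, 1L], v2 = e$vectors[, 2L], normal = v3,
         mu = mu, eigenvalues = e$values)
}

#' Rotation matrix that levels a fitted plane
#'
#' Built from the plane's slopes: the x-axis image follows the plane's
#' rise along x, the y-axis image its rise along y, and the z-axis is
#' their cross product; applying the inverse rotation makes the plane
#' horizontal while leaving the rotation about z unchanged.
#'
#' @param plane result of \code{\link{fitPlanePCA}}.
#' @return 3 x 3 rotation matrix whose third column is proportional to the
#'   plane normal.
#' @export
planeRotation <- function(plane) {
    n <- plane$normal
    if (abs(n[3L]) < 1e-9) stop("vertical plane: slopes undefined")
    ## z(x, y) on the plane: slope along x is -nx/nz, along y is -ny/nz
    sx <- -n[1L] / n[3L]
    sy <- -n[2L] / n[3L]
    xF <- c(1, 0, sx); xF <- xF / vnorm(xF)
    yF <- c(0, 1, sy); yF <- yF / vnorm(yF)
    zF <- c(xF[2L] * yF[3L] - xF[3L] * yF[2L],
            xF[3L] * yF[1L] - xF[1L] * yF[3L],
            xF[1L] * yF[2L] - xF[2L] * yF[1L])
    zF <- zF / vnorm(zF)
    ## the slope-based xF/yF pair is only orthogonal when one slope is
    ## zero; keep xF and the exact plane normal zF, re-orthogonalize yF
    ## (minimal correction, O(sx*sy)) so the result is a true rotation
    yF <- c(zF[2L] * xF[3L] - zF[3L] * xF[2L],
            zF[3L] * xF[1L] - zF[1L] * xF[3L],
            zF[1L] * xF[2L] - zF[2L] * xF[1L])
    yF <- yF / vnorm(yF)
    cbind(xF, yF, zF)
}

## Resolve the box symmetry: ordered extents fix the axis permutation;
## signs are chosen so the occlusal side maps to +z (bumpiness heuristic:
## of the two z-sign choices, the side whose high-normal-z subset shows the
## larger residual height spread is the cusp-bearing occlusal surface, the
## flat base having essentially none) and the buccal annotation to -y.
canonicalizeBoxSigns <- function(cloud, R, buccal = NULL) {
    score <- function(Rc) {
        nz <- cloud@normals %*% Rc[, 3L]
        keep <- nz > 0.7
        if (sum(keep) < 10L) return(-Inf)
        stats::sd((cloud@points %*% Rc[, 3L])[keep])
    }
    Rflip <- R; Rflip[, 2L] <- -R[, 2L]; Rflip[, 3L] <- -R[, 3L]
    if (score(Rflip) > score(R)) R <- Rflip
    if (!is.null(buccal)) {
        by <- sum(buccal * R[, 2L])
        if (by > 0) { R[, 1L] <- -R[, 1L]; R[, 2L] <- -R[, 2L] }
    }
    R
}

#' Normalize the 3D orientation of a tooth mesh
#'
#' Two-stage pose normalization: (1) derotation by the minimum-volume
#' bounding-box frame, making the pose independent of the scanner's
#' coordinate system, then (2) leveling of the occlusal plane fitted by
#' PCA to the subset of points whose normals exceed \code{nzT} in z. The
#' second rotation is built from the plane slopes only, so the rotation
#' about z is untouched. The output mesh is centered at its centroid in
#' xy with its base at z = 0.
#'
#' @param mesh \linkS4class{ToothMesh}.
#' @param nzT occlusal normal-z threshold (default 0.9).
#' @param buccal optional 3-vector annotation of the buccal direction in
#'   the same frame as the mesh; defaults to the mesh's own metadata.
#'   Without one the 180-degree in-plane ambiguity cannot be resolved.
#' @return list: \code{mesh} (normalized), \code{boxFrame}, \code{plane}
#'   (fitted on the derotated cloud), \code{rotation} (the full applied
#'   rotation), \code{buccal} (the annotation carried into the normalized
#'   frame, or NULL).
#' @export
normalizeOrientation <- function(mesh, nzT = 0.9, buccal = NULL) {
    if (is.null(buccal)) buccal <- mesh@metadata$buccal
    cloud <- new("OrientedPointCloud", points = mesh@vertices,
                 normals = mesh@normals)
    frame <- fitBoundingBox(cloud)
    R1 <- canonicalizeBoxSigns(cloud, frame$rotation, buccal)
    c1 <- derotateByBox(cloud, list(rotation = R1))
    ## plane leveling is iterated: the occlusal subset is re-selected in
    ## the leveled frame until the fitted plane is horizontal (the
    ## threshold cut moves slightly with the pose, so a single pass
    ## leaves a residual tilt of order 1 degree)
    Rtot <- R1
    plane <- NULL
    for (it in 1:12) {
        sub <- selectOcclusalSubset(c1, nzT)
        plane <- fitPlanePCA(sub)
        tilt <- acos(min(1, plane$normal[3L]))
        if (tilt < 1e-5 && it > 1L) break
        RP <- planeRotation(plane)
        Rtot <- Rtot %*% RP
        c1 <- derotateByBox(c1, list(rotation = RP))
    }
    ## canonicalize the residual rotation about z from the minimum-area
    ## bounding rectangle of the leveled silhouette (buccal side resolves
    ## the 90-degree ambiguity); the box frame only fixes it coarsely
    bNow <- if (!is.null(buccal)) as.numeric(buccal %*% Rtot) else NULL
    ip <- inplaneCanonicalAngle(c1@points[, 1:2, drop = FALSE],
                                if (is.null(bNow)) NULL else bNow[1:2])
    Rtot <- Rtot %*% rotZ(ip$angleDeg)
    v <- mesh@vertices %*% Rtot
    n <- mesh@normals %*% Rtot
    v[, 1L] <- v[, 1L] - mean(v[, 1L])
    v[, 2L] <- v[, 2L] - mean(v[, 2L])
    v[, 3L] <- v[, 3L] - min(v[, 3L])
    md <- mesh@metadata
    bOut <- if (!is.null(buccal)) as.numeric(buccal %*% Rtot) else NULL
    if (!is.null(bOut)) md$buccal <- bOut
    list(mesh = new("ToothMesh", vertices = v, faces = mesh@faces,
                    normals = n, metadata = md),
         boxFrame = frame, plane = plane, rotation = Rtot, buccal = bOut)
}
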