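#' @include AllClasses.R
NULL

#' Shape parameters of a synthetic molar crown
#'
#' The synthetic crown is a superellipse-footprint dome carrying Gaussian
#' cusp bumps, a central Gaussian fossa and band-limited surface noise,
#' closed by vertical side walls and a flat base. Its top surface is a
#' single-valued heightfield over the footprint, so the depth-map
#' projection is lossless by construction. Default dimensions are typical
#' of a lower first molar (about 11 x 10 mm footprint, 8 mm total height);
#' they are configuration values, not measurements.
#'
#' @param footprintRadii semi-axes of the superellipse footprint, mm.
#' @param footprintExponent superellipse exponent (2 = ellipse; larger is
#'   squarer).
#' @param baseHeight height of the crown dome at its center before cusp
#'   and fossa modulation, mm.
#' @param cuspCenters k x 2 matrix of cusp positions, mm.
#' @param cuspHeights,cuspWidths per-cusp Gaussian amplitude and sd, mm.
#' @param fossaDepth,fossaWidth central fossa Gaussian amplitude and sd, mm.
#' @param noiseAmp rms amplitude of the band-limited surface noise, mm.
#' @param buccalDirection unit 2-vector marking the cheek-facing side in
#'   the intrinsic frame (real scans carry no such label; synthetic teeth
#'   are annotated explicitly).
#' @param gridN angular resolution of the generated mesh (radial rings are
#'   scaled proportionally).
#' @return object of class \code{ToothShapeParams}.
#' @export
toothShapeParams <- function(footprintRadii = c(5.5, 5.0),
                             footprintExponent = 2.5,
                             baseHeight = 5.2,
                             cuspCenters = rbind(c(2.4, 2.2), c(-2.4, 2.2),
                                                 c(-2.4, -2.2), c(2.4, -2.2)),
                             cuspHeights = c(2.6, 2.4, 2.2, 2.5),
                             cuspWidths = rep(1.5, 4L),
                             fossaDepth = 1.2, fossaWidth = 1.8,
                             noiseAmp = 0.05,
                             buccalDirection = c(0, -1),
                             gridN = 288L) {
    stopifnot(length(footprintRadii) == 2L, all(footprintRadii > 0),
              baseHeight > 0, fossaDepth >= 0, fossaWidth > 0,
              nrow(cuspCenters) == length(cuspHeights),
              length(cuspWidths) == length(cuspHeights),
              all(cuspWidths > 0), noiseAmp >= 0)
    if (fossaDepth >= min(cuspHeights) + baseHeight)
        stop("fossa depth must stay below the cusp heights")
    b <- buccalDirection / vnorm(buccalDirection)
    structure(list(footprintRadii = footprintRadii,
                   footprintExponent = footprintExponent,
                   baseHeight = baseHeight, cuspCenters = cuspCenters,
                   cuspHeights = cuspHeights, cuspWidths = cuspWidths,
                   fossaDepth = fossaDepth, fossaWidth = fossaWidth,
                   noiseAmp = noiseAmp, buccalDirection = b,
                   gridN = as.integer(gridN)),
              class = "ToothShapeParams")
}

## Superellipse boundary point at polar angle theta.
superellipsePoint <- function(theta, radii, n) {
    ct <- cos(theta); st <- sin(theta)
    cbind(radii[1L] * sign(ct) * abs(ct)^(2 / n),
          radii[2L] * sign(st) * abs(st)^(2 / n))
}

footprintPolygon <- function(params, n = 256L) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    superellipsePoint(th, params$footprintRadii, params$footprintExponent)
}

## Band-limited noise field: a fixed sum of random plane waves, returned as
## a closure so mesh generation and test oracles evaluate the same field.
noiseField <- function(params, seed, nWaves = 12L) {
    if (params$noiseAmp == 0) return(function(x, y) rep(0, length(x)))
    coef <- withSeed(seed, {
        k <- stats::runif(nWaves, 0.4, 1.6)        # cycles per mm band
        ang <- stats::runif(nWaves, 0, 2 * pi)
        list(kx = 2 * pi * k * cos(ang), ky = 2 * pi * k * sin(ang),
             phase = stats::runif(nWaves, 0, 2 * pi),
             amp = stats::rnorm(nWaves))
    })
    scale <- params$noiseAmp / sqrt(sum(coef$amp^2) / 2)
    function(x, y) {
        z <- numeric(length(x))
        for (j in seq_along(coef$amp))
            z <- z + coef$amp[j] *
                cos(coef$kx[j] * x + coef$ky[j] * y + coef$phase[j])
        scale * z
    }
}

#' Analytic occlusal heightfield of a synthetic tooth
#'
#' Returns a function \code{f(x, y)} giving the top-surface height in mm in
#' the tooth's intrinsic frame (NA outside the footprint). The same field
#' drives mesh generation, so it serves as the exact oracle for projection
#' and mask tests.
#'
#' @param params \code{ToothShapeParams}.
#' @param seed integer seed fixing the noise field.
#' @export
heightfieldFunction <- function(params, seed = 0L) {
    nf <- noiseField(params, seed)
    a <- params$footprintRadii[1L]; b <- params$footprintRadii[2L]
    n <- params$footprintExponent
    function(x, y) {
        rho <- (abs(x / a)^n + abs(y / b)^n)^(1 / n)
        z <- params$baseHeight * (1 - 0.35 * rho^3)
        for (k in seq_along(params$cuspHeights)) {
            dx <- x - params$cuspCenters[k, 1L]
            dy <- y - params$cuspCenters[k, 2L]
            z <- z + params$cuspHeights[k] *
                exp(-(dx^2 + dy^2) / (2 * params$cuspWidths[k]^2))
        }
        z <- z - params$fossaDepth *
            exp(-(x^2 + y^2) / (2 * params$fossaWidth^2))
        z <- z + nf(x, y)
        z[rho > 1] <- NA_real_
        z
    }
}

## Orient all faces outward using the signed volume of the closed mesh.
orientOutward <- function(vertices, faces) {
    v1 <- vertices[faces[, 1L], , drop = FALSE]
    v2 <- vertices[faces[, 2L], , drop = FALSE]
    v3 <- vertices[faces[, 3L], , drop = FALSE]
    vol <- sum(v1[, 1L] * (v2[, 2L] * v3[, 3L] - v3[, 2L] * v2[, 3L]) -
               v2[, 1L] * (v1[, 2L] * v3[, 3L] - v3[, 2L] * v1[, 3L]) +
               v3[, 1L] * (v1[, 2L] * v2[, 3L] - v2[, 2L] * v1[, 3L])) / 6
    if (vol < 0) faces[, c(2L, 3L)] <- faces[, c(3L, 2L)]
    faces
}

#' Generate a synthetic molar crown mesh
#'
#' Builds a closed 2-manifold triangle mesh whose top surface samples the
#' analytic heightfield on a polar grid, with vertical side walls and a
#' flat base at z = 0. Deterministic for a fixed \code{(params, seed)}.
#'
#' @param params \code{ToothShapeParams}.
#' @param seed integer seed for the surface noise field.
#' @return a \linkS4class{ToothMesh}; metadata carries \code{params},
#'   \code{heightfield} and the 3D \code{buccal} direction.
#' @export
generateToothMesh <- function(params, seed = 0L) {
    if (!inherits(params, "ToothShapeParams")) stop("invalid params")
    if (min(params$footprintRadii) < 1e-6) stop("degenerate footprint")
    hf <- heightfieldFunction(params, seed)
    nth <- params$gridN
    nu <- max(8L, as.integer(round(nth / 4)))
    nw <- 6L
    th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
    bnd <- superellipsePoint(th, params$footprintRadii,
                             params$footprintExponent)
    ## top surface: center vertex + nu rings
    u <- seq_len(nu) / nu
    topx <- as.vector(outer(bnd[, 1L], u))      # ring-major: theta fast
    topy <- as.vector(outer(bnd[, 2L], u))
    dim(topx) <- dim(topy) <- NULL
    topz <- hf(topx, topy)
    topz[is.na(topz)] <- hf(topx[is.na(topz)] * 0.999999,
                            topy[is.na(topz)] * 0.999999)
    cz <- hf(0, 0)
    marginZ <- topz[(nu - 1L) * nth + seq_len(nth)]
    ## wall rings (exclude the top boundary ring itself), then base ring z=0
    wallFrac <- seq_len(nw) / nw
    wallx <- rep(bnd[, 1L], nw)
    wally <- rep(bnd[, 2L], nw)
    wallz <- as.vector(vapply(wallFrac,
                              function(f) marginZ * (1 - f), numeric(nth)))
    verts <- rbind(c(0, 0, cz),
                   cbind(topx, topy, topz),
                   cbind(wallx, wally, wallz),
                   c(0, 0, 0))
    dimnames(verts) <- NULL
    idxCenter <- 1L
    idxTop <- function(ring, j) 1L + (ring - 1L) * nth + j   # ring in 1..nu
    idxWall <- function(ring, j) 1L + nu * nth + (ring - 1L) * nth + j
    idxBase <- nrow(verts)
    jn <- c(seq_len(nth)[-1L], 1L)               # next angular index
    faces <- vector("list", 4L)
    ## center fan
    faces[[1L]] <- cbind(idxCenter, idxTop(1L, seq_len(nth)),
                         idxTop(1L, jn))
    ## top ring quads
    ringQuads <- function(iA, iB) {
        a1 <- iA(seq_len(nth)); a2 <- iA(jn)
        b1 <- iB(seq_len(nth)); b2 <- iB(jn)
        rbind(cbind(a1, b1, b2), cbind(a1, b2, a2))
    }
    tq <- lapply(seq_len(nu - 1L), function(r)
        ringQuads(function(j) idxTop(r, j), function(j) idxTop(r + 1L, j)))
    faces[[2L]] <- do.call(rbind, tq)
    ## wall quads: top boundary ring down through wall rings
    wallLevels <- c(list(function(j) idxTop(nu, j)),
                    lapply(seq_len(nw), function(r)
                        function(j) idxWall(r, j)))
    wq <- lapply(seq_len(nw), function(k)
        ringQuads(wallLevels[[k]], wallLevels[[k + 1L]]))
    faces[[3L]] <- do.call(rbind, wq)
    ## base fan (bottom ring is wall ring nw, z = 0)
    faces[[4L]] <- cbind(idxBase, idxWall(nw, jn), idxWall(nw, seq_len(nth)))
    fmat <- do.call(rbind, faces)
    dimnames(fmat) <- NULL
    fmat <- orientOutward(verts, fmat)
    normals <- computeVertexNormals(verts, fmat)
    new("ToothMesh", vertices = verts, faces = fmat, normals = normals,
        metadata = list(params = params, seed = as.integer(seed),
                        heightfield = hf,
                        buccal = c(params$buccalDirection, 0)))
}

#' Rigid transform of a tooth mesh
#'
#' Applies rotation then translation to vertices; normals and the carried
#' buccal annotation rotate with the mesh. Connectivity is unchanged.
#'
#' @param mesh \linkS4class{ToothMesh}.
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation length-3 numeric, mm.
#' @export
applyRigidTransform <- function(mesh, rotation = diag(3),
                                translation = c(0, 0, 0)) {
    if (!isRotationMatrix(rotation))
        stop("rotation must be proper orthonormal (det +1)")
    v <- mesh@vertices %*% t(rotation)
    v <- sweep(v, 2L, translation, "+")
    n <- mesh@normals %*% t(rotation)
    md <- mesh@metadata
    if (!is.null(md$buccal)) md$buccal <- as.numeric(rotation %*% md$buccal)
    md$heightfieldFrameValid <- FALSE
    new("ToothMesh", vertices = v, faces = mesh@faces, normals = n,
        metadata = md)
}

#' Specification of a cavity preparation
#'
#' Four preparation types of increasing removed occlusal area are
#' provided, mirroring commonly used inlay geometries: type "a" is an
#' interior cavity that leaves the outer contour intact, types "b"-"d"
#' open the contour on one or both proximal sides. The removed fraction of
#' the occlusal area rises monotonically a -> d across roughly 0.3 to 0.8.
#' Cavity footprints are sized numerically against the tooth footprint at
#' construction so the target fractions hold for any crown dimensions.
#'
#' @param prepType one of "a", "b", "c", "d".
#' @param params the \code{ToothShapeParams} of the tooth to be prepared.
#' @param floorZ cavity floor height, mm (defaults per type; floors stay
#'   inside the depth window so the cavity remains visible in the map).
#' @param zNorm depth window used to define the visible occlusal area
#'   that the removed-area fractions refer to, mm.
#' @param wallSlopeDeg cavity wall slope in degrees from vertical. The
#'   near-vertical default keeps wall normals an order of magnitude below
#'   the occlusal normal-z threshold used in mask extraction and keeps
#'   the projected wall band sub-pixel at the working resolution, so the
#'   mask boundary coincides with the preparation edge.
#' @return object of class \code{PreparationSpec} with the cavity footprint
#'   polygon, floor height, wall slope and contour-cut flag.
#' @export
preparationSpec <- function(prepType = c("a", "b", "c", "d"), params,
                            floorZ = NULL, wallSlopeDeg = 1.5,
                            zNorm = 4.5) {
    prepType <- match.arg(prepType)
    a <- params$footprintRadii[1L]; b <- params$footprintRadii[2L]
    fp <- footprintPolygon(params)
    target <- c(a = 0.29, b = 0.44, c = 0.60, d = 0.76)[[prepType]]
    if (is.null(floorZ))
        floorZ <- c(a = 3.3, b = 3.2, c = 3.1, d = 3.0)[[prepType]]
    poly <- switch(prepType,
        a = function(s) shiftPoly(sePoly(s * 1.2 * a, s * 0.85 * b, 2.2),
                                  0.3, 0),
        b = function(s) shiftPoly(sePoly(s * 1.1 * a, s * 0.8 * b, 2.2),
                                  0.45 * a, 0),
        c = function(s) sePoly(1.35 * a, s * b, 3.5),
        d = function(s) shiftPoly(sePoly(s * a, s * b,
                                         params$footprintExponent), 0.12 * a, 0))
    p0 <- params; p0$noiseAmp <- 0
    hf0 <- heightfieldFunction(p0, 0L)
    scale <- fitPolygonScale(poly, target, fp, hf = hf0, zNorm = zNorm)
    structure(list(prepType = prepType, cavityPolygon = poly(scale),
                   floorZ = floorZ, wallSlopeDeg = wallSlopeDeg,
                   cutsOuterContour = prepType != "a",
                   targetFraction = target),
              class = "PreparationSpec")
}

sePoly <- function(ra, rb, n, k = 96L) {
    th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
    superellipsePoint(th, c(ra, rb), n)
}

shiftPoly <- function(poly, dx, dy) sweep(poly, 2L, c(dx, dy), "+")

## Binary-search the polygon scale so that area(polygon & visible region)
## equals targetFrac * area(visible region), measured on a fine grid. The
## visible region is the part of the occlusal surface inside the depth
## window (relative removed areas are defined against the nonzero pixels
## of the depth map).
fitPolygonScale <- function(polyFn, targetFrac, footprint, gridN = 240L,
                            hf = NULL, zNorm = Inf) {
    xr <- range(footprint[, 1L]); yr <- range(footprint[, 2L])
    gx <- seq(xr[1L], xr[2L], length.out = gridN)
    gy <- seq(yr[1L], yr[2L], length.out = gridN)
    px <- rep(gx, times = gridN); py <- rep(gy, each = gridN)
    inFp <- pointInPolygon(px, py, footprint)
    if (!is.null(hf) && is.finite(zNorm)) {
        z <- hf(px, py)
        top <- max(z, na.rm = TRUE)
        inFp <- inFp & !is.na(z) & (z > top - zNorm)
    }
    nFp <- sum(inFp)
    frac <- function(s) {
        poly <- polyFn(s)
        sum(pointInPolygon(px[inFp], py[inFp], poly)) / nFp
    }
    lo <- 0.05; hi <- 1.6
    for (i in 1:40) {
        mid <- (lo + hi) / 2
        if (frac(mid) < targetFrac) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

#' Carve a cavity preparation into a synthetic tooth
#'
#' Lowers the top surface to the cavity floor inside the cavity footprint,
#' with near-vertical walls rising at the specified slope outside it; the
#' operation only removes material (the new surface is the pointwise
#' minimum of the old surface and the cavity profile), producing the sharp
#' break in surface continuity at the preparation edge that mask
#' extraction relies on.
#'
#' @param mesh normalized-orientation \linkS4class{ToothMesh} (intrinsic
#'   frame of its params).
#' @param spec a \code{PreparationSpec}.
#' @return list with elements \code{mesh} (the prepared tooth; its
#'   metadata gains \code{prepSpec} and an analytic \code{removedFn(x, y)}
#'   ground-truth indicator), and \code{region} (the cavity footprint
#'   polygon in the occlusal plane).
#' @export
carvePreparation <- function(mesh, spec) {
    if (!inherits(spec, "PreparationSpec")) stop("invalid preparation spec")
    poly <- spec$cavityPolygon
    if (nrow(poly) < 3L || polygonArea(poly) < 1e-9)
        return(list(mesh = mesh, region = poly[0, , drop = FALSE]))
    v <- mesh@vertices
    tanS <- tan(spec$wallSlopeDeg * pi / 180)
    profile <- function(x, y) {
        sd <- signedDistToPolygon(x, y, poly)
        spec$floorZ + pmax(0, sd) / tanS
    }
    prof <- profile(v[, 1L], v[, 2L])
    inside <- pointInPolygon(v[, 1L], v[, 2L], poly)
    if (any(inside) && max(v[inside, 3L]) <= spec$floorZ)
        stop("cavity floor lies above the occlusal surface")
    vnew <- v
    vnew[, 3L] <- pmin(v[, 3L], prof)
    normals <- computeVertexNormals(vnew, mesh@faces)
    md <- mesh@metadata
    md$prepSpec <- spec
    hf <- md$heightfield
    if (!is.null(hf)) {
        md$heightfield <- function(x, y) pmin(hf(x, y), profile(x, y))
        md$removedFn <- function(x, y) {
            z0 <- hf(x, y)
            !is.na(z0) & (z0 - profile(x, y) > 1e-9)
        }
        md$removalDepthFn <- function(x, y) {
            z0 <- hf(x, y)
            d <- z0 - profile(x, y)
            d[is.na(d) | d < 0] <- 0
            d
        }
    }
    list(mesh = new("ToothMesh", vertices = vnew, faces = mesh@faces,
                    normals = normals, metadata = md),
         region = poly)
}

#' Generate a population of synthetic molars
#'
#' Draws \code{n} teeth with shape parameters jittered around
#' \code{baseParams}: footprint radii within +/-8 percent, cusp positions
#' within 0.25 mm, cusp heights and fossa depth within +/-15 percent, and
#' an independent noise field per tooth. Deterministic per seed.
#'
#' @param n number of teeth.
#' @param baseParams center of the population.
#' @param seed master seed; per-tooth seeds are derived from it.
#' @return list of \linkS4class{ToothMesh}.
#' @export
generateToothDataset <- function(n, baseParams = toothShapeParams(),
                                 seed = 1L) {
    stopifnot(n >= 1)
    lapply(seq_len(n), function(i) {
        si <- (as.integer(seed) + 7919L * i) %% 2147483647L
        p <- withSeed(si, {
            p <- baseParams
            p$footprintRadii <- p$footprintRadii * stats::runif(2L, 0.92, 1.08)
            p$cuspCenters <- p$cuspCenters +
                matrix(stats::rnorm(length(p$cuspCenters), 0, 0.25),
                       ncol = 2L)
            p$cuspHeights <- p$cuspHeights *
                stats::runif(length(p$cuspHeights), 0.85, 1.15)
            p$fossaDepth <- p$fossaDepth * stats::runif(1L, 0.85, 1.15)
            p
        })
        generateToothMesh(p, seed = si)
    })
}
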