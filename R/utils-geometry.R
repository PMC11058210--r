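## Internal geometry helpers shared across modules.

## Evaluate an expression with a temporary RNG seed, restoring the caller's
## stream afterwards so generators are pure functions of (params, seed).
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Rotation about the z axis (degrees), 3x3.
rotZ <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

rotX <- function(deg) {
    a <- deg * pi / 180
    matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
}

rotY <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
}

## Uniform random proper rotation (QR of a Gaussian matrix, det forced +1).
randomRotation <- function() {
    q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L, 3L)))
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    q
}

isRotationMatrix <- function(R, tol = 1e-8) {
    is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
        max(abs(crossprod(R) - diag(3L))) < tol && abs(det(R) - 1) < tol
}

vnorm <- function(v) sqrt(sum(v^2))

normalizeRows <- function(m) {
    n <- sqrt(rowSums(m^2))
    n[n == 0] <- 1
    m / n
}

## Even-odd point-in-polygon test, vectorised over query points.
## poly: k x 2 matrix of vertices (open ring).
pointInPolygon <- function(px, py, poly) {
    n <- nrow(poly)
    inside <- logical(length(px))
    j <- n
    for (i in seq_len(n)) {
        xi <- poly[i, 1L]; yi <- poly[i, 2L]
        xj <- poly[j, 1L]; yj <- poly[j, 2L]
        crosses <- ((yi > py) != (yj > py)) &
            (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- xor(inside, crosses)
        j <- i
    }
    inside
}

## Unsigned distance from points to a polygon boundary (closed ring implied).
distToPolygonBoundary <- function(px, py, poly) {
    n <- nrow(poly)
    d2 <- rep(Inf, length(px))
    j <- n
    for (i in seq_len(n)) {
        ax <- poly[j, 1L]; ay <- poly[j, 2L]
        bx <- poly[i, 1L]; by <- poly[i, 2L]
        vx <- bx - ax; vy <- by - ay
        L2 <- vx * vx + vy * vy
        t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
        dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
        d2 <- pmin(d2, dx * dx + dy * dy)
        j <- i
    }
    sqrt(d2)
}

## Signed distance to polygon boundary: negative inside, positive outside.
signedDistToPolygon <- function(px, py, poly) {
    d <- distToPolygonBoundary(px, py, poly)
    ifelse(pointInPolygon(px, py, poly), -d, d)
}

polygonArea <- function(poly) {
    x <- poly[, 1L]; y <- poly[, 2L]
    abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

## Minimum-area bounding rectangle of 2D points via rotating calipers over
## convex-hull edges. Returns angle (degrees, edge direction of the optimal
## rectangle), center, half-extents, and area.
minAreaRect <- function(xy) {
    xy <- xy[stats::complete.cases(xy), , drop = FALSE]
    h <- grDevices::chull(xy)
    hull <- xy[h, , drop = FALSE]
    nh <- nrow(hull)
    if (nh < 2L)
        return(list(angleDeg = 0, center = colMeans(xy),
                    halfExtents = c(0, 0), area = 0))
    best <- NULL
    for (i in seq_len(nh)) {
        j <- if (i == nh) 1L else i + 1L
        e <- hull[j, ] - hull[i, ]
        L <- vnorm(e)
        if (L == 0) next
        u <- e / L                        # edge direction
        v <- c(-u[2L], u[1L])             # perpendicular
        pu <- hull %*% u
        pv <- hull %*% v
        du <- max(pu) - min(pu)
        dv <- max(pv) - min(pv)
        area <- du * dv
        if (is.null(best) || area < best$area - 1e-12) {
            cu <- (max(pu) + min(pu)) / 2
            cv <- (max(pv) + min(pv)) / 2
            best <- list(angleDeg = atan2(u[2L], u[1L]) * 180 / pi,
                         center = as.numeric(cu * u + cv * v),
                         halfExtents = c(du, dv) / 2, area = area)
        }
    }
    ## canonical angle in [-45, 45): rectangle symmetry is 90 degrees
    a <- best$angleDeg %% 90
    if (a >= 45) a <- a - 90
    he <- best$halfExtents
    ## if the 90-degree reduction swapped the axes, swap extents accordingly
    if (abs(((best$angleDeg - a) / 90) %% 2 - 1) < 1e-9) he <- rev(he)
    best$angleDeg <- a
    best$halfExtents <- he
    best
}

## Canonical in-plane angle of a 2D point set: minimum-area rectangle
## angle, with the 90-degree ambiguity resolved (when a buccal direction
## is given) so the buccal side maps to -y. Points rotate as
## xy %*% rotZ(angleDeg)[1:2, 1:2].
inplaneCanonicalAngle <- function(xy, buccal2 = NULL) {
    rect <- minAreaRect(xy)
    ang <- rect$angleDeg
    if (!is.null(buccal2)) {
        best <- NULL
        for (k in 0:3) {
            aa <- (-ang + 90 * k) * pi / 180
            by <- sin(aa) * buccal2[1L] + cos(aa) * buccal2[2L]
            if (is.null(best) || by < best$by) best <- list(k = k, by = by)
        }
        ang <- ang - 90 * best$k
    }
    list(angleDeg = ang, center = rect$center)
}

## Bilinear resampling of a matrix image under an inverse-mapped rigid
## transform: output pixel (r,c) takes its value from input position
## rotated by -angleDeg about `center` then shifted by -shift (rows, cols).
## Out-of-domain samples are 0 (image background convention).
affineResampleImage <- function(m, angleDeg, shift = c(0, 0),
                                center = (dim(m) + 1) / 2) {
    h <- nrow(m); w <- ncol(m)
    a <- angleDeg * pi / 180
    ca <- cos(a); sa <- sin(a)
    rc <- matrix(rep(seq_len(h), w), h, w)
    cc <- matrix(rep(seq_len(w), each = h), h, w)
    ## position in source image for each destination pixel
    r0 <- rc - shift[1L] - center[1L]
    c0 <- cc - shift[2L] - center[2L]
    rs <- ca * r0 - sa * c0 + center[1L]
    cs <- sa * r0 + ca * c0 + center[2L]
    rf <- floor(rs); cf <- floor(cs)
    fr <- rs - rf; fc <- cs - cf
    val <- function(ri, ci) {
        ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
        out <- numeric(length(ri))
        out[ok] <- m[cbind(ri[ok], ci[ok])]
        out
    }
    v <- (1 - fr) * (1 - fc) * val(rf, cf) +
        (1 - fr) * fc * val(rf, cf + 1) +
        fr * (1 - fc) * val(rf + 1, cf) +
        fr * fc * val(rf + 1, cf + 1)
    matrix(v, h, w)
}
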