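## Ground-truth oracle for mask-extraction checks: carves a preparation
## into a synthetic tooth, runs the mask pipeline, rasterizes the
## analytic removed region on the same pixel grid under the two
## admissible discretizations (inner bracket: pixel fully removed and
## deeper than the 0.2 mm detection floor declared by the z threshold;
## outer bracket: removal touches the pixel), and measures the edge
## agreement of the extracted mask in pixels (0 when the extracted edge
## lies within the one-pixel band around the true edge; the boundary
## section following the tooth's outer silhouette is excluded, as there
## the mask edge is the silhouette itself).

maskOracle <- function(tooth, params, prepType, cfg, seed = 3L) {
    spec <- preparationSpec(prepType, params)
    cv <- carvePreparation(tooth, spec)
    zT <- spec$floorZ + (cfg@zNorm - max(vertices(cv$mesh)[, 3L])) + 0.2
    mx <- extractPreparationMask(cv$mesh, cfg, maskThresholds(0.3, zT),
                                 seed = seed)
    pr <- projectTooth(cv$mesh, cfg, seed = seed, returnCloud = TRUE,
                       normalMode = "face")
    w <- cfg@resolution
    pix <- cfg@planeSize / w
    cols <- matrix(rep(seq_len(w), each = w), w)
    rows <- matrix(rep(seq_len(w), w), w)
    xi <- (cols - 0.5) * pix - cfg@planeSize / 2
    yi <- cfg@planeSize / 2 - (rows - 0.5) * pix
    aa <- -pr$pose$angleDeg * pi / 180
    Rot <- matrix(c(cos(aa), sin(aa), -sin(aa), cos(aa)), 2L, 2L)
    evalAt <- function(dx, dy, fn) {
        p <- sweep(cbind(as.vector(xi) + dx * pix,
                         as.vector(yi) + dy * pix) %*% Rot, 2L,
                   pr$pose$center, "+")
        matrix(fn(p[, 1L], p[, 2L]), w, w)
    }
    fg <- pixels(mx$map) > 0
    fgF <- matrix(as.numeric(EBImage::fillHull(
        matrix(as.numeric(fg), w))), w) > 0.5
    center <- evalAt(0, 0, cv$mesh@metadata$removedFn)
    inner <- center & (evalAt(0, 0, cv$mesh@metadata$removalDepthFn) > 0.25)
    outer <- center
    for (dx in c(-0.5, 0.5)) for (dy in c(-0.5, 0.5)) {
        rm <- evalAt(dx, dy, cv$mesh@metadata$removedFn)
        dp <- evalAt(dx, dy, cv$mesh@metadata$removalDepthFn)
        inner <- inner & rm & (dp > 0.25)
        outer <- outer | rm
    }
    inner <- inner & center & fgF
    outer <- outer & fgF
    black <- maskMatrix(mx$mask) == 0

    dil1 <- function(x)
        matrix(as.numeric(EBImage::dilate(matrix(as.numeric(x), w),
                                          EBImage::makeBrush(3L, "box"))),
               w) > 0.5
    dbg <- matrix(as.numeric(EBImage::distmap(
        matrix(as.numeric(fgF), w))), w)
    interior <- dbg >= 3
    distToRegion <- function(pts, region) {
        if (nrow(pts) == 0L) return(0)
        prg <- which(region, arr.ind = TRUE)
        mx2 <- 0
        for (i in seq_len(nrow(pts))) {
            d <- pmax(abs(prg[, 1L] - pts[i, 1L]),
                      abs(prg[, 2L] - pts[i, 2L]))
            mx2 <- max(mx2, min(d))
        }
        mx2
    }
    over <- which(black & !dil1(outer) & interior, arr.ind = TRUE)
    under <- which(inner & !dil1(black) & interior, arr.ind = TRUE)
    agree <- max(distToRegion(over, outer), distToRegion(under, black))

    list(mask = mx$mask, boundary = mx$boundary, map = pixels(mx$map),
         edgeAgreementPx = agree,
         removedFraction = sum(black) / sum(fg))
}
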