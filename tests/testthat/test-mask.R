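test_that("the normal/height heuristic strips walls and floor exactly", {
    pr <- fxPreparation("a")
    cfg <- fxConfig()
    cloud <- projectTooth(pr$carved$mesh, cfg, seed = 3L, returnCloud = TRUE,
                          normalMode = "face")$cloud
    kept <- extractRetainedPoints(cloud, maskThresholds(0.3, pr$zT))
    ## no near-vertical (wall) normals survive
    expect_true(all(kept@normals[, 3L] > 0.3))
    ## nothing at or below the floor threshold survives
    expect_true(all(kept@points[, 3L] > pr$zT))
    ## an unprepared tooth yields a mask with no removed pixels inside
    ## the silhouette
    mx <- extractPreparationMask(fxNormalized()$mesh, cfg,
                                 maskThresholds(0.3, 0.5), seed = 4L)
    expect_equal(sum(maskMatrix(mx$mask) == 0 & pixels(mx$map) > 0), 0L)
    expect_error(extractRetainedPoints(cloud, maskThresholds(0.999, 100)),
                 "no points")
})

test_that("binarization maps exactly the nonzero support", {
    cfg <- projectionConfig(resolution = 16L)
    z <- new("DepthMap", pixels = matrix(0, 16, 16), config = cfg,
             provenance = "t")
    expect_true(all(maskMatrix(binarizeDepthMap(z)) == 0))
    px <- matrix(0, 16, 16); px[c(3, 17, 200)] <- c(1, 100.5, 255)
    d <- new("DepthMap", pixels = px, config = cfg, provenance = "t")
    b <- binarizeDepthMap(d)
    expect_equal(sum(maskMatrix(b) == 1), 3L)
    ## idempotence under rescaling
    d2 <- new("DepthMap", pixels = 255 * maskMatrix(b), config = cfg,
              provenance = "t")
    expect_identical(maskMatrix(binarizeDepthMap(d2)), maskMatrix(b))
})

test_that("mask finalization removes speckles, fills holes, and is idempotent", {
    fg <- matrix(FALSE, 64, 64); fg[10:55, 10:55] <- TRUE
    m <- matrix(1, 64, 64)
    m[20:40, 20:40] <- 0                 # preparation region
    m[30:31, 30:31] <- 1                 # small hole inside it
    m[50, 50] <- 0                       # isolated speckle
    m[12, c(12, 13, 14)] <- 0            # another small speckle
    raw <- new("BinaryMask", mask = m, source = "extracted")
    fin <- finalizeMask(raw, foreground = fg)
    expect_true(all(maskMatrix(fin)[30:31, 30:31] == 0))   # hole filled
    expect_equal(maskMatrix(fin)[50, 50], 1)               # speckle gone
    expect_equal(maskMatrix(fin)[12, 12], 1)
    expect_true(all(maskMatrix(fin)[20:40, 20:40] == 0))
    expect_true(all(maskMatrix(fin)[!fg] == 1))            # white background
    fin2 <- finalizeMask(fin, foreground = fg)
    expect_identical(maskMatrix(fin2), maskMatrix(fin))
    ## artifact-free raw mask: only the background gets whitened
    clean <- matrix(1, 64, 64); clean[!fg] <- 0; clean[25:35, 25:35] <- 0
    fc <- finalizeMask(new("BinaryMask", mask = clean, source = "extracted"),
                       foreground = fg)
    expect_true(all(maskMatrix(fc)[25:35, 25:35] == 0))
    expect_true(all(maskMatrix(fc)[!fg] == 1))
})

test_that("boundary rings hug the removed region", {
    m <- matrix(1, 32, 32); m[16, 16] <- 0
    M <- new("BinaryMask", mask = m, source = "synthetic")
    ring <- boundaryMask(M, 1L)
    sel <- which(maskMatrix(ring) == 1, arr.ind = TRUE)
    expect_equal(nrow(sel), 8L)
    expect_true(all(abs(sel[, 1L] - 16) <= 1 & abs(sel[, 2L] - 16) <= 1))
    ## ring and removed region are disjoint; ring lies in the retained set
    expect_true(all(m[maskMatrix(ring) == 1] == 1))
    ## disk: ring size close to perimeter * width (brute-force oracle)
    rr <- 8
    rows <- matrix(rep(1:64, 64), 64); cols <- t(rows)
    disk <- sqrt((rows - 32)^2 + (cols - 32)^2) <= rr
    M2 <- new("BinaryMask", mask = 1 - disk * 1, source = "synthetic")
    ring2 <- boundaryMask(M2, 1L)
    dil <- matrix(as.numeric(EBImage::dilate(matrix(as.numeric(disk), 64),
                                             EBImage::makeBrush(3L, "box"))),
                  64) > 0.5
    oracle <- dil & !disk
    expect_true(all((maskMatrix(ring2) == 1) == oracle))
    expect_lt(abs(sum(oracle) - 2 * pi * rr * 1) / (2 * pi * rr), 0.5)
    expect_error(boundaryMask(new("BinaryMask", mask = matrix(1, 8, 8),
                                  source = "synthetic")), "no removed")
})

test_that("circle masks hit the requested area and stay interior", {
    d <- fxMap()
    fg <- pixels(d) > 0
    for (fr in c(0.1, 0.3, 0.5)) {
        M <- circleMask(d, fr)
        got <- sum(maskMatrix(M) == 0) / sum(fg)
        expect_lt(abs(got - fr), 0.01)
        ## strictly inside the silhouette: dilated black stays in fg
        blk <- maskMatrix(M) == 0
        dil <- EBImage::dilate(matrix(as.numeric(blk), nrow(blk)),
                               EBImage::makeBrush(3L, "box")) > 0.5
        expect_true(all(fg[dil]))
    }
    expect_true(all(maskMatrix(circleMask(d, 0)) == 1))
    expect_error(circleMask(d, 0.95), "infeasible|touch")
})

test_that("contour-cutting masks remove equal areas but touch the contour", {
    d <- fxMap()
    fg <- pixels(d) > 0
    Mc <- circleMask(d, 0.3)
    Mb <- boundaryCutMask(d, 0.3, side = "top")
    nc <- sum(maskMatrix(Mc) == 0); nb <- sum(maskMatrix(Mb) == 0)
    expect_lt(abs(nb - nc) / nc, 0.01)
    ## black region touches the silhouette boundary
    blk <- maskMatrix(Mb) == 0
    er <- EBImage::erode(matrix(as.numeric(fg), nrow(fg)),
                         EBImage::makeBrush(3L, "box")) > 0.5
    contour <- fg & !er
    expect_gt(sum(blk & contour), 0)
    ## intersection happens in the requested half
    hit <- which(blk & contour, arr.ind = TRUE)
    expect_true(all(hit[, 1L] <= nrow(blk) / 2))
    expect_equal(sum(maskMatrix(circleMask(d, 0.3)) == 0 & !fg), 0L)
})

test_that("extracted masks reproduce the carved region boundary to one pixel", {
    for (ty in c("a", "d")) {
        pr <- fxPreparation(ty)
        black <- maskMatrix(pr$mask$mask) == 0
        expect_lte(maskEdgeAgreementPx(black, pr$truthStrict, pr$truthOuter,
                                       pr$fg), 1)
        jac <- sum(black & pr$truth) / sum(black | pr$truth)
        expect_gt(jac, 0.95)
        ## the boundary ring is retained-territory only
        ring <- maskMatrix(pr$mask$boundary) == 1
        expect_true(all(maskMatrix(pr$mask$mask)[ring] == 1))
    }
})
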