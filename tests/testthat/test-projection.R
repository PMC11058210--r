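test_that("z normalization pins the cloud top to the depth window", {
    set.seed(1)
    pts <- cbind(rnorm(50), rnorm(50), runif(50, -3, 0))
    out <- normalizeZ(pts, 8)
    expect_equal(max(out[, 3L]), 8, tolerance = 1e-12)
    expect_identical(out[, 1:2], pts[, 1:2])
    ## already aligned -> unchanged
    expect_equal(normalizeZ(out, 8), out, tolerance = 1e-12)
    shifted <- pts; shifted[, 3L] <- shifted[, 3L] - max(shifted[, 3L])
    expect_equal(max(normalizeZ(shifted, 8)[, 3L]) - 8, 0, tolerance = 1e-12)
})

test_that("depth rasterization follows the linear top-surface rule", {
    cfg <- projectionConfig(resolution = 16L, planeSize = 4, zNorm = 8)
    ## single point at the window top -> 255
    d <- projectDepth(matrix(c(0.1, 0.1, 8), 1L), cfg, center = c(0, 0))
    expect_equal(max(pixels(d)), 255)
    expect_equal(sum(pixels(d) > 0), 1L)
    ## point below the window -> 0
    d0 <- projectDepth(matrix(c(0.1, 0.1, -1), 1L), cfg, center = c(0, 0))
    expect_true(all(pixels(d0) == 0))
    ## flat plate at half window: covered pixels at exactly 127.5
    g <- as.matrix(expand.grid(x = seq(-0.9, 0.9, by = 0.05),
                               y = seq(-0.9, 0.9, by = 0.05)))
    d <- projectDepth(cbind(g, 4), cfg, center = c(0, 0))
    covered <- pixels(d)[pixels(d) > 0]
    expect_true(all(abs(covered - 127.5) < 1e-9))
    expect_equal(length(covered), 64L)   # 1.8mm square at 0.25mm pixels
    ## out-of-plane points are an error
    expect_error(projectDepth(matrix(c(10, 0, 1), 1L), cfg, center = c(0, 0)),
                 "outside")
    ## non-power-of-two resolution refused (generator schedule gate)
    expect_error(projectionConfig(resolution = 100L), "power of two")
})

test_that("mm calibration round-trips and RMSE identities hold", {
    cfg <- projectionConfig()
    c1 <- calibration(cfg)
    expect_equal(c1, 4.5 / 255)
    a <- fxMap()
    expect_equal(projectionRmseMm(a, a)[["rmseMm"]], 0)
    ## one pixel off by 255 in a 128x128 image
    px <- pixels(a); px2 <- px
    i <- which(px == 0)[1L]
    px2[i] <- 255
    b <- new("DepthMap", pixels = px2, config = a@config, provenance = "t")
    expect_equal(projectionRmseMm(a, b)[["rmseMm"]], (255 / 128) * c1,
                 tolerance = 1e-12)
    ## uniform difference of 1 intensity unit -> exactly the calibration
    d1 <- new("DepthMap", pixels = matrix(10, 128, 128), config = a@config,
              provenance = "t")
    d2 <- new("DepthMap", pixels = matrix(11, 128, 128), config = a@config,
              provenance = "t")
    expect_equal(projectionRmseMm(d1, d2)[["rmseMm"]], c1, tolerance = 1e-12)
    ## background-inclusive = background-exclusive * sqrt(nonzero fraction)
    r <- projectionRmseMm(a, b)
    nz <- mean(pixels(a) > 0 | pixels(b) > 0)
    expect_equal(r[["rmseMm"]], r[["rmseMmNonzero"]] * sqrt(nz),
                 tolerance = 1e-12)
    ## symmetry
    expect_equal(projectionRmseMm(a, b), projectionRmseMm(b, a))
    bad <- new("DepthMap", pixels = px2,
               config = projectionConfig(zNorm = 6), provenance = "t")
    expect_error(projectionRmseMm(a, bad), "mismatch")
})

test_that("in-plane canonicalization centers and squares the silhouette", {
    d0 <- fxMap()
    can <- canonicalizeInplane(d0, buccalHint = c(0, 1))
    expect_lt(abs(can$pose$angleDeg), 0.5)
    expect_lte(max(abs(can$pose$translationPx)), 0.5)
    ## post-condition: the output's bounding rectangle sits on the image
    ## center, axis-parallel
    fgc <- which(pixels(can$map) > 0, arr.ind = TRUE)
    rc <- occlumap:::minAreaRect(cbind(fgc[, 2L], fgc[, 1L]))
    expect_lte(max(abs(rc$center - (128 + 1) / 2)), 0.5)
    expect_lt(abs(rc$angleDeg), 0.5)
    ## a 30-degree rotated copy canonicalizes back to the original
    ## (smooth crown: the comparison measures pose recovery, not
    ## interpolation of surface roughness)
    ps <- toothShapeParams(noiseAmp = 0)
    ds <- projectTooth(generateToothMesh(ps, 0L), fxConfig(), seed = 2L)
    rot <- occlumap:::affineResampleImage(pixels(ds), 30)
    dr <- new("DepthMap", pixels = pmin(pmax(rot, 0), 255),
              config = ds@config, provenance = "t")
    bk <- canonicalizeInplane(dr, buccalHint = c(sin(pi / 6), cos(pi / 6)))
    common <- pixels(ds) > 0 & pixels(bk$map) > 0
    expect_lt(mean(abs(pixels(ds) - pixels(bk$map))[common]), 2)
    ## 180-degree flip with flipped hint resolves identically
    r180 <- pixels(ds)[128:1, 128:1]
    d180 <- new("DepthMap", pixels = r180, config = ds@config,
                provenance = "t")
    c180 <- canonicalizeInplane(d180, buccalHint = c(0, -1))
    expect_lt(mean(abs(pixels(c180$map) -
                       pixels(canonicalizeInplane(ds, c(0, 1))$map))), 2)
    empty <- new("DepthMap", pixels = matrix(0, 128, 128),
                 config = d0@config, provenance = "t")
    expect_error(canonicalizeInplane(empty), "empty")
})

test_that("sampling is uniform, deterministic, and repeatability behaves", {
    sq <- new("ToothMesh",
              vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
              faces = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
              normals = matrix(rep(c(0, 0, 1), each = 4L), 4L),
              metadata = list())
    pc <- sampleSurface(sq, 1e5, seed = 1L)
    q <- table(pc@points[, 1L] > 0.5, pc@points[, 2L] > 0.5)
    expect_true(all(abs(q - 25000) < 3 * sqrt(1e5 * 0.25 * 0.75)))
    expect_error(sampleSurface(sq, 0), "positive")
    pc2 <- sampleSurface(sq, 1e5, seed = 1L)
    expect_identical(pc@points, pc2@points)
    ## same seed reused -> zero-width confidence interval
    cfg <- projectionConfig(nSample = 2e4)
    m1 <- projectTooth(fxNormalized()$mesh, cfg, seed = 7L)
    m2 <- projectTooth(fxNormalized()$mesh, cfg, seed = 7L)
    expect_identical(pixels(m1), pixels(m2))
    ci <- repeatabilityCi(fxNormalized()$mesh, cfg, nRep = 5L, seed = 2L)
    expect_lte(ci$low, ci$high)
    expect_gte(ci$low, 0)
})

test_that("back-projection inverts the depth map up to quantization", {
    cfg <- projectionConfig(resolution = 16L, planeSize = 4, zNorm = 8)
    px <- matrix(0, 16, 16)
    px[8:9, 8:9] <- 255
    d <- new("DepthMap", pixels = px, config = cfg, provenance = "t")
    mesh <- backproject(d)
    expect_equal(nrow(vertices(mesh)), 4L)
    expect_equal(nrow(faces(mesh)), 2L)
    expect_true(all(abs(vertices(mesh)[, 3L] - 8) < 1e-12))
    ## monotone ramp stays monotone in height
    ramp <- matrix(rep(1:16 * 10, each = 16), 16)
    dr <- new("DepthMap", pixels = pmin(ramp, 255), config = cfg,
              provenance = "t")
    mr <- backproject(dr)
    ord <- order(vertices(mr)[, 1L])
    expect_true(all(diff(vertices(mr)[ord, 3L][order(vertices(mr)[ord, 1L])])
                    >= -1e-12))
    expect_error(backproject(new("DepthMap", pixels = matrix(0, 16, 16),
                                 config = cfg, provenance = "t")), "zero")
    ## round trip on a real tooth map
    dq <- quantizeDepthMap(fxMap())
    bp <- backproject(dq)
    cl <- new("OrientedPointCloud", points = vertices(bp),
              normals = vertexNormals(bp))
    d2 <- projectDepth(normalizeZ(cl, fxConfig()@zNorm), fxConfig(),
                       center = c(0, 0))
    common <- pixels(dq) > 0 & pixels(d2) > 0
    expect_lt(mean(abs(pixels(dq) - pixels(d2))[common]), 1)
    rt <- sqrt(mean(((pixels(dq) - pixels(d2))[common])^2)) * calibration(dq)
    expect_lt(rt, 2 * calibration(dq))
})
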