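test_that("bounding box recovers canonical frames and beats the axis-aligned box", {
    cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
    bb <- fitBoundingBox(cube)
    expect_equal(sort(bb$extents), c(1, 1, 1), tolerance = 1e-9)
    expect_equal(abs(bb$rotation), diag(3L), tolerance = 1e-9)
    ## rotated cuboid: recovered frame equals the applied one up to the
    ## 24-element box symmetry group; containment exact
    set.seed(2)
    for (i in 1:5) {
        R <- randomRotationMatrix()
        box <- as.matrix(expand.grid(c(0, 3), c(0, 2), c(0, 1))) %*% t(R)
        bb <- fitBoundingBox(box)
        expect_equal(bb$volume, 6, tolerance = 1e-6)
        expect_equal(sort(bb$extents), c(1, 2, 3), tolerance = 1e-6)
        ## symmetry check: each recovered axis is (+/-) a cuboid axis
        align <- abs(crossprod(bb$rotation, R))
        expect_equal(sort(apply(align, 1L, max)), c(1, 1, 1),
                     tolerance = 1e-6)
        q <- sweep(box, 2L, bb$center) %*% bb$rotation
        expect_true(all(abs(q) <= rep(bb$extents / 2 + 1e-9, each = 8L)))
    }
    ## random clouds: volume never above the axis-aligned competitor
    for (i in 1:5) {
        pts <- matrix(rnorm(240), ncol = 3L) %*% diag(c(3, 1, 0.5)) %*%
            t(randomRotationMatrix())
        bb <- fitBoundingBox(pts)
        aabb <- prod(apply(pts, 2L, function(z) diff(range(z))))
        expect_lte(bb$volume, aabb + 1e-9)
        q <- sweep(pts, 2L, bb$center) %*% bb$rotation
        expect_true(all(abs(q) <= rep(bb$extents / 2 + 1e-9,
                                      each = nrow(q))))
    }
    expect_error(fitBoundingBox(cbind(rnorm(10), rnorm(10), 0)), "degenerate")
})

test_that("box derotation inverts a known rotation", {
    set.seed(3)
    pts <- matrix(rnorm(150), ncol = 3L)
    nrm <- pts / sqrt(rowSums(pts^2))
    cl <- new("OrientedPointCloud", points = pts, normals = nrm)
    same <- derotateByBox(cl, list(rotation = diag(3L)))
    expect_identical(same@points, pts)
    R <- randomRotationMatrix()
    rot <- new("OrientedPointCloud", points = pts %*% t(R),
               normals = nrm %*% t(R))
    ## derotating by R (columns = axes) maps p %*% R = R^-1 applied
    back <- derotateByBox(rot, list(rotation = R))
    expect_lt(max(abs(back@points - pts)), 1e-9)
})

test_that("occlusal subset selection is a monotone normal-z filter", {
    set.seed(4)
    n <- 500L
    disk <- cbind(runif(n, -1, 1), runif(n, -1, 1), 0)
    up <- matrix(rep(c(0, 0, 1), each = n), n)
    flat <- new("OrientedPointCloud", points = disk, normals = up)
    expect_equal(nrow(selectOcclusalSubset(flat, 0.99)@points), n)
    wallN <- matrix(rep(c(1, 0, 0), each = n), n)
    wall <- new("OrientedPointCloud", points = disk, normals = wallN)
    expect_error(selectOcclusalSubset(wall, 0.9), "empty")
    m <- fxTooth()
    cl <- new("OrientedPointCloud", points = vertices(m),
              normals = vertexNormals(m))
    s1 <- selectOcclusalSubset(cl, 0.1)
    s9 <- selectOcclusalSubset(cl, 0.9)
    expect_lt(nrow(s9@points), nrow(s1@points))
    key <- function(s) apply(s@points, 1L, paste, collapse = ",")
    expect_true(all(key(s9) %in% key(s1)))
})

test_that("PCA plane fit equals the total-least-squares plane", {
    set.seed(5)
    xy <- cbind(runif(200), runif(200))
    exact <- cbind(xy, 0.5 * xy[, 1L] - 0.25 * xy[, 2L] + 2)
    pl <- fitPlanePCA(exact)
    ref <- c(-0.5, 0.25, 1); ref <- ref / sqrt(sum(ref^2))
    expect_lt(max(abs(pl$normal - ref)), 1e-10)
    expect_lt(max(abs((exact %*% pl$normal) - sum(pl$normal * pl$mu))), 1e-10)
    flat <- cbind(xy, 0)
    expect_equal(fitPlanePCA(flat)$normal, c(0, 0, 1), tolerance = 1e-12)
    ## noisy cloud: within 0.5 degrees of the SVD oracle
    noisy <- exact + matrix(rnorm(600, 0, 0.01), ncol = 3L)
    pl2 <- fitPlanePCA(noisy)
    sv <- svd(sweep(noisy, 2L, colMeans(noisy)))
    vref <- sv$v[, 3L]; if (vref[3L] < 0) vref <- -vref
    ang <- acos(min(1, abs(sum(pl2$normal * vref)))) * 180 / pi
    expect_lt(ang, 0.5)
    expect_lt(acos(min(1, abs(sum(pl2$normal * ref)))) * 180 / pi, 0.5)
    expect_error(fitPlanePCA(cbind(1:9, 2 * (1:9), 3 * (1:9))), "collinear")
})

test_that("plane rotation levels the fitted plane and keeps z-rotation fixed", {
    RP <- planeRotation(list(normal = c(0, 0, 1)))
    expect_equal(RP, diag(3L), tolerance = 1e-12, ignore_attr = TRUE)
    ## plane z = x
    RP <- planeRotation(list(normal = c(-1, 0, 1) / sqrt(2)))
    expect_equal(RP[, 1L], c(1, 0, 1) / sqrt(2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(RP[, 2L], c(0, 1, 0), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(RP[, 3L], c(-1, 0, 1) / sqrt(2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    set.seed(6)
    for (i in 1:5) {
        n <- rnorm(3); n[3L] <- abs(n[3L]) + 0.5; n <- n / sqrt(sum(n^2))
        RP <- planeRotation(list(normal = n))
        expect_lt(max(abs(crossprod(RP) - diag(3L))), 1e-8)
        expect_lt(max(abs(crossprod(RP, n) - c(0, 0, 1))), 1e-8)
    }
    expect_error(planeRotation(list(normal = c(1, 0, 0))), "vertical")
})

test_that("orientation normalization is idempotent and levels tilted teeth", {
    n0 <- fxNormalized()
    n2 <- normalizeOrientation(n0$mesh)
    ang <- acos(pmin(1, (sum(diag(n2$rotation)) - 1) / 2)) * 180 / pi
    expect_lt(ang, 0.2)
    expect_lt(sqrt(mean((vertices(n2$mesh) - vertices(n0$mesh))^2)), 1e-3)
    ## 15-degree tilt comes out horizontal
    tilt <- applyRigidTransform(fxTooth(), occlumap:::rotX(15))
    nt <- normalizeOrientation(tilt)
    cl <- new("OrientedPointCloud", points = vertices(nt$mesh),
              normals = vertexNormals(nt$mesh))
    pl <- fitPlanePCA(selectOcclusalSubset(cl, 0.9))
    expect_lt(acos(min(1, pl$normal[3L])) * 180 / pi, 0.1)
})

test_that("normalization and projection are invariant to rigid transforms", {
    cfg <- fxConfig()
    d0 <- projectTooth(fxNormalized()$mesh, cfg, seed = 1L)
    set.seed(11)
    for (i in 1:2) {
        mt <- applyRigidTransform(fxTooth(), randomRotationMatrix(),
                                  rnorm(3, 0, 4))
        nt <- normalizeOrientation(mt)
        dt <- projectTooth(nt$mesh, cfg, seed = 1L)
        expect_lt(projectionRmseMm(d0, dt)[["rmseMm"]], 0.02)
    }
})
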