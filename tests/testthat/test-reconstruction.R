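test_that("the corruption operator is an exact Hadamard product", {
    x <- matrix(runif(64, 0, 255), 8L)
    ones <- new("BinaryMask", mask = matrix(1, 8, 8), source = "synthetic")
    zeros <- new("BinaryMask", mask = matrix(0, 8, 8), source = "synthetic")
    expect_identical(corrupt(x, ones), x * 1)
    expect_true(all(corrupt(x, zeros) == 0))
    chk <- matrix(rep(c(1, 0), 32), 8L)
    out <- corrupt(x, chk)
    expect_identical(out, x * chk)            # elementwise oracle
    expect_equal(sum(out == 0), 32L)
    expect_error(corrupt(x, matrix(1, 4, 4)), "mismatch")
})

test_that("loss components match their closed forms", {
    n <- 16L
    x <- matrix(runif(n * n, 0, 255), n)
    M <- matrix(1, n, n); M[5:8, 5:8] <- 0
    ## pixel loss: zero at equality, masked-out differences invisible
    expect_equal(pixelLoss(x, x, M), 0)
    g <- x; g[6, 6] <- g[6, 6] + 100
    expect_equal(pixelLoss(x, g, M), 0)
    g2 <- x + 3 * M
    expect_equal(pixelLoss(x, g2, M), 9 * sum(M) / n^2, tolerance = 1e-12)
    ## boundary loss: single ring deviation d -> d^2 / ring size
    MB <- matrix(0, n, n); MB[4, 5:8] <- 1
    expect_equal(boundaryLoss(x, x, MB), 0)
    g3 <- x; g3[4, 6] <- g3[4, 6] - 5
    expect_equal(boundaryLoss(x, g3, MB), 25 / 4, tolerance = 1e-12)
    expect_error(boundaryLoss(x, x, matrix(0, n, n)), "empty")
    ## prior: unit perturbation of one entry -> 1 / (nRes * 512)
    mu <- matrix(0, 12, 512)
    w <- mu; w[3, 7] <- 1
    expect_equal(latentPriorLoss(w, mu), 1 / (12 * 512), tolerance = 1e-15)
    expect_equal(latentPriorLoss(3 * w, mu), 9 / (12 * 512),
                 tolerance = 1e-15)
    ## colinearity: identical rows 0, orthogonal 1, antiparallel 2
    wi <- matrix(rep(rnorm(512), each = 2L), 2L)
    expect_equal(colinearityLoss(wi), 0, tolerance = 1e-12)
    wo <- rbind(c(1, 0, rep(0, 510)), c(0, 1, rep(0, 510)))
    expect_equal(colinearityLoss(wo), 1)
    wa <- rbind(c(1, rep(0, 511)), c(-1, rep(0, 511)))
    expect_equal(colinearityLoss(wa), 2)
    expect_equal(colinearityLoss(matrix(1, 1, 512)), 0)
    ## perceptual: zero at equality, symmetric
    ext <- fxExtractor()
    xi <- pixels(fxMap())
    Mfull <- matrix(1, 128, 128)
    expect_equal(perceptualLoss(xi, xi, Mfull, ext), 0)
    gi <- xi + matrix(rnorm(128^2), 128)
    expect_equal(perceptualLoss(xi, gi, Mfull, ext),
                 perceptualLoss(gi, xi, Mfull, ext), tolerance = 1e-9)
})

test_that("the total objective composes its parts with the published weights", {
    G <- fxGenerator()
    ext <- fxExtractor()
    x <- pixels(fxMap())
    M <- circleMask(fxMap(), 0.3)
    MB <- boundaryMask(M, 1L, foreground = x > 0)
    set.seed(3)
    w <- matrix(rnorm(12 * 512, 0, 0.5), 12, 512)
    zero <- lossWeights(0, 0, 0, 0, 0)
    expect_equal(totalLoss(corrupt(x, M), w, G, M, MB, zero, ext), 0)
    onlyB <- lossWeights(0, 0, 0, 0, 4e-4)
    lb <- boundaryLoss(corrupt(x, M), generateImage(G, w), MB)
    expect_equal(totalLoss(corrupt(x, M), w, G, M, MB, onlyB, ext),
                 4e-4 * lb, tolerance = 1e-12)
    ## defaults are the printed operating point
    wts <- lossWeights()
    expect_equal(wts$lambdaW, -3.2)
    expect_equal(wts$lambdaColin, 8.6e-4)
    expect_equal(wts$lambdaPixel, 6.7e-4)
    expect_equal(wts$lambdaPercept, 9.2e3)
    expect_equal(wts$lambdaPixelB, 4.0e-4)
    expect_equal(lossWeights(flipPriorSign = TRUE)$lambdaW, 3.2)
})

test_that("every loss term's analytic gradient matches central differences", {
    G <- fxGenerator()
    ext <- fxExtractor()
    x <- pixels(fxMap())
    M <- circleMask(fxMap(), 0.3)
    MB <- boundaryMask(M, 1L, foreground = x > 0)
    xc <- corrupt(x, M)
    set.seed(6)
    w <- matrix(rnorm(12 * 512, 0, 0.5), 12, 512)
    terms <- list(pixel = lossWeights(0, 0, 6.7e-4, 0, 0),
                  percept = lossWeights(0, 0, 0, 9.2e3, 0),
                  prior = lossWeights(-3.2, 0, 0, 0, 0),
                  colin = lossWeights(0, 8.6e-4, 0, 0, 0),
                  boundary = lossWeights(0, 0, 0, 0, 4e-4))
    h <- 1e-3
    for (nm in names(terms)) {
        wt <- terms[[nm]]
        ev <- totalLossGrad(xc, w, G, M, MB, wt, ext)
        maxrel <- 0
        for (k in 1:6) {
            i <- sample(12, 1)
            j <- if (nm %in% c("prior", "colin")) sample(512, 1)
                 else sample(G@rank, 1)
            wp <- w; wp[i, j] <- w[i, j] + h
            wm <- w; wm[i, j] <- w[i, j] - h
            fd <- (totalLoss(xc, wp, G, M, MB, wt, ext) -
                   totalLoss(xc, wm, G, M, MB, wt, ext)) / (2 * h)
            rel <- abs(fd - ev$grad[i, j]) /
                max(abs(fd), abs(ev$grad[i, j]), 1e-10)
            maxrel <- max(maxrel, rel)
        }
        expect_lt(maxrel, 1e-4)
    }
})

test_that("merging selects corrupted and generated pixels exactly", {
    x <- matrix(runif(256, 0, 255), 16L)
    g <- matrix(runif(256, 0, 255), 16L)
    ones <- matrix(1, 16, 16); zeros <- matrix(0, 16, 16)
    xc <- x * ones
    expect_identical(mergeImages(xc, ones, g), xc)
    expect_identical(mergeImages(x * zeros, zeros, g), g)
    set.seed(12)
    M <- matrix(rbinom(256, 1, 0.5), 16L)
    xc <- x * M
    merged <- mergeImages(xc, M, g)
    oracle <- ifelse(M == 1, xc, g)       # brute-force elementwise
    expect_identical(merged, oracle)
    expect_error(mergeImages(xc, M * 0.5, g), "binary")
})

test_that("diminishing-returns detection finds the stagnation step", {
    flat <- rep(1, 200)
    expect_equal(diminishingReturns(flat), 50L)
    ## decay to a plateau: closed-form crossing step
    w <- 50L; tol <- 1e-3; A <- 1; C <- 0.5; r <- 0.05
    t <- 0:999
    trace <- A * exp(-r * t) + C
    lhs <- function(t) {
        a <- trace[t - w + 1L]
        (a - trace[t + 1L]) / a
    }
    pred <- which(vapply(seq.int(w, 999), lhs, numeric(1L)) < tol)[1L] +
        w - 1L
    expect_lt(abs(diminishingReturns(trace) - pred), 2)
    ## appending plateau steps never moves the detection earlier
    longer <- c(trace, rep(trace[1000L], 100))
    expect_gte(diminishingReturns(longer), diminishingReturns(trace))
    ## short trace returns its length
    expect_equal(diminishingReturns(c(3, 2, 1)), 3L)
})

test_that("optimization is deterministic and reduces the objective", {
    G <- fxGenerator()
    wTrue <- occlumap:::withSeed(101L, matrix(rnorm(12 * 512), 12, 512))
    xTrue <- generateImage(G, wTrue)
    dm <- new("DepthMap", pixels = xTrue, config = fxConfig(),
              provenance = "synthetic")
    M <- circleMask(dm, 0.3)
    MB <- boundaryMask(M, 1L, foreground = xTrue > 0)
    xc <- corrupt(xTrue, M)
    wts <- lossWeights(lambdaW = 0, lambdaColin = 0, lambdaPercept = 0,
                       lambdaPixelB = 0)
    opt <- optimizerConfig(nR = 150L, nRestarts = 2L, seed = 3L)
    r1 <- optimizeLatent(xc, M, MB, G, wts, opt)
    r2 <- optimizeLatent(xc, M, MB, G, wts, opt)
    expect_identical(r1@traces, r2@traces)
    expect_identical(r1@w, r2@w)
    tr <- r1@traces[[r1@chosenRestart]]
    expect_lt(tr[length(tr)], tr[1L])
    expect_equal(r1@chosenRestart, which.min(r1@finalLosses))
    ## merge identity holds bit-exactly on the result
    expect_identical(r1@xMerge,
                     xc + abs(maskMatrix(M) - 1) * r1@xClean)
    ## merged image equals the preparation on the boundary ring exactly
    ring <- maskMatrix(MB) == 1
    expect_identical(r1@xMerge[ring], xc[ring])
})

test_that("pixel-only inversion reaches the normal-equations solution", {
    G <- fxGenerator()
    wTrue <- occlumap:::withSeed(101L, matrix(rnorm(12 * 512), 12, 512))
    xTrue <- generateImage(G, wTrue)
    dm <- new("DepthMap", pixels = xTrue, config = fxConfig(),
              provenance = "synthetic")
    wts <- lossWeights(lambdaW = 0, lambdaColin = 0, lambdaPercept = 0,
                       lambdaPixelB = 0)
    for (fr in c(0.3, 0.5)) {
        M <- circleMask(dm, fr)
        MB <- boundaryMask(M, 1L, foreground = xTrue > 0)
        xc <- corrupt(xTrue, M)
        res <- optimizeLatent(xc, M, MB, G, wts,
                              optimizerConfig(nR = 2000L, nRestarts = 2L,
                                              seed = 3L))
        mv <- as.vector(maskMatrix(M)) == 1
        A <- G@components[mv, ]
        b <- as.vector(xTrue - G@meanImage)[mv]
        cstar <- qr.solve(crossprod(A), crossprod(A, b))
        Lstar <- wts$lambdaPixel * sum((A %*% cstar - b)^2) / (128 * 128)
        tr <- res@traces[[res@chosenRestart]]
        gap <- abs(res@finalLosses[res@chosenRestart] - Lstar) /
            max(tr[1L] - Lstar, 1e-12)
        expect_lt(gap, 1e-3)
        ## masked region recovered below twice the quantization step
        err <- (res@xMerge - xTrue)[maskMatrix(M) == 0]
        expect_lt(sqrt(mean(err^2)) * calibration(dm), 2 * calibration(dm))
    }
})
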