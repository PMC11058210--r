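#' @include AllClasses.R generator.R
NULL

#' Loss weights of the reconstruction objective
#'
#' Defaults are the published operating point of the Bayesian latent
#' inversion with the boundary term: lambdaW = -3.2 (latent prior),
#' lambdaColin = 8.6e-4 (row colinearity), lambdaPixel = 6.7e-4 (masked
#' pixel term), lambdaPercept = 9.2e3 (masked perceptual term),
#' lambdaPixelB = 4.0e-4 (boundary-ring term). Each component below is
#' normalized per entry so the weights are scale-comparable. The negative
#' prior weight is honored as printed; \code{flipPriorSign = TRUE} negates
#' it for experimentation.
#'
#' @param lambdaW,lambdaColin,lambdaPixel,lambdaPercept,lambdaPixelB
#'   component weights.
#' @param flipPriorSign negate \code{lambdaW}.
#' @export
lossWeights <- function(lambdaW = -3.2, lambdaColin = 8.6e-4,
                        lambdaPixel = 6.7e-4, lambdaPercept = 9.2e3,
                        lambdaPixelB = 4.0e-4, flipPriorSign = FALSE) {
    if (flipPriorSign) lambdaW <- -lambdaW
    list(lambdaW = lambdaW, lambdaColin = lambdaColin,
         lambdaPixel = lambdaPixel, lambdaPercept = lambdaPercept,
         lambdaPixelB = lambdaPixelB)
}

#' Corruption operator
#'
#' Hadamard product of an image with a binary mask: retained pixels pass
#' through, removed pixels become 0.
#'
#' @param x numeric image matrix.
#' @param M \linkS4class{BinaryMask} (or a 0/1 matrix).
#' @export
corrupt <- function(x, M) {
    m <- if (is(M, "BinaryMask")) M@mask else M
    if (!all(dim(x) == dim(m))) stop("image/mask shape mismatch")
    x * m
}

#' Reconstruction loss components
#'
#' Masked pixel term, boundary-ring term, masked perceptual term, latent
#' prior and latent row-colinearity. Each is normalized by its own entry
#' count so the published weights are scale-comparable.
#'
#' @param x target image (the corrupted preparation map).
#' @param Gw generated image G(w).
#' @param M \linkS4class{BinaryMask} or 0/1 matrix.
#' @param MB \linkS4class{BoundaryMask} or 0/1 matrix of ring pixels.
#' @param w,mu latent matrix and prior mean.
#' @param extractor feature extractor from \code{\link{convBankExtractor}}.
#' @name loss-components
NULL

#' @rdname loss-components
#' @export
pixelLoss <- function(x, Gw, M) {
    m <- if (is(M, "BinaryMask")) M@mask else M
    if (!all(dim(x) == dim(Gw), dim(x) == dim(m))) stop("shape mismatch")
    sum((m * (x - Gw))^2) / length(x)
}

#' @rdname loss-components
#' @export
boundaryLoss <- function(x, Gw, MB) {
    mb <- if (is(MB, "BoundaryMask")) MB@mask else MB
    ring <- mb == 1
    if (!any(ring)) stop("empty boundary ring")
    sum((x[ring] - Gw[ring])^2) / sum(ring)
}

#' @rdname loss-components
#' @export
latentPriorLoss <- function(w, mu) {
    if (!all(dim(w) == dim(mu))) stop("latent shape mismatch")
    sum((w - mu)^2) / length(w)
}

#' @rdname loss-components
#' @export
colinearityLoss <- function(w) {
    n <- nrow(w)
    if (n < 2L) return(0)
    nrm <- sqrt(rowSums(w^2))
    wn <- w
    nz <- nrm > 0
    wn[nz, ] <- w[nz, , drop = FALSE] / nrm[nz]
    wn[!nz, ] <- 0                     # zero rows: cosine treated as 0
    cosmat <- tcrossprod(wn)
    up <- upper.tri(cosmat)
    mean(1 - cosmat[up])
}

## gradient of colinearityLoss wrt w
colinearityGrad <- function(w) {
    n <- nrow(w)
    g <- matrix(0, n, ncol(w))
    if (n < 2L) return(g)
    nrm <- sqrt(rowSums(w^2))
    npairs <- n * (n - 1) / 2
    for (i in seq_len(n)) {
        if (nrm[i] == 0) next
        for (j in seq_len(n)) {
            if (j == i || nrm[j] == 0) next
            cij <- sum(w[i, ] * w[j, ]) / (nrm[i] * nrm[j])
            ## d cos / d w_i
            dci <- w[j, ] / (nrm[i] * nrm[j]) - cij * w[i, ] / nrm[i]^2
            g[i, ] <- g[i, ] - dci / npairs
        }
    }
    g
}

#' Fixed random convolution-bank feature extractor
#'
#' Deterministic multi-scale feature extractor for the perceptual term:
#' a fixed-seed bank of random convolution kernels applied circularly in
#' the Fourier domain, average-pooled. Linear, so its adjoint is exact
#' and the perceptual gradient is analytic. A pretrained perceptual
#' network can be substituted through the same interface (a list with
#' \code{forward} and \code{adjoint} functions and \code{nFeat}).
#'
#' @param width image resolution.
#' @param nKernels number of kernels.
#' @param kernelSizes support of each kernel, recycled over kernels.
#' @param pool average-pooling factor.
#' @param seed kernel seed (fixed default so runs are reproducible).
#' @export
convBankExtractor <- function(width, nKernels = 4L,
                              kernelSizes = c(3L, 7L, 15L, 31L),
                              pool = 4L, seed = 42L) {
    sizes <- rep_len(kernelSizes, nKernels)
    kernFft <- withSeed(seed, lapply(sizes, function(s) {
        k <- matrix(stats::rnorm(s * s), s, s)
        k <- k / sqrt(sum(k^2))
        pad <- matrix(0, width, width)
        pad[seq_len(s), seq_len(s)] <- k
        stats::fft(pad)
    }))
    P <- matrix(0, width, width %/% pool)
    for (j in seq_len(ncol(P)))
        P[((j - 1) * pool + 1):(j * pool), j] <- 1
    nFeat <- nKernels * (width %/% pool)^2
    forward <- function(img) {
        fimg <- stats::fft(img)
        lapply(kernFft, function(K)
            crossprod(P, Re(stats::fft(fimg * K, inverse = TRUE)) /
                          length(img)) %*% P / pool^2)
    }
    adjoint <- function(feats) {
        acc <- matrix(0, width, width)
        for (k in seq_along(kernFft)) {
            up <- P %*% feats[[k]] %*% t(P) / pool^2
            acc <- acc + Re(stats::fft(stats::fft(up) * Conj(kernFft[[k]]),
                                       inverse = TRUE)) / (width * width)
        }
        acc
    }
    list(forward = forward, adjoint = adjoint, nFeat = nFeat, width = width)
}

#' @rdname loss-components
#' @export
perceptualLoss <- function(x, Gw, M, extractor) {
    m <- if (is(M, "BinaryMask")) M@mask else M
    fx <- extractor$forward(x * m)
    fg <- extractor$forward(Gw * m)
    sum(vapply(seq_along(fx), function(k) sum((fx[[k]] - fg[[k]])^2),
               numeric(1L))) / extractor$nFeat
}

#' Total reconstruction objective
#'
#' Weighted sum of the five components:
#' lambdaPixel * pixel + lambdaPercept * perceptual + lambdaW * prior +
#' lambdaColin * colinearity + lambdaPixelB * boundary.
#'
#' @inheritParams loss-components
#' @param G a \linkS4class{ToothGenerator}.
#' @param weights \code{\link{lossWeights}}.
#' @return scalar loss.
#' @export
totalLoss <- function(x, w, G, M, MB, weights, extractor) {
    totalLossGrad(x, w, G, M, MB, weights, extractor,
                  wantGrad = FALSE)$loss
}

#' Total loss with its analytic latent gradient
#'
#' @inheritParams totalLoss
#' @param wantGrad also compute the gradient.
#' @param precomp optional precomputed list (target features) from a
#'   previous call on the same \code{x} and \code{M}.
#' @return list with \code{loss}, \code{grad} (nRes x 512 or NULL),
#'   \code{parts} (named component values), \code{precomp}.
#' @export
totalLossGrad <- function(x, w, G, M, MB, weights, extractor,
                          wantGrad = TRUE, precomp = NULL) {
    m <- if (is(M, "BinaryMask")) M@mask else M
    mb <- if (is(MB, "BoundaryMask")) MB@mask else MB
    mu <- latentMean(G)
    Gw <- generateImage(G, w)
    N <- length(x)
    parts <- c(pixel = 0, percept = 0, prior = 0, colin = 0, boundary = 0)
    S <- matrix(0, nrow(x), ncol(x))       # image-space sensitivity

    diffM <- m * (x - Gw)
    parts["pixel"] <- sum(diffM^2) / N
    if (wantGrad && weights$lambdaPixel != 0)
        S <- S - weights$lambdaPixel * 2 * diffM * m / N

    if (weights$lambdaPercept != 0) {
        if (is.null(precomp))
            precomp <- list(fx = extractor$forward(x * m))
        fg <- extractor$forward(Gw * m)
        fdiff <- lapply(seq_along(fg), function(k) precomp$fx[[k]] - fg[[k]])
        parts["percept"] <- sum(vapply(fdiff, function(d) sum(d^2),
                                       numeric(1L))) / extractor$nFeat
        if (wantGrad)
            S <- S - weights$lambdaPercept * 2 *
                (extractor$adjoint(fdiff) * m) / extractor$nFeat
    }

    ring <- mb == 1
    ringN <- sum(ring)
    if (ringN > 0) {
        diffB <- x[ring] - Gw[ring]
        parts["boundary"] <- sum(diffB^2) / ringN
        if (wantGrad && weights$lambdaPixelB != 0) {
            SB <- matrix(0, nrow(x), ncol(x))
            SB[ring] <- -2 * diffB / ringN
            S <- S + weights$lambdaPixelB * SB
        }
    }

    parts["prior"] <- sum((w - mu)^2) / length(w)
    parts["colin"] <- colinearityLoss(w)

    loss <- weights$lambdaPixel * parts[["pixel"]] +
        weights$lambdaPercept * parts[["percept"]] +
        weights$lambdaW * parts[["prior"]] +
        weights$lambdaColin * parts[["colin"]] +
        weights$lambdaPixelB * parts[["boundary"]]

    grad <- NULL
    if (wantGrad) {
        grad <- generatorGradient(G, w, S)
        grad <- grad + weights$lambdaW * 2 * (w - mu) / length(w)
        if (weights$lambdaColin != 0)
            grad <- grad + weights$lambdaColin * colinearityGrad(w)
    }
    list(loss = unname(loss), grad = grad, parts = parts, precomp = precomp)
}
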