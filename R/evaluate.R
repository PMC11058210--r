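#' @include AllClasses.R reconstruct.R mask.R
NULL

#' Millimetre RMSE against ground truth
#'
#' Full-image RMSE (background included, the reporting convention used
#' throughout) scaled by the mm-per-intensity calibration.
#'
#' @param xMerge,xTrue image matrices or \linkS4class{DepthMap}s on the
#'   same calibration.
#' @param calibrationMm mm per intensity unit; required when matrices are
#'   passed.
#' @export
rmseVsTruth <- function(xMerge, xTrue, calibrationMm = NULL) {
    if (is(xMerge, "DepthMap") && is(xTrue, "DepthMap")) {
        if (abs(calibration(xMerge) - calibration(xTrue)) > 1e-12)
            stop("calibration mismatch")
        calibrationMm <- calibration(xMerge)
        xMerge <- xMerge@pixels; xTrue <- xTrue@pixels
    }
    if (is.null(calibrationMm)) stop("calibrationMm required")
    sqrt(mean((xMerge - xTrue)^2)) * calibrationMm
}

#' Error-distance distribution inside the removed region
#'
#' Absolute mm errors of the reconstruction at the removed (mask = 0)
#' pixels; values above the chosen percentile are dropped (extreme
#' distances carry no information about a continuous occlusal surface)
#' and the rest is binned into a normalized histogram.
#'
#' @param xMerge,xTrue image matrices.
#' @param M \linkS4class{BinaryMask}.
#' @param calibrationMm mm per intensity unit.
#' @param cutoff percentile in (0, 100]; default 95.
#' @param binWidthMm histogram bin width, mm.
#' @return list: \code{distancesMm} (retained values), \code{breaks},
#'   \code{ratios} (sum 1), \code{cutoffMm}.
#' @export
distanceDistribution <- function(xMerge, xTrue, M, calibrationMm,
                                 cutoff = 95, binWidthMm = 0.01) {
    stopifnot(cutoff > 0, cutoff <= 100)
    black <- (if (is(M, "BinaryMask")) M@mask else M) == 0
    if (!any(black)) stop("empty removed region")
    d <- abs(xMerge[black] - xTrue[black]) * calibrationMm
    cutMm <- stats::quantile(d, cutoff / 100, names = FALSE, type = 1L)
    keep <- d <= cutMm
    dk <- d[keep]
    breaks <- seq(0, max(dk, binWidthMm) + binWidthMm, by = binWidthMm)
    h <- graphics::hist(dk, breaks = breaks, plot = FALSE)
    list(distancesMm = dk, breaks = breaks,
         ratios = h$counts / length(dk), cutoffMm = cutMm)
}

#' Pixels exceeding an error-distance threshold
#'
#' The overlay set used to visualize reconstruction defects: all pixels
#' whose absolute error exceeds \code{thresholdMm} (0.1 mm default,
#' 0.2 mm secondary).
#'
#' @param xMerge,xTrue image matrices.
#' @param calibrationMm mm per intensity unit.
#' @param thresholdMm threshold, mm.
#' @return integer matrix of pixel indices (row, col).
#' @export
thresholdOverlay <- function(xMerge, xTrue, calibrationMm,
                             thresholdMm = 0.1) {
    which(abs(xMerge - xTrue) * calibrationMm > thresholdMm, arr.ind = TRUE)
}

#' Linear regression of reconstruction error on relative mask area
#'
#' Ordinary least squares of the per-fraction mean RMSE on the relative
#' masked area, with the coefficient of determination and the two-sided
#' p-value for zero slope.
#'
#' @param pairs data.frame with columns \code{area} and \code{rmseMm}
#'   (one row per tooth x mask).
#' @return list: \code{slope}, \code{intercept}, \code{r2}, \code{p},
#'   \code{means} (per-area mean table).
#' @export
areaRmseRegression <- function(pairs) {
    means <- stats::aggregate(rmseMm ~ area, data = pairs, FUN = mean)
    if (nrow(means) < 3L) stop("need at least 3 distinct areas")
    fit <- stats::lm(rmseMm ~ area, data = means)
    s <- summary(fit)
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r2 = s$r.squared,
         p = unname(s$coefficients[2L, 4L]),
         means = means)
}

#' Rising circle-mask reconstruction study
#'
#' For every tooth and area fraction: build the interior circle mask,
#' corrupt, reconstruct by latent inversion, merge, and record the
#' full-image mm RMSE against the uncorrupted map. Infeasible fractions
#' (circle would touch the contour) are skipped with a warning.
#'
#' @param maps list of ground-truth \linkS4class{DepthMap}s.
#' @param fractions area fractions to test.
#' @param G \linkS4class{ToothGenerator}.
#' @param weights \code{\link{lossWeights}}.
#' @param opt \code{\link{optimizerConfig}}; restart seeds derive from its
#'   seed, per tooth and fraction.
#' @param extractor perceptual extractor (defaults to the fixed bank).
#' @return data.frame: tooth, fraction, area (measured), rmseMm.
#' @export
risingMaskExperiment <- function(maps, fractions, G,
                                 weights = lossWeights(),
                                 opt = optimizerConfig(),
                                 extractor = convBankExtractor(outputWidth(G))) {
    out <- list()
    for (i in seq_along(maps)) {
        xTrue <- maps[[i]]@pixels
        fg <- xTrue > 0
        for (fr in fractions) {
            M <- tryCatch(circleMask(maps[[i]], fr), error = function(e) {
                warning(sprintf("tooth %d fraction %.2f skipped: %s",
                                i, fr, conditionMessage(e)))
                NULL
            })
            if (is.null(M)) next
            MB <- boundaryMask(M, 1L, foreground = fg)
            xc <- corrupt(xTrue, M)
            o <- opt
            o$seed <- opt$seed + 1000L * i + round(100 * fr)
            res <- optimizeLatent(xc, M, MB, G, weights, o, extractor)
            out[[length(out) + 1L]] <- data.frame(
                tooth = i, fraction = fr,
                area = relativeMaskArea(M, maps[[i]]),
                rmseMm = rmseVsTruth(res@xMerge, xTrue, calibration(maps[[i]])))
        }
    }
    do.call(rbind, out)
}

#' Interior versus contour-cutting mask comparison
#'
#' At a fixed removed fraction, reconstructs each tooth once under the
#' interior circle mask and once under the contour-cutting mask of equal
#' removed pixel count, and reports both mm RMSEs: interior masks retain
#' the contour information and should reconstruct better.
#'
#' @param maps list of ground-truth \linkS4class{DepthMap}s.
#' @param fraction removed fraction (default 0.3).
#' @param side contour side for the cutting mask.
#' @inheritParams risingMaskExperiment
#' @return data.frame: tooth, maskType, area, rmseMm.
#' @export
boundaryCutComparison <- function(maps, fraction = 0.3, G,
                                  weights = lossWeights(),
                                  opt = optimizerConfig(), side = "top",
                                  extractor = convBankExtractor(outputWidth(G))) {
    out <- list()
    for (i in seq_along(maps)) {
        xTrue <- maps[[i]]@pixels
        fg <- xTrue > 0
        for (type in c("circle", "cut")) {
            M <- if (type == "circle") circleMask(maps[[i]], fraction)
                 else boundaryCutMask(maps[[i]], fraction, side)
            MB <- boundaryMask(M, 1L, foreground = fg)
            xc <- corrupt(xTrue, M)
            o <- opt
            o$seed <- opt$seed + 1000L * i + (type == "cut") * 7L
            res <- optimizeLatent(xc, M, MB, G, weights, o, extractor)
            out[[length(out) + 1L]] <- data.frame(
                tooth = i, maskType = type,
                area = relativeMaskArea(M, maps[[i]]),
                rmseMm = rmseVsTruth(res@xMerge, xTrue,
                                     calibration(maps[[i]])))
        }
    }
    do.call(rbind, out)
}

#' Boundary Hausdorff distance between two binary regions
#'
#' Symmetric Hausdorff distance between the boundary pixel sets of two
#' regions, in pixels; used to verify mask edge coincidence. The
#' Chebyshev metric counts one diagonal step as distance 1 (8-neighbour
#' adjacency); Euclidean is also available.
#'
#' @param a,b logical matrices (regions).
#' @param metric "chebyshev" or "euclidean".
#' @export
boundaryHausdorffPx <- function(a, b, metric = c("chebyshev", "euclidean")) {
    metric <- match.arg(metric)
    bnd <- function(x) {
        er <- EBImage::erode(matrix(as.numeric(x), nrow(x)),
                             EBImage::makeBrush(3L, "box")) > 0.5
        x & !er
    }
    ba <- bnd(a); bb <- bnd(b)
    if (!any(ba) || !any(bb)) stop("empty boundary")
    distTo <- function(set) {
        z <- matrix(1, nrow(set), ncol(set))
        z[set] <- 0
        EBImage::distmap(z)
    }
    h <- max(max(distTo(bb)[ba]), max(distTo(ba)[bb]))
    if (metric == "euclidean") return(h)
    ## convert: recompute with Chebyshev distance transform via
    ## coordinate-wise max over the two boundary point sets
    pa <- which(ba, arr.ind = TRUE)
    pb <- which(bb, arr.ind = TRUE)
    cheb <- function(p, q) {
        ## directed Hausdorff under Chebyshev metric, vectorised over q
        mx <- 0
        for (i in seq_len(nrow(p))) {
            d <- pmax(abs(q[, 1L] - p[i, 1L]), abs(q[, 2L] - p[i, 2L]))
            mx <- max(mx, min(d))
        }
        mx
    }
    max(cheb(pa, pb), cheb(pb, pa))
}
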