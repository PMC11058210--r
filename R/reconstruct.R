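#' @include losses.R
NULL

#' Optimizer configuration for latent inversion
#'
#' Adam over the latent matrix with the published settings: step size
#' 0.05, beta1 0.9, beta2 0.999, up to nR = 2000 steps. Restart count and
#' initialization spread are implementation choices (several restarts,
#' per-row Gaussian around the latent mean).
#'
#' @param alpha Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param nR maximum optimization steps per restart.
#' @param nRestarts independent restarts; the restart with the minimal
#'   final loss is kept.
#' @param initSd standard deviation of the latent initialization around
#'   the prior mean.
#' @param seed master seed; restart r uses seed + r.
#' @export
optimizerConfig <- function(alpha = 0.05, beta1 = 0.9, beta2 = 0.999,
                            nR = 2000L, nRestarts = 10L, initSd = 1,
                            seed = 1L) {
    stopifnot(alpha > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
              nR >= 1, nRestarts >= 1)
    list(alpha = alpha, beta1 = beta1, beta2 = beta2, nR = as.integer(nR),
         nRestarts = as.integer(nRestarts), initSd = initSd,
         seed = as.integer(seed))
}

#' Latent inversion of a corrupted depth map
#'
#' Minimizes the total reconstruction objective over the latent matrix
#' with Adam, restarting \code{nRestarts} times from Gaussian draws
#' around the latent prior mean; the restart with the minimal final loss
#' is returned, together with the merged image (corrupted input outside
#' the mask, generated fill inside it) and the point of diminishing
#' returns of its loss trace. Deterministic for a fixed configuration
#' seed. A restart whose loss turns non-finite is aborted with a warning.
#'
#' @param xCor corrupted image (numeric matrix).
#' @param M \linkS4class{BinaryMask}.
#' @param MB \linkS4class{BoundaryMask}.
#' @param G \linkS4class{ToothGenerator}.
#' @param weights \code{\link{lossWeights}}.
#' @param opt \code{\link{optimizerConfig}}.
#' @param extractor feature extractor; default is the fixed
#'   \code{\link{convBankExtractor}} at the generator's resolution.
#' @return a \linkS4class{ReconstructionResult}.
#' @export
optimizeLatent <- function(xCor, M, MB, G, weights = lossWeights(),
                           opt = optimizerConfig(),
                           extractor = convBankExtractor(outputWidth(G))) {
    mu <- latentMean(G)
    best <- NULL
    traces <- vector("list", opt$nRestarts)
    finals <- rep(NA_real_, opt$nRestarts)
    precomp <- NULL
    for (r in seq_len(opt$nRestarts)) {
        w <- mu + withSeed(opt$seed + r,
                           matrix(stats::rnorm(length(mu), 0, opt$initSd),
                                  nrow(mu), ncol(mu)))
        mAdam <- matrix(0, nrow(mu), ncol(mu))
        vAdam <- matrix(0, nrow(mu), ncol(mu))
        trace <- numeric(opt$nR)
        ok <- TRUE
        for (t in seq_len(opt$nR)) {
            ev <- totalLossGrad(xCor, w, G, M, MB, weights, extractor,
                                precomp = precomp)
            precomp <- ev$precomp
            if (!is.finite(ev$loss)) {
                warning(sprintf("restart %d aborted at step %d: non-finite loss",
                                r, t))
                ok <- FALSE
                trace <- trace[seq_len(t - 1L)]
                break
            }
            trace[t] <- ev$loss
            g <- ev$grad
            mAdam <- opt$beta1 * mAdam + (1 - opt$beta1) * g
            vAdam <- opt$beta2 * vAdam + (1 - opt$beta2) * g^2
            mh <- mAdam / (1 - opt$beta1^t)
            vh <- vAdam / (1 - opt$beta2^t)
            w <- w - opt$alpha * mh / (sqrt(vh) + 1e-8)
        }
        traces[[r]] <- trace
        if (!ok || length(trace) == 0L) next
        finals[r] <- trace[length(trace)]
        if (is.null(best) || finals[r] < best$final)
            best <- list(w = w, final = finals[r], restart = r)
    }
    if (is.null(best)) stop("all restarts failed")
    xClean <- generateImage(G, best$w)
    mMat <- if (is(M, "BinaryMask")) M@mask else M
    xMerge <- mergeImages(xCor, M, xClean)
    new("ReconstructionResult", w = best$w, xClean = xClean, xCor = xCor,
        xMerge = xMerge, traces = traces, finalLosses = finals,
        chosenRestart = as.integer(best$restart),
        nDr = diminishingReturns(traces[[best$restart]]))
}

#' Merge the corrupted input with the generated fill
#'
#' The merged image keeps the corrupted input on retained (mask = 1)
#' pixels exactly and takes the generated clean image on removed
#' (mask = 0) pixels exactly: x_merge = x_cor + |M - 1| o x_clean.
#'
#' @param xCor corrupted image.
#' @param M \linkS4class{BinaryMask} (strictly binary).
#' @param xClean generated clean image.
#' @export
mergeImages <- function(xCor, M, xClean) {
    m <- if (is(M, "BinaryMask")) M@mask else M
    if (!all(m %in% c(0, 1))) stop("mask must be binary")
    if (!all(dim(xCor) == dim(m), dim(xClean) == dim(m)))
        stop("shape mismatch")
    xCor + abs(m - 1) * xClean
}

#' Point of diminishing returns of a loss trace
#'
#' First step at which the relative loss decrease over a trailing window
#' falls below \code{tol}; the trace length if stagnation never occurs.
#' The rule (window 50 steps, tolerance 1e-3) is a configurable
#' implementation definition.
#'
#' @param trace numeric loss trace.
#' @param window trailing window length, steps.
#' @param tol relative-decrease threshold.
#' @export
diminishingReturns <- function(trace, window = 50L, tol = 1e-3) {
    n <- length(trace)
    if (n < window) return(as.integer(n))
    for (t in seq.int(window, n)) {
        a <- trace[t - window + 1L]
        rel <- (a - trace[t]) / max(abs(a), 1e-12)
        if (rel < tol) return(as.integer(t))
    }
    as.integer(n)
}
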