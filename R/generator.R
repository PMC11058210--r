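#' @include AllClasses.R AllGenerics.R
NULL

#' Latent row count for a generator resolution
#'
#' A style-based generator at output width w (= height, a power of two)
#' takes one 512-vector per synthesis-network input, giving
#' nRes = 2 (log2(w) - 1) latent rows.
#'
#' @param width output resolution (power of two, >= 4).
#' @export
nRes <- function(width) {
    l <- log2(width)
    if (length(width) != 1L || width < 4 || abs(l - round(l)) > 1e-9)
        stop("width must be a power of two (>= 4)")
    as.integer(2 * (round(l) - 1))
}

#' Mirror augmentation of a depth-map dataset
#'
#' Appends the left-right mirror (about the vertical image axis) of every
#' map: occlusal anatomy is chirally asymmetric, so mirroring doubles the
#' training set without leaving the data manifold.
#'
#' @param maps list of \linkS4class{DepthMap}.
#' @return list of length 2n: originals followed by mirrors.
#' @export
mirrorAugment <- function(maps) {
    mirrored <- lapply(maps, function(d)
        new("DepthMap", pixels = d@pixels[, rev(seq_len(ncol(d@pixels)))],
            config = d@config, provenance = paste0(d@provenance, ";mirrored")))
    c(maps, mirrored)
}

#' Deterministic train/test split
#'
#' @param maps list of depth maps (or any list).
#' @param nTest held-out count (< length of the list).
#' @param seed split seed.
#' @return list with \code{train} and \code{test}.
#' @export
splitDataset <- function(maps, nTest, seed = 1L) {
    n <- length(maps)
    stopifnot(nTest >= 0, nTest < n)
    idx <- withSeed(seed, sample.int(n, nTest))
    list(train = maps[setdiff(seq_len(n), idx)],
         test = maps[if (nTest > 0) idx else integer(0)])
}

#' Fit the desk-scale linear generator
#'
#' Computes the mean training image and the top principal components of
#' the training depth maps; component columns are scaled by their
#' singular values (divided by sqrt(n)) so latent coefficients are O(1),
#' mirroring the unit-scale latent convention of style-based generators.
#' The generator evaluates clip(mean + B fold(w), 0, 255), where fold
#' averages the nRes latent rows and keeps the first \code{rank} entries;
#' the shared fold across rows lets the row-colinearity loss act exactly
#' as it does for a style-based generator's per-resolution inputs.
#'
#' @param train list of \linkS4class{DepthMap} (>= rank + 1).
#' @param rank number of components (<= 512).
#' @return a \linkS4class{LinearToothGenerator}.
#' @export
fitLinearGenerator <- function(train, rank = 16L) {
    stopifnot(length(train) >= rank + 1, rank >= 1L, rank <= 512L)
    w <- nrow(train[[1L]]@pixels)
    X <- vapply(train, function(d) as.vector(d@pixels), numeric(w * w))
    mu <- rowMeans(X)
    Xc <- X - mu
    sv <- svd(Xc, nu = rank, nv = 0L)
    if (sv$d[rank] < 1e-8)
        stop("requested rank exceeds the rank of the training data")
    B <- sv$u %*% diag(sv$d[seq_len(rank)] / sqrt(length(train)), rank, rank)
    new("LinearToothGenerator", meanImage = matrix(mu, w, w),
        components = B, width = as.integer(w), rank = as.integer(rank),
        latentMean = matrix(0, nRes(w), 512L))
}

## fold: average latent rows, keep the first `rank` entries
foldLatent <- function(G, w) {
    colMeans(w)[seq_len(G@rank)]
}

#' @rdname generator-contract
setMethod("generateImage", "LinearToothGenerator", function(G, w) {
    if (!is.matrix(w) || nrow(w) != nrow(G@latentMean) || ncol(w) != 512L)
        stop(sprintf("latent must be %d x 512", nrow(G@latentMean)))
    img <- G@meanImage + matrix(G@components %*% foldLatent(G, w),
                                G@width, G@width)
    img[img < 0] <- 0
    img[img > 255] <- 255
    img
})

#' @rdname generator-contract
setMethod("generatorGradient", "LinearToothGenerator",
    function(G, w, sensitivity) {
    if (!is.matrix(w) || nrow(w) != nrow(G@latentMean) || ncol(w) != 512L)
        stop(sprintf("latent must be %d x 512", nrow(G@latentMean)))
    raw <- G@meanImage + matrix(G@components %*% foldLatent(G, w),
                                G@width, G@width)
    active <- raw > 0 & raw < 255          # clip subgradient
    s <- as.vector(sensitivity * active)
    gcoef <- as.vector(crossprod(G@components, s))   # length rank
    nr <- nrow(w)
    grad <- matrix(0, nr, 512L)
    grad[, seq_len(G@rank)] <- matrix(rep(gcoef / nr, each = nr), nr)
    grad
})

#' @rdname generator-contract
setMethod("latentMean", "LinearToothGenerator", function(G) G@latentMean)

#' @rdname generator-contract
setMethod("outputWidth", "LinearToothGenerator", function(G) G@width)

#' Training configuration of the full-scale generator adapter
#'
#' The full-scale model is a style-based GAN trained offline on clinical
#' depth maps; it is not re-trained here. Its training configuration is
#' recorded verbatim for provenance and the adapter refuses silent
#' changes: Adam with alpha 0.002, beta1 0.0, beta2 0.99; minibatch 32;
#' augmentation disabled; path-length regularization weight 10 with decay
#' 0.99; training ends after 7e5 images shown; dataset split 89/3 with
#' mirror augmentation to 178 training images.
#'
#' @return named list of the recorded values.
#' @export
styleganTrainingConfig <- function() {
    list(alpha = 0.002, beta1 = 0.0, beta2 = 0.99, minibatch = 32L,
         augmentation = FALSE, gammaPl = 10, betaPl = 0.99,
         imagesShown = 7e5, split = c(train = 89L, test = 3L),
         mirroredTrainingImages = 178L)
}

#' Save or load a linear generator checkpoint
#'
#' Plain-text container (JSON header + base64-free CSV matrices) so
#' checkpoints are portable and diffable.
#'
#' @param G \linkS4class{LinearToothGenerator}.
#' @param dir checkpoint directory.
#' @name generator-io
NULL

#' @rdname generator-io
#' @export
writeGenerator <- function(G, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(width = G@width, rank = G@rank,
                              nRes = nrow(G@latentMean)),
                         file.path(dir, "generator.json"), auto_unbox = TRUE)
    utils::write.table(G@meanImage, file.path(dir, "mean.csv"),
                       row.names = FALSE, col.names = FALSE, sep = ",")
    utils::write.table(G@components, file.path(dir, "components.csv"),
                       row.names = FALSE, col.names = FALSE, sep = ",")
    invisible(dir)
}

#' @rdname generator-io
#' @export
readGenerator <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "generator.json"),
                                simplifyVector = TRUE)
    mu <- as.matrix(utils::read.table(file.path(dir, "mean.csv"), sep = ","))
    B <- as.matrix(utils::read.table(file.path(dir, "components.csv"),
                                     sep = ","))
    dimnames(mu) <- dimnames(B) <- NULL
    new("LinearToothGenerator", meanImage = mu, components = B,
        width = as.integer(meta$width), rank = as.integer(meta$rank),
        latentMean = matrix(0, meta$nRes, 512L))
}
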