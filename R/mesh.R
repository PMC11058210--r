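#' @include AllClasses.R
NULL

## Face normals (unnormalized: length = 2 * area) for a triangle mesh.
faceNormalsRaw <- function(vertices, faces) {
    v1 <- vertices[faces[, 1L], , drop = FALSE]
    e1 <- vertices[faces[, 2L], , drop = FALSE] - v1
    e2 <- vertices[faces[, 3L], , drop = FALSE] - v1
    cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
          e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
          e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Area-weighted vertex normals
#'
#' Each vertex normal is the normalized sum of the (area-scaled) normals
#' of its incident faces; mesh normals approximate the surface gradient
#' direction that the mask-extraction heuristic relies on.
#'
#' @param vertices n x 3 matrix.
#' @param faces m x 3 index matrix.
#' @export
computeVertexNormals <- function(vertices, faces) {
    fn <- faceNormalsRaw(vertices, faces)
    nv <- nrow(vertices)
    acc <- matrix(0, nv, 3L)
    idx <- c(faces[, 1L], faces[, 2L], faces[, 3L])
    for (d in 1:3) {
        s <- rowsum(rep(fn[, d], 3L), idx)
        acc[as.integer(rownames(s)), d] <- s[, 1L]
    }
    normalizeRows(acc)
}

#' Uniform surface sampling of a mesh
#'
#' Area-weighted uniform point samples with barycentrically interpolated
#' (then renormalized) vertex normals. Deterministic for a fixed seed.
#'
#' @param mesh \linkS4class{ToothMesh}.
#' @param nSample number of points (> 0).
#' @param seed integer seed.
#' @param normalMode "interpolated" (barycentric vertex normals; smooth,
#'   used for plane fitting) or "face" (constant triangle normal; sharp
#'   at surface-continuity breaks, used for preparation-mask extraction).
#' @return an \linkS4class{OrientedPointCloud}.
#' @export
sampleSurface <- function(mesh, nSample, seed = 0L,
                          normalMode = c("interpolated", "face")) {
    normalMode <- match.arg(normalMode)
    if (nSample < 1) stop("nSample must be positive")
    f <- mesh@faces
    if (nrow(f) == 0L) stop("empty mesh")
    fn <- faceNormalsRaw(mesh@vertices, f)
    areas <- sqrt(rowSums(fn^2)) / 2
    if (sum(areas) <= 0) stop("mesh has zero surface area")
    withSeed(seed, {
        fi <- sample.int(nrow(f), nSample, replace = TRUE, prob = areas)
        r1 <- sqrt(stats::runif(nSample))
        r2 <- stats::runif(nSample)
        b1 <- 1 - r1; b2 <- r1 * (1 - r2); b3 <- r1 * r2
        v1 <- mesh@vertices[f[fi, 1L], , drop = FALSE]
        v2 <- mesh@vertices[f[fi, 2L], , drop = FALSE]
        v3 <- mesh@vertices[f[fi, 3L], , drop = FALSE]
        pts <- b1 * v1 + b2 * v2 + b3 * v3
        nrm <- if (normalMode == "face") {
            normalizeRows(fn[fi, , drop = FALSE])
        } else {
            n1 <- mesh@normals[f[fi, 1L], , drop = FALSE]
            n2 <- mesh@normals[f[fi, 2L], , drop = FALSE]
            n3 <- mesh@normals[f[fi, 3L], , drop = FALSE]
            normalizeRows(b1 * n1 + b2 * n2 + b3 * n3)
        }
        new("OrientedPointCloud", points = pts, normals = nrm)
    })
}

#' Read and write tooth meshes
#'
#' ASCII STL, OBJ and Wavefront-style PLY are supported; units are assumed
#' to be millimetres (apply \code{scale} on read otherwise). The format is
#' chosen from the file extension.
#'
#' @param mesh \linkS4class{ToothMesh}.
#' @param path file path ending in .stl, .obj or .ply.
#' @param scale multiplicative unit conversion applied to vertices on read.
#' @name mesh-io
NULL

#' @rdname mesh-io
#' @export
writeMesh <- function(mesh, path) {
    ext <- tolower(tools::file_ext(path))
    v <- mesh@vertices; f <- mesh@faces
    con <- file(path, "w")
    on.exit(close(con))
    if (ext == "stl") {
        fn <- normalizeRows(faceNormalsRaw(v, f))
        writeLines("solid occlumap", con)
        for (i in seq_len(nrow(f))) {
            writeLines(sprintf("facet normal %g %g %g", fn[i, 1L], fn[i, 2L],
                               fn[i, 3L]), con)
            writeLines("  outer loop", con)
            for (k in 1:3) {
                p <- v[f[i, k], ]
                writeLines(sprintf("    vertex %g %g %g", p[1L], p[2L], p[3L]),
                           con)
            }
            writeLines(c("  endloop", "endfacet"), con)
        }
        writeLines("endsolid occlumap", con)
    } else if (ext == "obj") {
        writeLines(sprintf("v %g %g %g", v[, 1L], v[, 2L], v[, 3L]), con)
        writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
    } else if (ext == "ply") {
        writeLines(c("ply", "format ascii 1.0",
                     sprintf("element vertex %d", nrow(v)),
                     "property float x", "property float y", "property float z",
                     sprintf("element face %d", nrow(f)),
                     "property list uchar int vertex_indices", "end_header"),
                   con)
        writeLines(sprintf("%g %g %g", v[, 1L], v[, 2L], v[, 3L]), con)
        writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L,
                           f[, 3L] - 1L), con)
    } else stop("unsupported mesh format: ", ext)
    invisible(path)
}

#' @rdname mesh-io
#' @export
readMesh <- function(path, scale = 1) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "obj") {
        ln <- readLines(path)
        vs <- ln[startsWith(ln, "v ")]
        fs <- ln[startsWith(ln, "f ")]
        v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"),
                                   function(x) as.numeric(x[1:3])))
        f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fs)), "\\s+"),
                                   function(x) as.integer(sub("/.*", "", x[1:3]))))
    } else if (ext == "ply") {
        ln <- readLines(path)
        nv <- as.integer(sub(".*vertex ", "", grep("element vertex", ln,
                                                   value = TRUE)[1L]))
        nf <- as.integer(sub(".*face ", "", grep("element face", ln,
                                                 value = TRUE)[1L]))
        hdr <- which(ln == "end_header")
        v <- do.call(rbind, lapply(strsplit(ln[hdr + seq_len(nv)], "\\s+"),
                                   function(x) as.numeric(x[1:3])))
        f <- do.call(rbind, lapply(strsplit(ln[hdr + nv + seq_len(nf)], "\\s+"),
                                   function(x) as.integer(x[2:4]) + 1L))
    } else if (ext == "stl") {
        ln <- readLines(path)
        vl <- grep("^\\s*vertex", ln, value = TRUE)
        coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                        function(x) as.numeric(x[2:4])))
        key <- apply(coords, 1L, paste, collapse = ",")
        uk <- !duplicated(key)
        v <- coords[uk, , drop = FALSE]
        idx <- match(key, key[uk])
        f <- matrix(idx, ncol = 3L, byrow = TRUE)
    } else stop("unsupported mesh format: ", ext)
    v <- v * scale
    new("ToothMesh", vertices = v, faces = f,
        normals = computeVertexNormals(v, f), metadata = list())
}

#' Euler characteristic of a mesh (V - E + F)
#'
#' Equals 2 for a closed surface of genus zero; used to check that
#' generated crowns are watertight.
#'
#' @param mesh \linkS4class{ToothMesh}.
#' @export
eulerCharacteristic <- function(mesh) {
    f <- mesh@faces
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
    nrow(mesh@vertices) - nrow(e) + nrow(f)
}
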