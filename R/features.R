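# Instance embeddings: a pluggable extractor contract plus the deterministic
# toy extractor, and image-space augmentation (rotation + optional blur).
#
# An extractor is any object of class "hnmil_extractor" exposing
#   $name, $embedding_dim, $input_kind ("patch2d" or "subvolume3d"),
#   $map(instance) -> numeric vector of length embedding_dim.
# An adapter for a real pretrained foundation model plugs in behind the same
# contract and owns its own input normalization.

#' Deterministic toy feature extractor
#'
#' Downsamples each instance to a fixed two-channel coarse grid (per-block
#' mean and per-block standard deviation), flattens, applies a seeded fixed
#' random linear projection to `dim` dimensions and a tanh nonlinearity.
#' Deterministic given the seed. The second (dispersion) channel guarantees
#' that both mean-intensity and variance differences in the input produce
#' embedding differences, which is the signal the downstream models must
#' recover.
#'
#' @param dim Embedding dimension.
#' @param input_kind `"patch2d"` (224x224 patches, pooled to 16x16 blocks)
#'   or `"subvolume3d"` (50^3 subvolumes, pooled to 10^3 blocks).
#' @param seed Seed for the fixed projection matrix.
#' @return An object of class `hnmil_extractor`.
#' @export
toy_extractor <- function(dim = 256L, input_kind = c("patch2d", "subvolume3d"),
                          seed = 1337L) {
  input_kind <- match.arg(input_kind)
  stopifnot(dim >= 1)
  in_len <- if (input_kind == "patch2d") 2L * 16L * 16L else 2L * 10L^3
  set.seed(derive_seed(seed, paste0("toy_extractor_", input_kind)))
  W <- matrix(stats::rnorm(in_len * dim, sd = 1 / sqrt(in_len)), in_len, dim)
  b <- stats::rnorm(dim, sd = 0.1)
  pool2d <- pooling_matrix(224L, 16L)
  pool1d <- pooling_matrix(50L, 10L)
  map <- if (input_kind == "patch2d") {
    function(inst) {
      px <- if (is.list(inst)) inst$pixels else inst
      if (!identical(dim(px), c(224L, 224L)))
        stop("toy patch2d extractor expects 224x224 patches", call. = FALSE)
      m1 <- crossprod(pool2d, px %*% pool2d)            # block means
      m2 <- crossprod(pool2d, (px * px) %*% pool2d)     # block mean squares
      bsd <- sqrt(pmax(m2 - m1 * m1, 0))
      as.numeric(tanh(c(m1 - 0.5, 4 * bsd) %*% W + b))
    }
  } else {
    function(inst) {
      vx <- if (is.list(inst)) inst$voxels else inst
      if (!identical(dim(vx), c(50L, 50L, 50L)))
        stop("toy subvolume3d extractor expects 50x50x50 volumes", call. = FALSE)
      m1 <- block_mean_3d(vx, pool1d)
      m2 <- block_mean_3d(vx * vx, pool1d)
      bsd <- sqrt(pmax(m2 - m1 * m1, 0))
      as.numeric(tanh(c(m1 - 0.5, 4 * bsd) %*% W + b))
    }
  }
  structure(list(name = "toy", embedding_dim = as.integer(dim),
                 input_kind = input_kind, seed = as.integer(seed),
                 normalization = "block mean, center at 0.5, tanh projection",
                 map = map),
            class = "hnmil_extractor")
}

# column-normalized block-pooling matrix: n input cells -> k blocks
pooling_matrix <- function(n, k) {
  stopifnot(n %% k == 0)
  block <- n %/% k
  P <- matrix(0, n, k)
  for (j in seq_len(k)) P[((j - 1) * block + 1):(j * block), j] <- 1 / block
  P
}

block_mean_3d <- function(v, P) {
  d <- dim(v); k <- ncol(P)
  m <- matrix(v, nrow = d[1])                 # d1 x (d2*d3)
  m <- crossprod(P, m)                        # k x (d2*d3)
  a <- aperm(array(m, c(k, d[2], d[3])), c(2, 1, 3))
  m <- crossprod(P, matrix(a, nrow = d[2]))   # pool axis 2
  a <- aperm(array(m, c(k, k, d[3])), c(3, 1, 2))
  m <- crossprod(P, matrix(a, nrow = d[3]))   # pool axis 3
  aperm(array(m, c(k, k, k)), c(2, 3, 1))
}

#' Rotate a 2D image about its center (bilinear interpolation, zero fill)
#'
#' @param mat Numeric matrix.
#' @param angle_deg Rotation angle in degrees.
#' @param fill Value used outside the source image.
#' @return Rotated matrix of the same shape.
#' @export
rotate_bilinear <- function(mat, angle_deg, fill = 0) {
  n <- nrow(mat); m <- ncol(mat)
  th <- angle_deg * pi / 180
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  i <- rep(seq_len(n), m) - cx
  j <- rep(seq_len(m), each = n) - cy
  x <- cos(th) * i + sin(th) * j + cx
  y <- -sin(th) * i + cos(th) * j + cy
  x0 <- floor(x); y0 <- floor(y)
  wx <- x - x0; wy <- y - y0
  gather <- function(xi, yi) {
    ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= m
    v <- rep(fill, length(xi))
    v[ok] <- mat[cbind(xi[ok], yi[ok])]
    v
  }
  v <- gather(x0, y0) * (1 - wx) * (1 - wy) +
    gather(x0 + 1, y0) * wx * (1 - wy) +
    gather(x0, y0 + 1) * (1 - wx) * wy +
    gather(x0 + 1, y0 + 1) * wx * wy
  matrix(v, n, m)
}

# cache of banded separable Gaussian convolution matrices
.blur_cache <- new.env(parent = emptyenv())

blur_band_matrix <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  if (!is.null(.blur_cache[[key]])) return(.blur_cache[[key]])
  r <- ceiling(3 * sigma)
  delta <- outer(seq_len(n), seq_len(n), "-")
  B <- exp(-delta^2 / (2 * sigma^2)) * (abs(delta) <= r)
  B <- B / rowSums(B)       # renormalized at the borders
  .blur_cache[[key]] <- B
  B
}

#' Gaussian blur of a 2D image (separable, border-renormalized)
#'
#' @param mat Numeric matrix.
#' @param sigma Kernel standard deviation in pixels.
#' @return Blurred matrix of the same shape.
#' @export
gauss_blur2d <- function(mat, sigma = 1) {
  Br <- blur_band_matrix(nrow(mat), sigma)
  Bc <- blur_band_matrix(ncol(mat), sigma)
  Br %*% mat %*% t(Bc)    # rows of the band matrices sum to 1
}

#' Augment a 2D patch (random rotation, optional Gaussian blur)
#'
#' A rotation with angle uniform in [0, 10] degrees is always applied
#' (bilinear interpolation, zero fill); a Gaussian blur with sigma = 1 pixel
#' is applied with probability 0.5. Output shape is unchanged. Uses the
#' current RNG state; seed it for reproducibility.
#'
#' @param patch A patch as returned by [extract_view_slices()], or a bare
#'   matrix.
#' @param max_angle Upper bound of the rotation angle in degrees.
#' @param blur_prob Probability of applying the blur.
#' @param blur_sigma Blur kernel sigma in pixels.
#' @return The augmented patch (same structure as the input).
#' @export
augment_patch <- function(patch, max_angle = 10, blur_prob = 0.5,
                          blur_sigma = 1) {
  px <- if (is.list(patch)) patch$pixels else patch
  angle <- stats::runif(1, 0, max_angle)
  out <- rotate_bilinear(px, angle)
  if (stats::runif(1) < blur_prob) out <- gauss_blur2d(out, sigma = blur_sigma)
  out <- matrix(pmin(pmax(as.numeric(out), 0), 1), nrow(px), ncol(px))
  if (is.list(patch)) { patch$pixels <- out; patch } else out
}

#' Augment a 3D subvolume
#'
#' In-plane (axial) rotation of every slice by one shared random angle in
#' [0, 10] degrees, plus per-slice Gaussian blur with probability 0.5.
#'
#' @inheritParams augment_patch
#' @param subvol A subvolume as returned by [sample_subvolumes()].
#' @return The augmented subvolume.
#' @export
augment_subvolume <- function(subvol, max_angle = 10, blur_prob = 0.5,
                              blur_sigma = 1) {
  vx <- subvol$voxels
  angle <- stats::runif(1, 0, max_angle)
  blur <- stats::runif(1) < blur_prob
  d <- dim(vx)
  for (k in seq_len(d[3])) {
    sl <- rotate_bilinear(vx[, , k], angle)
    if (blur) sl <- gauss_blur2d(sl, sigma = blur_sigma)
    vx[, , k] <- pmin(pmax(as.numeric(sl), 0), 1)
  }
  subvol$voxels <- vx
  subvol
}

#' Embed a bag of instances
#'
#' Runs every instance (and an augmented twin of each) through the extractor
#' and assembles the per-patient instance bag used for MIL training: plain
#' and augmented embedding matrices with identical instance order.
#'
#' @param instances List of patches or subvolumes (all matching the
#'   extractor's `input_kind`).
#' @param extractor An `hnmil_extractor`.
#' @param patient_id Patient identifier.
#' @param label Optional binary label.
#' @param endpoint Optional endpoint tag.
#' @param augment Compute the augmented twin (default TRUE).
#' @param seed Seed for the augmentation draws.
#' @return An `instance_bag`: `patient_id`, `embeddings` (N x D),
#'   `embeddings_aug` (N x D or NULL), `meta` (per-instance data frame),
#'   `label`, `endpoint`.
#' @export
embed_bag <- function(instances, extractor, patient_id = NULL, label = NULL,
                      endpoint = NULL, augment = TRUE, seed = 1L) {
  stopifnot(inherits(extractor, "hnmil_extractor"), length(instances) >= 1L)
  is2d <- extractor$input_kind == "patch2d"
  kind_of <- function(x) {
    if (is.list(x) && !is.null(x$voxels)) return("subvolume3d")
    if (is.list(x) && !is.null(x$pixels)) return("patch2d")
    if (is.matrix(x)) return("patch2d")
    if (is.array(x) && length(dim(x)) == 3L) return("subvolume3d")
    stop("unrecognized instance type", call. = FALSE)
  }
  kinds <- vapply(instances, kind_of, "")
  if (any(kinds != extractor$input_kind))
    stop(sprintf("instance kind does not match the extractor contract (%s)",
                 extractor$input_kind), call. = FALSE)

  E <- t(vapply(instances, extractor$map, numeric(extractor$embedding_dim)))
  E_aug <- NULL
  if (augment) {
    set.seed(seed)
    aug <- lapply(instances, function(x)
      if (is2d) augment_patch(x) else augment_subvolume(x))
    E_aug <- t(vapply(aug, extractor$map, numeric(extractor$embedding_dim)))
  }
  if (is.null(patient_id))
    patient_id <- (if (is.list(instances[[1]])) instances[[1]]$patient_id) %||% ""
  meta <- if (is2d && is.list(instances[[1]]) && !is.null(instances[[1]]$view)) {
    data.frame(view = vapply(instances, `[[`, "", "view"),
               slice_index = vapply(instances, `[[`, 0L, "slice_index"))
  } else if (!is2d) {
    data.frame(t(vapply(instances, function(x)
      x$center_voxel %||% c(NA_integer_, NA_integer_, NA_integer_),
      integer(3))))
  } else NULL
  structure(list(patient_id = patient_id, embeddings = E,
                 embeddings_aug = E_aug, meta = meta,
                 label = label, endpoint = endpoint),
            class = "instance_bag")
}

#' Write / read an embedding cache
#'
#' One file per patient holding the plain and augmented embedding matrices,
#' with a JSON sidecar describing patients, instance counts and embedding
#' dimension. Mirrors the extract-once / train-many workflow.
#'
#' @param bags List of `instance_bag`s.
#' @param directory Cache directory (created if absent).
#' @return `write_bags()` returns the sidecar invisibly; `read_bags()`
#'   returns the list of bags.
#' @export
write_bags <- function(bags, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(bags, function(b) {
    file <- paste0(b$patient_id, "_bag.rds")
    saveRDS(b, file.path(directory, file))
    list(patient_id = b$patient_id, file = file,
         n_instances = nrow(b$embeddings), dim = ncol(b$embeddings),
         augmented = !is.null(b$embeddings_aug))
  })
  sidecar <- list(bags = entries)
  jsonlite::write_json(sidecar, file.path(directory, "bags.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_bags
#' @export
read_bags <- function(directory) {
  sidecar <- jsonlite::read_json(file.path(directory, "bags.json"))
  lapply(sidecar$bags, function(e) {
    b <- readRDS(file.path(directory, e$file))
    if (!identical(nrow(b$embeddings), as.integer(e$n_instances)))
      stop(sprintf("cache sidecar disagrees with %s", e$file), call. = FALSE)
    b
  })
}
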