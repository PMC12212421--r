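# Handcrafted radiomics: a documented subset of IBSI-style shape,
# first-order and GLCM features computed from the GTVp, plus the
# variance -> clustering -> mRMR feature-selection chain and the logistic
# baseline model.

#' Shape features of a binary mask
#'
#' Volume (voxel count times voxel volume), surface area under the exposed
#' voxel-face convention, sphericity `(36*pi*V^2)^(1/3) / A`, and maximum 3D
#' diameter (largest center-to-center distance between surface voxels).
#'
#' @param mask {0,1} 3D array.
#' @param spacing Voxel spacing in mm.
#' @return Named numeric vector `shape_volume_mm3`, `shape_surface_mm2`,
#'   `shape_sphericity`, `shape_max_diameter_mm`.
#' @export
compute_shape_features <- function(mask, spacing = c(1, 1, 1)) {
  if (!any(mask == 1)) stop("empty mask", call. = FALSE)
  m <- crop_to_mask(array(as.integer(mask == 1), dim = dim(mask)), mask == 1)
  d <- dim(m)
  vol <- sum(m) * prod(spacing)
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  exposed <- array(0, dim = d)
  surf <- 0
  for (ax in 1:3) {
    lo <- switch(ax, pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)],
                 pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)],
                 pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]])
    hi <- switch(ax, pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)],
                 pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)],
                 pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)])
    nf <- core * ((lo == 0L) + (hi == 0L))
    surf <- surf + sum(nf) * face_area[ax]
    exposed <- exposed + nf
  }
  sph <- (36 * pi * vol^2)^(1 / 3) / surf
  surf_vox <- which(exposed > 0 & core == 1L, arr.ind = TRUE)
  if (nrow(surf_vox) > 6000L) {
    set.seed(20231L)  # deterministic thinning for very large masks
    surf_vox <- surf_vox[sample.int(nrow(surf_vox), 6000L), , drop = FALSE]
  }
  pts <- sweep(surf_vox - 0.5, 2, spacing, "*")
  maxd <- if (nrow(pts) < 2L) 0 else max(stats::dist(pts))
  c(shape_volume_mm3 = vol, shape_surface_mm2 = surf,
    shape_sphericity = sph, shape_max_diameter_mm = maxd)
}

#' First-order (intensity histogram) features inside a mask
#'
#' Mean, variance, skewness, kurtosis, energy, fixed-bin-width histogram
#' entropy, 10th/90th percentiles, minimum and maximum of in-mask HU.
#' Degenerate constant regions return variance, skewness and entropy 0.
#'
#' @param ct HU array.
#' @param mask {0,1} array aligned with `ct`.
#' @param bin_width Histogram bin width in HU for the entropy (default 25).
#' @return Named numeric vector of `fo_*` features.
#' @export
compute_firstorder_features <- function(ct, mask, bin_width = 25) {
  x <- ct[mask == 1]
  if (!length(x)) stop("empty mask", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  bins <- floor((x - min(x)) / bin_width)
  pb <- tabulate(bins + 1L) / n
  pb <- pb[pb > 0]
  entropy <- -sum(pb * log2(pb))
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  c(fo_mean = mu, fo_variance = if (n > 1) stats::var(x) else 0,
    fo_skewness = skew, fo_kurtosis = kurt,
    fo_energy = sum(x^2), fo_entropy = entropy,
    fo_p10 = q[1], fo_p90 = q[2], fo_min = min(x), fo_max = max(x))
}

# crop an array to the bounding box of a logical mask, 1-voxel margin
crop_to_mask <- function(arr, mask) {
  w <- which(mask, arr.ind = TRUE)
  d <- dim(arr)
  lo <- pmax(1L, apply(w, 2, min) - 1L)
  hi <- pmin(d, apply(w, 2, max) + 1L)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

# the 13 unique 3D direction offsets at Chebyshev distance 1
glcm_offsets_3d <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 | (offs$dy == 0 & offs$dx > 0)))
  as.matrix(offs[keep, ])
}

#' Gray-level co-occurrence (GLCM) texture features inside a mask
#'
#' In-mask HU are discretized into `n_bins` equal-width levels; a single
#' symmetric normalized co-occurrence matrix is aggregated over the 13
#' unique 3D direction offsets at the given distance, skipping neighbor
#' pairs that leave the mask. Features follow the IBSI formulas: contrast,
#' dissimilarity, homogeneity (inverse difference), joint entropy and
#' correlation. A single-level (uniform) region is degenerate and returns
#' contrast 0, entropy 0 and correlation 1 by convention.
#'
#' @param ct HU array.
#' @param mask {0,1} array aligned with `ct`.
#' @param n_bins Number of gray levels (default 16).
#' @param distance Offset length in voxels (default 1).
#' @return Named numeric vector of `glcm_*` features; the matrix itself is
#'   attached as attribute `"glcm"`.
#' @export
compute_glcm_features <- function(ct, mask, n_bins = 16L, distance = 1L) {
  x <- ct[mask == 1]
  if (!length(x)) stop("empty mask", call. = FALSE)
  rngx <- range(x)
  d <- dim(ct)
  lev <- array(0L, dim = d)
  if (rngx[1] == rngx[2]) {
    lev[mask == 1] <- 1L
  } else {
    w <- (rngx[2] - rngx[1]) / n_bins
    lev[mask == 1] <- pmin(n_bins, floor((x - rngx[1]) / w) + 1L)
  }
  lev <- crop_to_mask(lev, lev > 0L)
  d <- dim(lev)
  offs <- glcm_offsets_3d() * distance
  nl <- max(lev)
  P <- matrix(0, nl, nl)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    if (any(abs(o) >= d)) next
    sx <- seq_len(d[1] - abs(o[1])); sy <- seq_len(d[2] - abs(o[2]))
    sz <- seq_len(d[3] - abs(o[3]))
    tx <- sx + abs(o[1]); ty <- sy + abs(o[2]); tz <- sz + abs(o[3])
    # handle negative components by mirroring the source block
    if (o[1] < 0) { tmp <- sx; sx <- tx; tx <- tmp }
    if (o[2] < 0) { tmp <- sy; sy <- ty; ty <- tmp }
    if (o[3] < 0) { tmp <- sz; sz <- tz; tz <- tmp }
    a <- lev[sx, sy, sz]; b <- lev[tx, ty, tz]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    cnt <- tabulate((a[ok] - 1L) * nl + b[ok], nbins = nl * nl)
    tab <- matrix(cnt, nl, nl, byrow = TRUE)
    P <- P + tab + t(tab)
  }
  if (sum(P) == 0) {
    # isolated voxels only: fall back to the degenerate convention
    feats <- c(glcm_contrast = 0, glcm_dissimilarity = 0,
               glcm_homogeneity = 1, glcm_joint_entropy = 0,
               glcm_correlation = 1)
    attr(feats, "glcm") <- P
    return(feats)
  }
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(nl) * px)
  sig2 <- sum((seq_len(nl) - mu)^2 * px)
  contrast <- sum(P * (i - j)^2)
  dissim <- sum(P * abs(i - j))
  homog <- sum(P / (1 + abs(i - j)))
  pe <- P[P > 0]
  jent <- -sum(pe * log2(pe))
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1
  feats <- c(glcm_contrast = contrast, glcm_dissimilarity = dissim,
             glcm_homogeneity = homog, glcm_joint_entropy = jent,
             glcm_correlation = corr)
  attr(feats, "glcm") <- P
  feats
}

#' Full radiomics feature vector for one patient
#'
#' @param ct HU array (isotropically resampled).
#' @param mask Binary GTVp mask aligned with `ct`.
#' @param spacing Voxel spacing of `ct`.
#' @param bin_width First-order entropy bin width (HU).
#' @param n_bins GLCM gray levels.
#' @return Named numeric vector combining shape, first-order and GLCM
#'   features.
#' @export
compute_radiomics_features <- function(ct, mask, spacing = c(1, 1, 1),
                                       bin_width = 25, n_bins = 16L) {
  c(compute_shape_features(mask, spacing),
    compute_firstorder_features(ct, mask, bin_width),
    compute_glcm_features(ct, mask, n_bins))
}

#' Radiomics feature-selection chain
#'
#' Implements the selection chain: (1) drop near-zero-variance features;
#' (2) z-score the rest; (3) average-linkage hierarchical clustering on the
#' correlation distance `1 - |Spearman rho|`, cut at height `cutoff`;
#' (4) keep per cluster the feature with the highest mean absolute Spearman
#' correlation to its co-members; (5) rank representatives by mRMR in the
#' difference form (relevance = |point-biserial correlation with the
#' label|, redundancy = mean |Spearman| with already-selected features);
#' (6) keep `k = max(1, floor(n_minority / 10))` features.
#'
#' @param table Data frame or matrix of features (rows = patients).
#' @param labels Binary labels (0/1).
#' @param cutoff Correlation-distance cut height (default 0.20).
#' @param var_tol Variance threshold under which a feature is dropped.
#' @return A `selection_trace` list: `variance_dropped`, `clusters`,
#'   `representatives`, `mrmr_order`, `k_selected`, `selected`.
#' @export
select_features <- function(table, labels, cutoff = 0.20, var_tol = 1e-8) {
  X <- as.matrix(table)
  stopifnot(nrow(X) == length(labels))
  labels <- as.numeric(labels)
  vars <- apply(X, 2, stats::var)
  dropped <- colnames(X)[vars <= var_tol]
  X <- X[, vars > var_tol, drop = FALSE]
  if (!ncol(X)) stop("all features are (near-)constant", call. = FALSE)
  Z <- scale(X)

  reps <- colnames(Z)
  clusters <- as.list(colnames(Z))
  if (ncol(Z) > 1L) {
    rho <- stats::cor(Z, method = "spearman")
    dmat <- stats::as.dist(1 - abs(rho))
    hc <- stats::hclust(dmat, method = "average")
    memb <- stats::cutree(hc, h = cutoff)
    clusters <- split(colnames(Z), memb)
    reps <- vapply(clusters, function(members) {
      if (length(members) == 1L) return(members)
      sub <- abs(rho[members, members, drop = FALSE])
      score <- (rowSums(sub) - 1) / (length(members) - 1)
      members[which.max(score)]
    }, "")
  }

  # mRMR (difference form) over the cluster representatives
  reps <- unname(reps)
  rel <- vapply(reps, function(f) abs(stats::cor(Z[, f], labels)), 0)
  names(rel) <- reps
  Zr <- Z[, reps, drop = FALSE]
  rho_r <- if (length(reps) > 1L)
    abs(stats::cor(Zr, method = "spearman")) else matrix(1, 1, 1,
                                                         dimnames = list(reps, reps))
  selected <- character(0)
  remaining <- reps
  while (length(remaining)) {
    sc <- vapply(remaining, function(f) {
      red <- if (!length(selected)) 0 else mean(rho_r[f, selected])
      rel[[f]] - red
    }, 0)
    pick <- remaining[which.max(sc)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  n_min <- min(sum(labels == 1), sum(labels == 0))
  k <- max(1L, floor(n_min / 10))
  structure(list(variance_dropped = dropped,
                 clusters = unname(clusters),
                 representatives = unname(reps),
                 mrmr_order = selected,
                 k_selected = as.integer(min(k, length(selected))),
                 selected = selected[seq_len(min(k, length(selected)))]),
            class = "selection_trace")
}

#' Fit the logistic radiomics baseline
#'
#' Logistic regression on z-scored selected features; the standardization
#' parameters are learned on the training data and frozen for deployment.
#'
#' @param features Data frame/matrix of the selected features
#'   (rows = patients).
#' @param labels Binary labels (0/1).
#' @return An `hnmil_logistic` scoring model; use [predict()] with
#'   `newdata` to obtain probabilities.
#' @export
fit_radiomics_classifier <- function(features, labels) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Zs <- scale(X, center = ctr, scale = scl)
  df <- data.frame(Zs, y = as.numeric(labels), check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  structure(list(fit = fit, center = ctr, scale = scl,
                 features = colnames(X)),
            class = "hnmil_logistic")
}

#' @export
predict.hnmil_logistic <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Zs <- scale(X, center = object$center, scale = object$scale)
  as.numeric(stats::predict(object$fit,
                            newdata = data.frame(Zs, check.names = FALSE),
                            type = "response"))
}
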