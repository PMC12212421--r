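# Geometry and intensity preprocessing: body masking, isotropic resampling,
# HU windowing/normalization, 2D patch extraction and 3D subvolume sampling.

# -- 3D connected components (6-connectivity), frontier flood fill ---------
# No installed package labels 3D components, so this is done by hand.
label_components_3d <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  fg <- which(as.logical(mask))
  lab <- integer(n)
  if (!length(fg)) return(array(lab, dim = d))
  is_fg <- logical(n); is_fg[fg] <- TRUE
  # precomputed coordinates for boundary guards
  ix <- ((seq_len(n) - 1L) %% d[1]) + 1L
  iy <- (((seq_len(n) - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((seq_len(n) - 1L) %/% (d[1] * d[2])) + 1L
  offs <- list(c(-1L, 1L), c(-d[1], d[1]), c(-d[1] * d[2], d[1] * d[2]))
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      nbrs <- integer(0)
      fx <- ix[frontier]; fy <- iy[frontier]; fz <- iz[frontier]
      nbrs <- c(frontier[fx > 1L] - 1L, frontier[fx < d[1]] + 1L,
                frontier[fy > 1L] - d[1], frontier[fy < d[2]] + d[1],
                frontier[fz > 1L] - d[1] * d[2],
                frontier[fz < d[3]] + d[1] * d[2])
      nbrs <- unique(nbrs[is_fg[nbrs] & lab[nbrs] == 0L])
      lab[nbrs] <- cur
      frontier <- nbrs
    }
  }
  array(lab, dim = d)
}

# fill internal cavities: everything not reachable from the border through
# the complement belongs to the body
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  comp <- !as.logical(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- comp
  # border ring of the padded complement is all background by construction
  pad_lab <- label_components_3d(pad | make_border_array(d + 2L))
  outside_label <- pad_lab[1L, 1L, 1L]
  outside <- pad_lab[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] == outside_label
  array(as.integer(!outside), dim = d)
}

make_border_array <- function(d) {
  b <- array(FALSE, dim = d)
  b[c(1L, d[1]), , ] <- TRUE
  b[, c(1L, d[2]), ] <- TRUE
  b[, , c(1L, d[3])] <- TRUE
  b
}

#' Segment the patient body and remove the bed
#'
#' Thresholds the CT above an air threshold, keeps the largest connected
#' component (which drops the disconnected bed slab), fills internal
#' cavities, and replaces everything outside the body with a fill HU value
#' so downstream windowing never sees the bed.
#'
#' @param ct HU-valued 3D array.
#' @param air_threshold HU threshold separating tissue from air
#'   (default -500).
#' @param fill_hu HU value assigned outside the body (default -1024, air).
#' @return List with `mask` ({0,1} integer array) and `ct_masked` (the CT
#'   with out-of-body voxels set to `fill_hu`).
#' @export
mask_body <- function(ct, air_threshold = -500, fill_hu = -1024) {
  stopifnot(length(dim(ct)) == 3L)
  bin <- ct > air_threshold
  if (!any(bin))
    stop("no voxels above the air threshold; cannot segment a body",
         call. = FALSE)
  lab <- label_components_3d(bin)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  body <- fill_holes_3d(array(as.integer(lab == keep), dim = dim(ct)))
  ct_masked <- ct
  ct_masked[body == 0L] <- fill_hu
  list(mask = body, ct_masked = ct_masked)
}

# -- resampling -----------------------------------------------------------

# separable per-axis resampling under the cell-extent convention: a grid of
# n voxels at spacing s spans n*s mm with voxel centers at (i - 0.5)*s
resample_axis <- function(arr, axis, sp_in, sp_out, method) {
  d <- dim(arr)
  n_in <- d[axis]
  n_out <- max(1L, as.integer(round(n_in * sp_in / sp_out)))
  pos <- (seq_len(n_out) - 0.5) * sp_out
  if (method == "nearest") {
    idx <- pmin(n_in, pmax(1L, ceiling(pos / sp_in)))
    return(index_axis(arr, axis, idx))
  }
  centers <- (seq_len(n_in) - 0.5) * sp_in
  lo <- findInterval(pos, centers)
  lo <- pmin(pmax(lo, 1L), n_in)
  hi <- pmin(lo + 1L, n_in)
  w <- (pos - centers[lo]) / ifelse(hi > lo, centers[hi] - centers[lo], 1)
  w[hi == lo] <- 0
  w[pos < centers[1]] <- 0
  a <- index_axis(arr, axis, lo)
  b <- index_axis(arr, axis, hi)
  wexp <- broadcast_axis(w, dim(a), axis)
  a * (1 - wexp) + b * wexp
}

index_axis <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

broadcast_axis <- function(v, d, axis) {
  src <- c(axis, setdiff(1:3, axis))      # v lies along the first dim here
  aperm(array(v, dim = d[src]), order(src))
}

#' Resample a CT and mask to isotropic spacing
#'
#' CT intensities are linearly interpolated and the mask is resampled with
#' nearest-neighbor lookup; the physical extent is preserved to within one
#' voxel.
#'
#' @param ct HU array.
#' @param mask Binary array aligned with `ct` (may be `NULL`).
#' @param spacing Input voxel spacing (mm triple).
#' @param target Target spacing, default 1 mm isotropic.
#' @return List with `ct`, `mask` and `spacing = target`.
#' @export
resample_isotropic <- function(ct, mask = NULL, spacing, target = c(1, 1, 1)) {
  assert_pos(spacing, "spacing"); assert_pos(target, "target")
  stopifnot(length(dim(ct)) == 3L)
  out <- ct
  for (ax in 1:3) out <- resample_axis(out, ax, spacing[ax], target[ax], "linear")
  m_out <- NULL
  if (!is.null(mask)) {
    m_out <- mask
    for (ax in 1:3) m_out <- resample_axis(m_out, ax, spacing[ax], target[ax], "nearest")
    m_out <- array(as.integer(m_out), dim = dim(m_out))
  }
  list(ct = out, mask = m_out, spacing = as.numeric(target))
}

#' Soft-tissue window specification
#' @param level Window level in HU (default 50).
#' @param width Window width in HU (default 120); must be positive.
#' @export
window_spec <- function(level = 50, width = 120) {
  if (!is.numeric(width) || width <= 0) stop("window width must be > 0", call. = FALSE)
  structure(list(level = level, width = width), class = "window_spec")
}

#' Apply an HU window and rescale to [0, 1]
#'
#' Clips HU to `[level - width/2, level + width/2]` and scales that range
#' affinely onto `[0, 1]`; monotone nondecreasing in HU.
#'
#' @param ct HU array (any shape).
#' @param window A [window_spec()].
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
window_hu <- function(ct, window = window_spec()) {
  stopifnot(inherits(window, "window_spec"))
  lo <- window$level - window$width / 2
  (pmin(pmax(ct, lo), lo + window$width) - lo) / window$width
}

#' Normalize a 3D CT to the [-1024, 2048] HU range
#'
#' Clips to `[-1024, 2048]` HU and scales affinely to `[0, 1]` (the input
#' normalization used for 3D subvolume models).
#'
#' @param ct HU array.
#' @return Array in `[0, 1]`.
#' @export
normalize_3d <- function(ct) {
  (pmin(pmax(ct, -1024), 2048) + 1024) / 3072
}

# center of mass of a binary mask in voxel indices, rounded half-up
mask_center_of_mass <- function(mask) {
  w <- which(mask == 1, arr.ind = TRUE)
  if (!nrow(w)) stop("empty mask", call. = FALSE)
  as.integer(round_half_up(colMeans(w)))
}

# crop a matrix to size x size centered at (r, c), zero-padding at borders
crop_center_2d <- function(mat, center, size = 224L) {
  out <- matrix(0, size, size)
  half <- size %/% 2L
  r0 <- center[1] - half + 1L; c0 <- center[2] - half + 1L
  rr <- seq.int(r0, r0 + size - 1L); cc <- seq.int(c0, c0 + size - 1L)
  rv <- rr >= 1L & rr <= nrow(mat); cv <- cc >= 1L & cc <= ncol(mat)
  out[which(rv), which(cv)] <- mat[rr[rv], cc[cv], drop = FALSE]
  out
}

#' Extract per-view 2D patches containing the GTVp
#'
#' For each requested CT view, selects every slice index where the GTVp mask
#' has at least one voxel and crops a 224x224 patch centered at the in-plane
#' projection of the 3D GTVp center of mass, zero-padded at volume borders.
#'
#' @param ct01 Windowed CT in `[0, 1]` (isotropic).
#' @param gtvp_mask Binary mask aligned with `ct01`; must be nonempty.
#' @param views Subset of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param patient_id Carried into each patch.
#' @param size Patch side length (default 224).
#' @return List of patches, each a list with `pixels` (`size` x `size`
#'   matrix), `view`, `slice_index`, `patient_id`.
#' @export
extract_view_slices <- function(ct01, gtvp_mask, views = "axial",
                                patient_id = "", size = 224L) {
  stopifnot(all(views %in% c("axial", "coronal", "sagittal")))
  if (!any(gtvp_mask == 1)) stop("empty GTVp mask", call. = FALSE)
  com <- mask_center_of_mass(gtvp_mask)
  # view -> slice axis: axial = z, coronal = y, sagittal = x
  ax_of <- c(axial = 3L, coronal = 2L, sagittal = 1L)
  patches <- list()
  for (v in views) {
    ax <- ax_of[[v]]
    plane <- setdiff(1:3, ax)
    present <- which(apply(gtvp_mask == 1, ax, any))
    for (s in present) {
      sl <- switch(ax, ct01[s, , ], ct01[, s, ], ct01[, , s])
      patches[[length(patches) + 1L]] <- list(
        pixels = crop_center_2d(sl, com[plane], size),
        view = v, slice_index = as.integer(s), patient_id = patient_id)
    }
  }
  patches
}

#' Sample 3D subvolumes around the GTVp center of mass
#'
#' Draws `n` centers from an isotropic Gaussian (per-axis variance
#' `variance`) around the GTVp center of mass, rounds to voxel indices,
#' clamps so the cube lies inside the volume, and extracts `size`^3 boxes.
#'
#' @param ct_norm3d Normalized CT array.
#' @param gtvp_mask Binary mask aligned with `ct_norm3d`.
#' @param n Number of subvolumes (default 100).
#' @param variance Per-axis Gaussian variance in voxels^2 (default 16).
#' @param size Cube side length in voxels (default 50).
#' @param patient_id Carried into each subvolume.
#' @return List of subvolumes, each with `voxels` (size^3 array),
#'   `center_voxel`, `patient_id`. Uses the current RNG state; seed it for
#'   reproducibility.
#' @export
sample_subvolumes <- function(ct_norm3d, gtvp_mask, n = 100L, variance = 16,
                              size = 50L, patient_id = "") {
  size <- as.integer(size)
  d <- dim(ct_norm3d)
  if (any(d < size))
    stop(sprintf("volume %s smaller than the %d^3 subvolume",
                 paste(d, collapse = "x"), size), call. = FALSE)
  com <- mask_center_of_mass(gtvp_mask)
  centers <- matrix(stats::rnorm(3L * n, mean = rep(com, each = n),
                                 sd = sqrt(variance)), ncol = 3L)
  centers <- round_half_up(centers)
  half_lo <- size %/% 2L - 1L      # size 50: 24 below, 25 above the center
  half_hi <- size - half_lo - 1L
  lapply(seq_len(n), function(i) {
    c_i <- as.integer(pmin(pmax(centers[i, ], half_lo + 1L), d - half_hi))
    v <- ct_norm3d[(c_i[1] - half_lo):(c_i[1] + half_hi),
                   (c_i[2] - half_lo):(c_i[2] + half_hi),
                   (c_i[3] - half_lo):(c_i[3] + half_hi)]
    list(voxels = v, center_voxel = c_i, patient_id = patient_id)
  })
}
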