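# 3D shape descriptors of the binary ROI. Surface area uses the exposed-face
# convention: the sum of the areas of foreground voxel faces not shared with
# another foreground voxel.

# Count exposed faces along one axis and return their total area in mm^2.
exposed_face_area_axis <- function(mask, axis, spacing) {
  d <- dim(mask)
  face_area <- prod(spacing[-axis])
  n <- d[axis]
  # neighbours along +axis: pairs (i, i+1); a face is shared iff both fg
  idx_lo <- lapply(seq_len(3), function(a)
    if (a == axis) seq_len(n - 1L) else seq_len(d[a]))
  idx_hi <- lapply(seq_len(3), function(a)
    if (a == axis) seq_len(n - 1L) + 1L else seq_len(d[a]))
  if (n > 1L) {
    lo <- do.call(`[`, c(list(mask), idx_lo, list(drop = FALSE)))
    hi <- do.call(`[`, c(list(mask), idx_hi, list(drop = FALSE)))
    shared <- sum(lo & hi)
  } else shared <- 0L
  # each foreground voxel has 2 faces along this axis; shared faces join 2
  (2L * sum(mask) - 2L * shared) * face_area
}

# Foreground voxels with at least one exposed face (6-neighbourhood).
surface_voxel_indices <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (axis in 1:3) {
    n <- d[axis]
    pad <- array(FALSE, replace(d, axis, 1L))
    sub <- function(from, to) {
      idx <- lapply(seq_len(3), function(a)
        if (a == axis) seq.int(from, to) else seq_len(d[a]))
      do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
    }
    fwd <- if (n > 1L) abind_axis(sub(2L, n), pad, axis) else pad
    bwd <- if (n > 1L) abind_axis(pad, sub(1L, n - 1L), axis) else pad
    interior <- interior & fwd & bwd
  }
  which(mask & !interior, arr.ind = TRUE)
}

# Minimal bind of two arrays along one axis (avoids an abind dependency).
abind_axis <- function(a, b, axis) {
  da <- dim(a); db <- dim(b)
  dd <- da; dd[axis] <- da[axis] + db[axis]
  out <- array(vector(mode = typeof(a), 1L), dd)
  idx_a <- lapply(seq_len(3), function(ax)
    if (ax == axis) seq_len(da[axis]) else seq_len(dd[ax]))
  idx_b <- lapply(seq_len(3), function(ax)
    if (ax == axis) da[axis] + seq_len(db[axis]) else seq_len(dd[ax]))
  out <- do.call(`[<-`, c(list(out), idx_a, list(value = a)))
  do.call(`[<-`, c(list(out), idx_b, list(value = b)))
}

#' Shape features of a tumour ROI
#'
#' Computes 17 geometric descriptors from the binary mask alone: voxel-count
#' volume (mm^3), exposed-face surface area (mm^2), surface-to-volume ratio,
#' two compactness variants, spherical disproportion, sphericity, maximum 3D
#' diameter, principal axis lengths with elongation and flatness from the
#' foreground coordinate covariance, bounding-box extents, and voxel count.
#'
#' @param vm A [volume_mask()].
#' @return Named numeric vector of length 17 (names prefixed `shape.`), with
#'   attribute `block = "HC"`.
#' @export
shape_features <- function(vm) {
  stopifnot(inherits(vm, "volume_mask"))
  mask <- vm$mask
  sp <- vm$spacing
  n_vox <- sum(mask)
  if (n_vox == 0L) stop("mask is empty", call. = FALSE)
  V <- n_vox * prod(sp)
  A <- sum(vapply(1:3, function(ax) exposed_face_area_axis(mask, ax, sp),
                  numeric(1)))
  R <- (3 * V / (4 * pi))^(1 / 3)
  surf <- surface_voxel_indices(mask)
  coords_s <- sweep(surf - 1, 2, sp, "*")
  # max pairwise distance is attained between surface voxels
  max_diam <- if (nrow(coords_s) > 1L) max(stats::dist(coords_s)) else 0
  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, sp, "*")
  if (n_vox > 1L) {
    ev <- sort(pmax(eigen(stats::cov(coords), symmetric = TRUE,
                          only.values = TRUE)$values, 0), decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axis_len <- 4 * sqrt(ev)
  elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  bbox <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * sp
  vals <- c(
    volume = V, n_voxels = as.numeric(n_vox),
    surface_area = A, surface_to_volume = A / V,
    compactness1 = V / (sqrt(pi) * A^1.5),
    compactness2 = 36 * pi * V^2 / A^3,
    spherical_disproportion = A / (4 * pi * R^2),
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    max_diameter_3d = max_diam,
    major_axis = axis_len[1], minor_axis = axis_len[2],
    least_axis = axis_len[3],
    elongation = elongation, flatness = flatness,
    bbox_x = bbox[1], bbox_y = bbox[2], bbox_z = bbox[3]
  )
  names(vals) <- paste("shape", names(vals), sep = ".")
  structure(vals, block = "HC")
}
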