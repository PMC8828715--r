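# 2.5D multiplanar tumour representation: three orthogonal views through the
# ROI centroid, cropped, resampled to isotropic pixels, zero-padded to square,
# resized to 224x224 and linearly mapped to [0, 255].

#' Physical centroid of the tumour ROI
#'
#' Mean of the foreground voxel-centre coordinates in millimetres
#' (0-based voxel index times spacing, voxel-centre convention).
#'
#' @param vm A [volume_mask()].
#' @return Numeric length-3 point in mm.
#' @export
roi_centroid <- function(vm) {
  stopifnot(inherits(vm, "volume_mask"))
  idx <- which(vm$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  as.numeric((colMeans(idx) - 1) * vm$spacing)
}

# Nearest-neighbour 1D resampling indices: map n_out output pixels onto
# n_in input pixels (pixel-centre convention).
nn_indices <- function(n_in, n_out) {
  pmin(pmax(floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1L, 1L), n_in)
}

resize_nn <- function(img, shape) {
  img[nn_indices(nrow(img), shape[1]), nn_indices(ncol(img), shape[2]),
      drop = FALSE]
}

pad_square <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr == nc) return(img)
  side <- max(nr, nc)
  out <- matrix(0, side, side)
  r0 <- (side - nr) %/% 2
  c0 <- (side - nc) %/% 2
  out[r0 + seq_len(nr), c0 + seq_len(nc)] <- img
  out
}

# Extract one plane through slice index `k` along `axis`, returning the 2D
# intensity and mask slices plus their in-plane spacings.
take_slice <- function(vm, axis, k) {
  if (axis == 3L) {
    list(img = vm$intensities[, , k], msk = vm$mask[, , k],
         sp = vm$spacing[c(1, 2)])
  } else if (axis == 1L) {
    list(img = vm$intensities[k, , ], msk = vm$mask[k, , ],
         sp = vm$spacing[c(2, 3)])
  } else {
    list(img = vm$intensities[, k, ], msk = vm$mask[, k, ],
         sp = vm$spacing[c(1, 3)])
  }
}

build_view <- function(vm, axis, k, margin, source_range, out_shape) {
  sl <- take_slice(vm, axis, k)
  img <- sl$img; msk <- sl$msk
  if (!any(msk)) {
    # centroid slice misses the (non-convex) ROI: crop to the projection of
    # the 3D mask onto this plane instead
    proj <- apply(vm$mask, setdiff(1:3, axis), any)
    msk <- proj
  }
  rr <- range(which(rowSums(msk) > 0))
  cc <- range(which(colSums(msk) > 0))
  rr <- c(max(1L, rr[1] - margin), min(nrow(img), rr[2] + margin))
  cc <- c(max(1L, cc[1] - margin), min(ncol(img), cc[2] + margin))
  img <- img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  # resample in-plane to isotropic pixels so the physical aspect ratio is
  # preserved by the subsequent square padding
  pix <- min(sl$sp)
  n1 <- max(1L, round(nrow(img) * sl$sp[1] / pix))
  n2 <- max(1L, round(ncol(img) * sl$sp[2] / pix))
  img <- resize_nn(img, c(n1, n2))
  # linear map of the source range to [0, 255]; padded zeros are background
  img <- (img - source_range[1]) * 255 / diff(source_range)
  img <- pad_square(img)
  resize_nn(img, out_shape)
}

#' Build the 2.5D multiplanar views of a tumour ROI
#'
#' Takes the axial, sagittal and coronal planes through the voxel nearest the
#' physical ROI centroid; crops each to the in-plane ROI bounding box,
#' resamples to isotropic pixels (nearest neighbour), zero-pads the shorter
#' side to square (preserving the tumour's physical aspect ratio), resizes to
#' 224x224 with nearest-neighbour interpolation, and linearly maps the source
#' intensity range (default \[0, 4096\]) to \[0, 255\] as continuous values.
#' Intensities outside the source range are clipped with a warning.
#'
#' @param vm A [volume_mask()].
#' @param source_range Intensity interval mapped onto \[0, 255\].
#' @param margin Crop margin around the ROI bounding box, in voxels.
#' @param out_shape Output view shape (default `c(224, 224)`).
#' @return An object of class `multiplanar_views` with elements `axial`,
#'   `sagittal`, `coronal` (each `out_shape` matrices in \[0, 255\]),
#'   `view_centre` (mm) and `patient_id`.
#' @export
extract_views <- function(vm, source_range = c(0, 4096), margin = 0L,
                          out_shape = c(224L, 224L)) {
  stopifnot(inherits(vm, "volume_mask"))
  rng <- range(vm$intensities)
  if (rng[1] < source_range[1] || rng[2] > source_range[2]) {
    warning("intensities outside the source range were clipped",
            call. = FALSE)
    vm$intensities <- pmin(pmax(vm$intensities, source_range[1]),
                           source_range[2])
  }
  centre <- roi_centroid(vm)
  kvox <- pmin(pmax(round(centre / vm$spacing) + 1L, 1L), dim(vm$mask))
  views <- list(
    axial    = build_view(vm, 3L, kvox[3], margin, source_range, out_shape),
    sagittal = build_view(vm, 1L, kvox[1], margin, source_range, out_shape),
    coronal  = build_view(vm, 2L, kvox[2], margin, source_range, out_shape)
  )
  structure(c(views,
              list(view_centre = centre, patient_id = vm$patient_id,
                   params = list(source_range = source_range,
                                 margin = margin, out_shape = out_shape))),
            class = "multiplanar_views")
}

#' @export
print.multiplanar_views <- function(x, ...) {
  cat(sprintf("<multiplanar_views> %s: 3 views %s, centre (%s) mm\n",
              x$patient_id, paste(dim(x$axial), collapse = "x"),
              paste(format(x$view_centre, digits = 4), collapse = ", ")))
  invisible(x)
}
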