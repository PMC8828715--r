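# Synthetic tumour phantoms: ellipsoidal, textured lesions in noisy volumes.

#' Construct a volume-with-mask object
#'
#' Bundles a 3D intensity array, a binary tumour ROI mask of identical shape,
#' and the physical voxel spacing in millimetres. All imaging operations in
#' the package consume this container.
#'
#' @param intensities 3D numeric array.
#' @param mask 3D logical (or 0/1) array, same shape as `intensities`; must
#'   contain at least one foreground voxel.
#' @param spacing Numeric length-3 vector of voxel spacing in mm, all > 0.
#' @param patient_id Character identifier.
#' @return An object of class `volume_mask`.
#' @export
volume_mask <- function(intensities, mask, spacing, patient_id = "P000") {
  if (length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(intensities), dim(mask)))
    stop("'intensities' and 'mask' must have identical dimensions",
         call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive numbers (mm)", call. = FALSE)
  structure(list(intensities = intensities, mask = mask, spacing = spacing,
                 patient_id = as.character(patient_id)),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask> %s: %s voxels, spacing (%s) mm, %d in ROI\n",
              x$patient_id, paste(dim(x$intensities), collapse = "x"),
              paste(format(x$spacing), collapse = ", "), sum(x$mask)))
  invisible(x)
}

#' Specify a synthetic tumour phantom
#'
#' Describes an ellipsoidal tumour embedded in a noisy volume: grid geometry,
#' lesion position and size in physical units, the amplitude of the
#' intra-tumour texture, and the storable intensity range.
#'
#' @param grid_shape Integer length-3: voxels per axis.
#' @param spacing Numeric length-3: mm per voxel along each axis.
#' @param semi_axes Numeric length-3: ellipsoid radii in mm (all > 0).
#' @param centre Numeric length-3: lesion centre in mm (voxel-centre, 0-based
#'   convention); defaults to the physical centre of the grid.
#' @param texture_scale Amplitude of the smooth intra-tumour intensity
#'   modulation, in the same (HU-like) units as the intensities.
#' @param background_noise_sd Standard deviation of the additive Gaussian
#'   noise present everywhere in the volume.
#' @param intensity_range Closed interval to which stored intensities are
#'   clipped; the default matches the view-normalisation contract.
#' @param base_intensity Mean intensity of tumour voxels before texture and
#'   noise are added.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L),
                         spacing = c(1, 1, 1),
                         semi_axes = c(10, 10, 10),
                         centre = NULL,
                         texture_scale = 150,
                         background_noise_sd = 20,
                         intensity_range = c(0, 4096),
                         base_intensity = 1000) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  semi_axes <- as.numeric(semi_axes)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("'grid_shape' must be three positive integers", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive numbers", call. = FALSE)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("'semi_axes' must be three positive numbers (mm)", call. = FALSE)
  extent <- (grid_shape - 1) * spacing
  if (is.null(centre)) centre <- extent / 2
  centre <- as.numeric(centre)
  if (length(centre) != 3L || any(centre < 0) || any(centre > extent))
    stop("'centre' must lie inside the volume's physical extent",
         call. = FALSE)
  if (length(intensity_range) != 2L ||
      intensity_range[1] >= intensity_range[2])
    stop("'intensity_range' must be an interval with lower < upper",
         call. = FALSE)
  for (ax in 1:3) {
    if (centre[ax] - semi_axes[ax] < 0 || centre[ax] + semi_axes[ax] > extent[ax])
      stop(sprintf("ellipsoid exceeds the grid extent along axis %d", ax),
           call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 semi_axes = semi_axes, centre = centre,
                 texture_scale = texture_scale,
                 background_noise_sd = background_noise_sd,
                 intensity_range = as.numeric(intensity_range),
                 base_intensity = base_intensity),
            class = "phantom_spec")
}

#' Generate a synthetic tumour phantom
#'
#' Voxelises the ellipsoid of a [phantom_spec()] (a voxel is foreground when
#' its centre lies strictly inside the ellipsoid), fills tumour voxels with
#' a base intensity plus a smooth, seeded sum of low-frequency sinusoids and
#' Gaussian noise, fills the background with noise only, and clips to the
#' storable intensity range. Identical `(spec, seed)` pairs yield
#' bit-identical volumes.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @param patient_id Character identifier for the result.
#' @return A [volume_mask()].
#' @export
generate_phantom <- function(spec, seed, patient_id = "P000") {
  stopifnot(inherits(spec, "phantom_spec"))
  stopifnot_scalar_number(seed, "seed")
  dims <- spec$grid_shape
  sp <- spec$spacing
  ax <- (seq_len(dims[1]) - 1) * sp[1]
  ay <- (seq_len(dims[2]) - 1) * sp[2]
  az <- (seq_len(dims[3]) - 1) * sp[3]
  # squared normalised distance to the ellipsoid centre, separable per axis
  dx2 <- ((ax - spec$centre[1]) / spec$semi_axes[1])^2
  dy2 <- ((ay - spec$centre[2]) / spec$semi_axes[2])^2
  dz2 <- ((az - spec$centre[3]) / spec$semi_axes[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  mask <- d2 < 1
  if (!any(mask))
    stop("ellipsoid contains no voxel centre; enlarge 'semi_axes'",
         call. = FALSE)
  vol <- with_seed(seed, {
    v <- array(stats::rnorm(prod(dims), 0, spec$background_noise_sd), dims)
    idx <- which(mask, arr.ind = TRUE)
    coords <- cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2],
                    (idx[, 3] - 1) * sp[3])
    # smooth texture: four seeded low-frequency sinusoids in physical space
    tex <- numeric(nrow(idx))
    for (m in 1:4) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      lambda <- stats::runif(1, 8, 20)           # wavelength in mm
      phase <- stats::runif(1, 0, 2 * pi)
      tex <- tex + sin(2 * pi * (coords %*% u) / lambda + phase)
    }
    v[mask] <- v[mask] + spec$base_intensity + spec$texture_scale * tex / 2
    v
  })
  vol <- pmin(pmax(vol, spec$intensity_range[1]), spec$intensity_range[2])
  volume_mask(vol, mask, sp, patient_id)
}
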