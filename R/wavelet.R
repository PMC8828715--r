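# Single-level 3D undecimated (stationary) wavelet decomposition with the
# Coiflet-1 filter pair, plus first-order and GLCM features per band.

# Coiflet-1 decomposition filters (low/high pass), length 6.
coif1_lo <- c(-0.015655728135791993, -0.07273261951252645,
               0.3848648468648578,    0.8525720202116004,
               0.3378976624574818,   -0.07273261951252645)
coif1_hi <- c( 0.07273261951252645,   0.3378976624574818,
              -0.8525720202116004,    0.3848648468648578,
               0.07273261951252645,  -0.015655728135791993)

# Circular (periodic) convolution of a 3D array with a 1D filter along one
# axis; the filter is centred at tap `offset` (0-based).
conv_axis_periodic <- function(arr, filt, axis, offset = 2L) {
  d <- dim(arr)
  n <- d[axis]
  out <- array(0, d)
  for (k in seq_along(filt)) {
    shift <- (k - 1L) - offset
    idx <- ((seq_len(n) - 1L + shift) %% n) + 1L
    sel <- lapply(1:3, function(a) if (a == axis) idx else seq_len(d[a]))
    out <- out + filt[k] * do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
  }
  out
}

#' Single-level stationary 3D wavelet decomposition
#'
#' Applies the Coiflet-1 analysis filter pair along each axis without
#' downsampling (periodic boundary), yielding the eight subbands LLL..HHH.
#' Because the transform is undecimated, every band is aligned with the
#' original voxel grid and the original ROI mask applies unchanged.
#'
#' @param arr 3D numeric array; every axis must be at least as long as the
#'   filter (6 taps).
#' @return Named list of eight 3D arrays (`LLL`, `LLH`, ..., `HHH`; the
#'   letters name the filter applied along axes 1, 2, 3 in order).
#' @export
swt3_bands <- function(arr) {
  d <- dim(arr)
  if (length(d) != 3L) stop("'arr' must be a 3D array", call. = FALSE)
  if (any(d < length(coif1_lo)))
    stop(sprintf("axis %d is shorter than the wavelet filter (%d voxels)",
                 which.min(d), length(coif1_lo)), call. = FALSE)
  bands <- list(arr)
  labels <- ""
  for (axis in 1:3) {
    nxt <- list()
    nxt_labels <- character(0)
    for (i in seq_along(bands)) {
      nxt[[length(nxt) + 1L]] <- conv_axis_periodic(bands[[i]], coif1_lo, axis)
      nxt_labels <- c(nxt_labels, paste0(labels[i], "L"))
      nxt[[length(nxt) + 1L]] <- conv_axis_periodic(bands[[i]], coif1_hi, axis)
      nxt_labels <- c(nxt_labels, paste0(labels[i], "H"))
    }
    bands <- nxt
    labels <- nxt_labels
  }
  names(bands) <- labels
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' Wavelet-band features of a tumour ROI
#'
#' Decomposes the full volume with [swt3_bands()] and computes, on each of the
#' eight subbands restricted to the original ROI mask, the 19 first-order and
#' 27 co-occurrence statistics, for 8 x 46 = 368 features.
#'
#' @param vm A [volume_mask()].
#' @param n_bins Grey-level count for the per-band GLCM and first-order
#'   histogram statistics.
#' @param offsets 3D offsets for the per-band GLCM.
#' @return Named numeric vector of length 368 (names prefixed
#'   `wavelet.<band>.`), with attribute `block = "HC"`.
#' @export
wavelet_features <- function(vm, n_bins = 32L, offsets = glcm_offsets_13()) {
  stopifnot(inherits(vm, "volume_mask"))
  bands <- swt3_bands(vm$intensities)
  out <- unlist(lapply(names(bands), function(nm) {
    b <- bands[[nm]]
    fo <- first_order_values(b[vm$mask], n_bins,
                             prefix = sprintf("wavelet.%s.fo", nm))
    P <- glcm_matrix(b, vm$mask, n_bins, offsets)
    gl <- glcm_stats(P, prefix = sprintf("wavelet.%s.glcm", nm))
    c(fo, gl)
  }))
  structure(out, block = "HC")
}
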