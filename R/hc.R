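# The full handcrafted feature catalogue: 19 + 17 + 27 + 8 x 46 = 431.

#' Default handcrafted extraction configuration
#'
#' @param n_bins Grey levels for GLCM and histogram statistics.
#' @param offsets 3D direction offsets for the GLCM.
#' @return A list of class `hc_config`.
#' @export
hc_config <- function(n_bins = 32L, offsets = glcm_offsets_13()) {
  structure(list(n_bins = as.integer(n_bins), offsets = offsets),
            class = "hc_config")
}

#' Extract the handcrafted radiomics feature vector
#'
#' Concatenates the first-order (19), shape (17), co-occurrence (27) and
#' wavelet-band (368) families into the package's fixed 431-feature
#' handcrafted catalogue. Names are unique and order-stable across runs.
#'
#' @param vm A [volume_mask()].
#' @param config An [hc_config()].
#' @return Named numeric vector of length 431 with attribute `block = "HC"`.
#' @export
extract_hc <- function(vm, config = hc_config()) {
  stopifnot(inherits(vm, "volume_mask"))
  out <- c(first_order(vm, config$n_bins),
           shape_features(vm),
           glcm_features(vm, config$n_bins, config$offsets),
           wavelet_features(vm, config$n_bins, config$offsets))
  if (anyDuplicated(names(out)))
    stop("internal error: duplicate handcrafted feature names", call. = FALSE)
  structure(out, block = "HC")
}

#' Extract handcrafted features for a list of volumes
#'
#' @param volumes List of [volume_mask()] objects.
#' @param config An [hc_config()].
#' @return Patients-by-features numeric matrix (431 columns), row names from
#'   patient ids, with attribute `block = "HC"`.
#' @export
extract_hc_cohort <- function(volumes, config = hc_config()) {
  rows <- lapply(volumes, extract_hc, config = config)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(volumes, function(v) v$patient_id, character(1))
  structure(m, block = "HC")
}
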