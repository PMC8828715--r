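# Deep-feature block contract over 2.5D views. The package ships a
# deterministic filter-bank extractor that honours the same per-view contract
# as a pooled CNN layer: each 224x224 view maps to `width` real numbers.

# Fixed oriented edge / blob / corner kernels (5x5), cycled before the seeded
# random projections so early features respond to interpretable structure.
base_kernels_5x5 <- function() {
  g <- function(v) matrix(v, 5, 5, byrow = TRUE)
  ramp <- matrix(rep(-2:2, each = 5), 5, 5)            # vertical edge
  list(
    edge_v = ramp,
    edge_h = t(ramp),
    edge_d1 = outer(-2:2, -2:2, function(a, b) (a + b) / 2),
    edge_d2 = outer(-2:2, -2:2, function(a, b) (a - b) / 2),
    blob = { d2 <- outer((-2:2)^2, (-2:2)^2, "+")       # Laplacian-of-Gaussian
             k <- (1 - d2 / 4) * exp(-d2 / 4); k - mean(k) },
    corner = outer(-2:2, -2:2, function(a, b) sign(a) * sign(b)),
    line_v = g(rep(c(-1, -1, 4, -1, -1), 5)),
    line_h = t(g(rep(c(-1, -1, 4, -1, -1), 5)))
  )
}

#' Deterministic filter-bank stand-in for a deep view extractor
#'
#' Builds a seeded bank of small convolution kernels — a fixed catalogue of
#' oriented edge, line, blob and corner detectors followed by seeded Gaussian
#' random projections — each applied to a 4x4 average-pooled view, rectified,
#' and globally average-pooled into one number. The result is a fully
#' deterministic drop-in for a pooled CNN layer: same seed, same kernels,
#' same outputs. Two stand-ins with different seeds give distinct feature
#' blocks (used for the transfer-learned vs fine-tuned blocks in synthetic
#' runs).
#'
#' @param seed Integer seed for the random kernels and biases.
#' @param width Number of features emitted per 2D view (default 2048, so the
#'   three multiplanar views concatenate to 6144).
#' @param name Extractor name used in feature identifiers.
#' @return An object of class `view_extractor`.
#' @export
filterbank_standin <- function(seed, width = 2048L, name = NULL) {
  width <- as.integer(width)
  if (width < 1L) stop("'width' must be >= 1", call. = FALSE)
  stopifnot_scalar_number(seed, "seed")
  base <- base_kernels_5x5()
  K <- with_seed(seed, {
    k <- matrix(stats::rnorm(25L * width, sd = 0.3), 25L, width)
    for (jj in seq_len(width)) {
      if (jj <= length(base)) k[, jj] <- as.vector(base[[jj]])
    }
    # unit-norm kernels so pooled responses are on a comparable scale
    sweep(k, 2, sqrt(colSums(k^2)), "/")
  })
  bias <- with_seed(seed + 1L, stats::runif(width, -20, 20))
  structure(list(name = name %||% sprintf("standin%d", as.integer(seed)),
                 width = width, seed = as.integer(seed),
                 kernels = K, bias = bias, kernel_size = 5L, pool = 8L),
            class = "view_extractor")
}

# f x f block-average pooling of a matrix whose sides are multiples of f.
block_pool <- function(a, f) {
  n1 <- nrow(a) %/% f
  n2 <- ncol(a) %/% f
  a <- a[seq_len(n1 * f), seq_len(n2 * f), drop = FALSE]
  a <- colSums(array(a, c(f, n1 * n2 * f))) / f     # pool rows
  a <- matrix(a, n1, n2 * f)
  a <- t(a)
  a <- colSums(array(a, c(f, n2 * n1))) / f         # pool columns
  t(matrix(a, n2, n1))
}

# im2col for valid 5x5 patches: (out1*out2) x 25 matrix.
im2col5 <- function(a) {
  o1 <- nrow(a) - 4L
  o2 <- ncol(a) - 4L
  cols <- matrix(0, o1 * o2, 25L)
  p <- 1L
  for (dc in 0:4) for (dr in 0:4) {
    cols[, p] <- as.vector(a[dr + seq_len(o1), dc + seq_len(o2)])
    p <- p + 1L
  }
  cols
}

# Apply a view_extractor to one 2D view: pool, convolve the bank, add bias,
# rectify, global average pool.
apply_extractor <- function(extractor, view) {
  pooled <- block_pool(view, extractor$pool)
  patches <- im2col5(pooled)
  z <- patches %*% extractor$kernels
  z <- z + matrix(extractor$bias, nrow(z), ncol(z), byrow = TRUE)
  colMeans(pmax(z, 0))
}

#' Extract a deep feature block from 2.5D views
#'
#' Applies a view extractor to the axial, sagittal and coronal views in that
#' fixed order and concatenates the outputs, giving `3 * width` features per
#' patient. Feature names encode the block tag, the view and the within-view
#' index.
#'
#' @param views A `multiplanar_views` object from [extract_views()].
#' @param extractor A `view_extractor`, e.g. [filterbank_standin()].
#' @param block Block tag for the resulting features (`"TL"` or `"FT"`).
#' @return Named numeric vector of length `3 * width` with attribute
#'   `block`.
#' @export
extract_deep <- function(views, extractor, block = "TL") {
  stopifnot(inherits(views, "multiplanar_views"),
            inherits(extractor, "view_extractor"))
  out <- lapply(c("axial", "sagittal", "coronal"), function(vn) {
    v <- apply_extractor(extractor, views[[vn]])
    if (length(v) != extractor$width)
      stop(sprintf("extractor '%s' emitted %d values for view '%s' (width %d)",
                   extractor$name, length(v), vn, extractor$width),
           call. = FALSE)
    names(v) <- sprintf("%s.%s.%04d", block, vn, seq_len(extractor$width))
    v
  })
  structure(unlist(out), block = block)
}

#' Extract a deep feature block for a cohort
#'
#' @param views_list List of `multiplanar_views`, one per patient.
#' @param extractor A `view_extractor`.
#' @param block Block tag (`"TL"` or `"FT"`).
#' @return Patients-by-features matrix with attribute `block`.
#' @export
extract_deep_cohort <- function(views_list, extractor, block = "TL") {
  rows <- lapply(views_list, extract_deep, extractor = extractor,
                 block = block)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(views_list, function(v) v$patient_id, character(1))
  structure(m, block = block)
}
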