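# Grey-level co-occurrence matrix texture features over the 3D ROI.

#' The 13 unique 3D direction offsets at distance 1
#'
#' One representative per opposite-direction pair of the 26-neighbourhood.
#'
#' @return A 13x3 integer matrix of voxel steps.
#' @export
glcm_offsets_13 <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

# Equal-width quantisation of ROI intensities into n_bins levels; voxels
# outside the mask are NA. A zero-range ROI collapses to level 1.
quantise_roi <- function(x, mask, n_bins) {
  q <- array(NA_integer_, dim(x))
  v <- x[mask]
  rng <- range(v)
  if (diff(rng) > 0) {
    q[mask] <- pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  } else {
    q[mask] <- 1L
  }
  q
}

# Accumulate symmetric co-occurrence counts over the offsets, restricted to
# voxel pairs that are both inside the ROI, and normalise to sum 1.
glcm_matrix <- function(x, mask, n_bins = 32L, offsets = glcm_offsets_13()) {
  d <- dim(x)
  q <- quantise_roi(x, mask, n_bins)
  counts <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    lo <- pmax(1L, 1L - off)
    hi <- pmin(d, d - off)
    if (any(hi < lo)) next
    src <- lapply(1:3, function(a) seq.int(lo[a], hi[a]))
    dst <- lapply(1:3, function(a) src[[a]] + off[a])
    A <- do.call(`[`, c(list(q), src, list(drop = FALSE)))
    B <- do.call(`[`, c(list(q), dst, list(drop = FALSE)))
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    tab <- tabulate((A[ok] - 1L) * n_bins + B[ok], n_bins * n_bins)
    counts <- counts + matrix(tab, n_bins, n_bins, byrow = TRUE)
  }
  counts <- counts + t(counts)
  total <- sum(counts)
  if (total == 0)
    stop("ROI has no voxel pairs for the given offsets (single-voxel ROI?)",
         call. = FALSE)
  counts / total
}

# Second-largest eigenvalue statistic (maximal correlation coefficient) of
# the Q matrix; degenerate matrices (fewer than two occupied levels) give 1.
glcm_mcc <- function(P) {
  px <- rowSums(P)
  keep <- px > 0
  if (sum(keep) < 2L) return(1)
  Ps <- P[keep, keep, drop = FALSE]
  pxs <- px[keep]
  # Q[i,j] = sum_k P[i,k] P[j,k] / (px[i] py[k]); marginals equal by symmetry
  W <- sweep(Ps, 2, pxs, "/")            # P[j,k]/py[k]
  Q <- sweep(Ps %*% t(W), 1, pxs, "/")   # row scale by 1/px[i]
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, min(1, ev[2])))
}

#' Grey-level co-occurrence features of a tumour ROI
#'
#' Quantises the ROI intensities into `n_bins` equal-width levels, accumulates
#' co-occurrence counts over the given 3D offsets restricted to in-ROI voxel
#' pairs, symmetrises and normalises the matrix to sum 1, and computes 27
#' Haralick-style statistics. Entropies use base-2 logarithms. The exact
#' catalogue (in order): angular second moment, energy, contrast, correlation,
#' variance, inverse difference moment, sum average, sum variance, sum
#' entropy, entropy, difference variance, difference entropy, the two
#' informational measures of correlation, maximal correlation coefficient,
#' autocorrelation, cluster shade, cluster prominence, cluster tendency,
#' dissimilarity, difference average, maximum probability, inverse variance,
#' inverse difference, and normalised inverse difference moment/difference
#' (IDMN, IDN), and joint average.
#'
#' @param vm A [volume_mask()].
#' @param n_bins Number of grey levels (>= 2).
#' @param offsets Integer matrix of 3D voxel steps (one row per direction).
#' @return Named numeric vector of length 27 (names prefixed `glcm.`), with
#'   attribute `block = "HC"`.
#' @export
glcm_features <- function(vm, n_bins = 32L, offsets = glcm_offsets_13()) {
  stopifnot(inherits(vm, "volume_mask"))
  if (n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  if (sum(vm$mask) < 2L)
    stop("ROI must contain at least 2 voxels", call. = FALSE)
  P <- glcm_matrix(vm$intensities, vm$mask, n_bins, offsets)
  glcm_stats(P)
}

# The 27 statistics from a normalised symmetric GLCM.
glcm_stats <- function(P, prefix = "glcm") {
  nb <- nrow(P)
  lvl <- seq_len(nb)
  i <- matrix(lvl, nb, nb)
  j <- t(i)
  px <- rowSums(P)                      # == colSums(P) by symmetry
  mu_x <- sum(lvl * px)
  var_x <- sum((lvl - mu_x)^2 * px)
  sd_x <- sqrt(var_x)
  log2p <- function(p) ifelse(p > 0, log2(p), 0)
  asm <- sum(P^2)
  entropy <- -sum(P * log2p(P))
  # sum and difference distributions
  ks <- 2:(2 * nb)
  p_sum <- vapply(ks, function(k) sum(P[(i + j) == k]), numeric(1))
  kd <- 0:(nb - 1)
  p_diff <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  sum_avg <- sum(ks * p_sum)
  sum_var <- sum((ks - sum_avg)^2 * p_sum)
  sum_ent <- -sum(p_sum * log2p(p_sum))
  diff_avg <- sum(kd * p_diff)
  diff_var <- sum((kd - diff_avg)^2 * p_diff)
  diff_ent <- -sum(p_diff * log2p(p_diff))
  # informational measures of correlation
  HX <- -sum(px * log2p(px))
  pxy <- outer(px, px)
  HXY1 <- -sum(P * log2p(pxy))
  HXY2 <- -sum(pxy * log2p(pxy))
  imc1 <- if (HX > 0) (entropy - HXY1) / HX else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * log(2) * (HXY2 - entropy))))
  correlation <- if (sd_x > 0)
    sum((i - mu_x) * (j - mu_x) * P) / var_x else 1
  od <- i != j
  vals <- c(
    asm = asm, energy = sqrt(asm),
    contrast = sum((i - j)^2 * P),
    correlation = correlation,
    variance = sum((i - mu_x)^2 * P),
    idm = sum(P / (1 + (i - j)^2)),
    sum_average = sum_avg, sum_variance = sum_var, sum_entropy = sum_ent,
    entropy = entropy,
    difference_variance = diff_var, difference_entropy = diff_ent,
    imc1 = imc1, imc2 = imc2,
    mcc = glcm_mcc(P),
    autocorrelation = sum(i * j * P),
    cluster_shade = sum((i + j - 2 * mu_x)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu_x)^4 * P),
    cluster_tendency = sum((i + j - 2 * mu_x)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    difference_average = diff_avg,
    maximum_probability = max(P),
    inverse_variance = sum(P[od] / (i[od] - j[od])^2),
    inverse_difference = sum(P / (1 + abs(i - j))),
    idmn = sum(P / (1 + ((i - j) / nb)^2)),
    idn = sum(P / (1 + abs(i - j) / nb)),
    joint_average = sum(i * P)
  )
  names(vals) <- paste(prefix, names(vals), sep = ".")
  structure(vals, block = "HC")
}
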