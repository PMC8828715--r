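# Independent reference implementations used to validate the package's
# vectorised code. Everything here is deliberately written as plain loops
# over definitions, sharing no code with the implementation under test.

# --- GLCM: explicit pair enumeration and scalar-loop statistics -----------

oracle_glcm_matrix <- function(x, mask, n_bins, offsets) {
  rng <- range(x[mask])
  d <- dim(x)
  q <- array(NA_integer_, d)
  for (i in which(mask)) {
    q[i] <- if (diff(rng) > 0)
      min(floor((x[i] - rng[1]) / diff(rng) * n_bins) + 1, n_bins) else 1L
  }
  C <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      a <- q[i, j, k]; b <- q[ii, jj, kk]
      if (is.na(a) || is.na(b)) next
      C[a, b] <- C[a, b] + 1
      C[b, a] <- C[b, a] + 1          # symmetrise as pairs are counted
    }
  }
  C / sum(C)
}

oracle_glcm_stats <- function(P) {
  nb <- nrow(P)
  px <- numeric(nb); for (i in 1:nb) px[i] <- sum(P[i, ])
  mu <- 0; for (i in 1:nb) mu <- mu + i * px[i]
  va <- 0; for (i in 1:nb) va <- va + (i - mu)^2 * px[i]
  lg <- function(v) if (v > 0) log2(v) else 0
  s <- list(asm = 0, contrast = 0, entropy = 0, idm = 0, maxp = 0,
            autoc = 0, dissim = 0, invdiff = 0, joint_avg = 0,
            shade = 0, prom = 0, tend = 0, corr = 0, variance = 0,
            invvar = 0, idmn = 0, idn = 0)
  for (i in 1:nb) for (j in 1:nb) {
    p <- P[i, j]
    s$asm <- s$asm + p^2
    s$contrast <- s$contrast + (i - j)^2 * p
    s$entropy <- s$entropy - p * lg(p)
    s$idm <- s$idm + p / (1 + (i - j)^2)
    s$maxp <- max(s$maxp, p)
    s$autoc <- s$autoc + i * j * p
    s$dissim <- s$dissim + abs(i - j) * p
    s$invdiff <- s$invdiff + p / (1 + abs(i - j))
    s$joint_avg <- s$joint_avg + i * p
    s$shade <- s$shade + (i + j - 2 * mu)^3 * p
    s$prom <- s$prom + (i + j - 2 * mu)^4 * p
    s$tend <- s$tend + (i + j - 2 * mu)^2 * p
    s$variance <- s$variance + (i - mu)^2 * p
    if (va > 0) s$corr <- s$corr + (i - mu) * (j - mu) * p / va
    if (i != j) s$invvar <- s$invvar + p / (i - j)^2
    s$idmn <- s$idmn + p / (1 + ((i - j) / nb)^2)
    s$idn <- s$idn + p / (1 + abs(i - j) / nb)
  }
  if (va == 0) s$corr <- 1
  # sum / difference distributions
  psum <- numeric(2 * nb); pdif <- numeric(nb)
  for (i in 1:nb) for (j in 1:nb) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  sa <- 0; for (k in 2:(2 * nb)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * nb)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * nb)) se <- se - psum[k] * lg(psum[k])
  da <- 0; for (k in 0:(nb - 1)) da <- da + k * pdif[k + 1]
  dv <- 0; for (k in 0:(nb - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  de <- 0; for (k in 0:(nb - 1)) de <- de - pdif[k + 1] * lg(pdif[k + 1])
  HX <- 0; for (i in 1:nb) HX <- HX - px[i] * lg(px[i])
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:nb) for (j in 1:nb) {
    HXY1 <- HXY1 - P[i, j] * lg(px[i] * px[j])
    HXY2 <- HXY2 - px[i] * px[j] * lg(px[i] * px[j])
  }
  imc1 <- if (HX > 0) (s$entropy - HXY1) / HX else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (HXY2 - s$entropy))))
  c(glcm.asm = s$asm, glcm.energy = sqrt(s$asm), glcm.contrast = s$contrast,
    glcm.correlation = s$corr, glcm.variance = s$variance, glcm.idm = s$idm,
    glcm.sum_average = sa, glcm.sum_variance = sv, glcm.sum_entropy = se,
    glcm.entropy = s$entropy, glcm.difference_variance = dv,
    glcm.difference_entropy = de, glcm.imc1 = imc1, glcm.imc2 = imc2,
    glcm.autocorrelation = s$autoc, glcm.cluster_shade = s$shade,
    glcm.cluster_prominence = s$prom, glcm.cluster_tendency = s$tend,
    glcm.dissimilarity = s$dissim, glcm.difference_average = da,
    glcm.maximum_probability = s$maxp, glcm.inverse_variance = s$invvar,
    glcm.inverse_difference = s$invdiff, glcm.idmn = s$idmn,
    glcm.idn = s$idn, glcm.joint_average = s$joint_avg)
}

# --- mRMR: table()-based greedy MID ---------------------------------------

oracle_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] / n *
        log(tab[i, j] * n / (sum(tab[i, ]) * sum(tab[, j])))
  }
  mi
}

oracle_discretise <- function(x) {
  out <- matrix(2L, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    mu <- mean(x[, j]); s <- sd(x[, j])
    out[x[, j] < mu - s, j] <- 1L
    out[x[, j] > mu + s, j] <- 3L
  }
  out
}

oracle_mrmr <- function(x, y, k) {
  D <- oracle_discretise(x)
  y <- as.integer(factor(y))
  p <- ncol(x)
  rel <- sapply(seq_len(p), function(j) oracle_mi(D[, j], y))
  sel <- integer(0)
  for (step in seq_len(k)) {
    best <- -Inf; who <- NA
    for (j in seq_len(p)) {
      if (j %in% sel) next
      red <- if (length(sel)) mean(sapply(sel, function(s2)
        oracle_mi(D[, j], D[, s2]))) else 0
      sc <- rel[j] - red
      if (sc > best + 1e-12) { best <- sc; who <- j }
    }
    sel <- c(sel, who)
  }
  sel
}

# --- enrichment: direct running-sum / KS statistic ------------------------

oracle_es <- function(genes, metric, set, p = 0) {
  N <- length(genes)
  hits <- genes %in% set
  w <- abs(metric)^p
  sw <- sum(w[hits])
  if (sw == 0) { w[] <- 1; sw <- sum(w[hits]) }
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- if (hits[i]) run + w[i] / sw else run - 1 / (N - sum(hits))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# --- wavelet: direct separable periodic convolution -----------------------

oracle_conv3 <- function(arr, f1, f2, f3, offset = 2) {
  d <- dim(arr)
  L <- length(f1)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in 1:L) for (b in 1:L) for (cc in 1:L) {
      ii <- ((i - 1 + a - 1 - offset) %% d[1]) + 1
      jj <- ((j - 1 + b - 1 - offset) %% d[2]) + 1
      kk <- ((k - 1 + cc - 1 - offset) %% d[3]) + 1
      acc <- acc + f1[a] * f2[b] * f3[cc] * arr[ii, jj, kk]
    }
    out[i, j, k] <- acc
  }
  out
}
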