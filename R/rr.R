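# Radiogenomics relationship (RR) calling: Spearman correlation between
# signature features and gene expression, counting/overlap summaries, and
# directional strength comparison.

# Spearman rho and t-approximation p-values between the columns of a
# patients-by-features matrix and the rows of a genes-by-patients matrix.
# Zero-variance features or genes give NA with a warning.
spearman_matrix <- function(features, expr) {
  features <- as.matrix(features)
  expr <- as.matrix(expr)
  n <- nrow(features)
  if (n < 5L) stop("need at least 5 patients", call. = FALSE)
  if (ncol(expr) != n)
    stop("patient counts of features and expression disagree", call. = FALSE)
  if (!is.null(rownames(features)) && !is.null(colnames(expr)) &&
      !identical(rownames(features), colnames(expr)))
    stop("patient orders of features and expression disagree", call. = FALSE)
  rf <- apply(features, 2, rank)           # average ranks handle ties
  re <- apply(expr, 1, rank)               # patients x genes
  sd_f <- apply(rf, 2, stats::sd)
  sd_e <- apply(re, 2, stats::sd)
  bad_f <- sd_f == 0
  bad_e <- sd_e == 0
  if (any(bad_f) || any(bad_e))
    warning(sprintf("skipping %d zero-variance feature(s) and %d gene(s): rho undefined",
                    sum(bad_f), sum(bad_e)), call. = FALSE)
  zf <- scale(rf)
  ze <- scale(re)
  rho <- crossprod(zf, ze) / (n - 1)
  rho[bad_f, ] <- NA_real_
  rho[, bad_e] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) == 1] <- 0
  dimnames(rho) <- dimnames(p) <- list(colnames(features), rownames(expr))
  list(rho = rho, p = p, n = n)
}

#' Call radiogenomics relationships by Spearman correlation
#'
#' Correlates every (signature feature, gene) pair with the Spearman rank
#' correlation (average ranks; p-values from the t approximation with n - 2
#' degrees of freedom) and retains the pairs with `p < alpha` as RRs.
#'
#' @param features Patients-by-signature-features numeric matrix.
#' @param expr Genes-by-patients expression matrix, patients in the same
#'   order.
#' @param alpha Significance threshold on the raw p-value (default 0.001, no
#'   multiple-testing correction). Set attribute note: an optional
#'   Benjamini-Hochberg mode is available via `adjust = "BH"`.
#' @param adjust `"none"` (default) or `"BH"` to threshold on FDR-adjusted
#'   p-values instead.
#' @param source Signature provenance tag recorded on the table.
#' @return A data frame of class `rr_table` with columns `feature_id`,
#'   `gene`, `rho`, `p`, `direction` (`positive`/`inverse`), and attributes
#'   `rho_matrix`, `p_matrix`, `n`, `alpha`, `source`.
#' @export
spearman_rr <- function(features, expr, alpha = 0.001, adjust = c("none", "BH"),
                        source = "FF") {
  adjust <- match.arg(adjust)
  sm <- spearman_matrix(features, expr)
  pv <- sm$p
  if (adjust == "BH") {
    ok <- !is.na(pv)
    pv[ok] <- stats::p.adjust(pv[ok], method = "BH")
  }
  hit <- which(!is.na(pv) & pv < alpha, arr.ind = TRUE)
  tab <- data.frame(
    feature_id = rownames(pv)[hit[, 1]],
    gene = colnames(pv)[hit[, 2]],
    rho = sm$rho[hit],
    p = pv[hit],
    stringsAsFactors = FALSE
  )
  tab$direction <- ifelse(tab$rho >= 0, "positive", "inverse")
  tab <- tab[order(tab$p, tab$feature_id, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("rr_table", "data.frame"),
            rho_matrix = sm$rho, p_matrix = sm$p, n = sm$n,
            alpha = alpha, source = source)
}

#' Count RRs and partition genes across signatures
#'
#' For each signature's RR table reports the number of RR rows and unique
#' genes; across signatures, partitions the union of RR genes into exclusive
#' and shared Venn regions (up to 4 signatures).
#'
#' @param tables Named list of `rr_table` objects.
#' @return List with `counts` (data frame: signature, n_rr, n_genes) and
#'   `regions` (named integer vector; names are `+`-joined signature
#'   combinations).
#' @export
rr_summary <- function(tables) {
  if (!length(tables)) stop("need at least one RR table", call. = FALSE)
  if (length(tables) > 4L)
    stop("gene overlap regions support at most 4 signatures", call. = FALSE)
  gene_sets <- lapply(tables, function(t) unique(t$gene))
  counts <- data.frame(
    signature = names(tables),
    n_rr = vapply(tables, nrow, integer(1)),
    n_genes = vapply(gene_sets, length, integer(1)),
    row.names = NULL
  )
  universe <- unique(unlist(gene_sets))
  membership <- vapply(gene_sets, function(g) universe %in% g,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  nm <- names(tables)
  regions <- integer(0)
  for (size in seq_along(nm)) {
    for (combo in utils::combn(seq_along(nm), size, simplify = FALSE)) {
      inside <- rowSums(membership[, combo, drop = FALSE]) == length(combo)
      outside <- rowSums(membership[, -combo, drop = FALSE]) == 0
      if (!length(setdiff(seq_along(nm), combo))) outside <- TRUE
      regions[paste(nm[combo], collapse = "+")] <- sum(inside & outside)
    }
  }
  list(counts = counts, regions = regions)
}

# One-sided Welch t-test ("x stronger than y"); equal constant samples give
# t = 0, p = 0.5 rather than an error.
welch_greater <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (nx < 2L || ny < 2L || !is.finite(vx) || !is.finite(vy)) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  }
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    d <- mean(x) - mean(y)
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = nx + ny - 2,
                p = if (d > 0) 0 else if (d < 0) 1 else 0.5))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = stats::pt(tstat, df, lower.tail = FALSE))
}

#' Compare RR strengths between two signatures, per direction
#'
#' Splits each RR table by correlation direction and applies a one-sided
#' Welch two-sample t-test on |rho| within each stratum, testing whether the
#' first signature's RRs are stronger than the second's. A direction with an
#' empty stratum in either table is reported as untestable.
#'
#' @param a,b `rr_table` objects (e.g. the fused signature vs a single-block
#'   signature).
#' @return Data frame with one row per direction: `direction`, `n_a`, `n_b`,
#'   `t`, `df`, `p`, `testable`.
#' @export
compare_strengths <- function(a, b) {
  out <- lapply(c("positive", "inverse"), function(dir) {
    xa <- abs(a$rho[a$direction == dir])
    xb <- abs(b$rho[b$direction == dir])
    if (!length(xa) || !length(xb)) {
      data.frame(direction = dir, n_a = length(xa), n_b = length(xb),
                 t = NA_real_, df = NA_real_, p = NA_real_,
                 testable = FALSE)
    } else {
      w <- welch_greater(xa, xb)
      data.frame(direction = dir, n_a = length(xa), n_b = length(xb),
                 t = w$t, df = w$df, p = w$p,
                 testable = is.finite(w$p))
    }
  })
  do.call(rbind, out)
}
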