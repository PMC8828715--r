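# Probe collapsing and quartile gene filtering.

#' Collapse probe-level expression to gene level
#'
#' Probes mapping to zero or to two or more distinct gene symbols are
#' discarded; the remaining probes of each gene are averaged per patient.
#' Gene order follows the first appearance of each symbol among the retained
#' probes.
#'
#' @param probe_matrix Probes-by-patients numeric matrix with probe row
#'   names.
#' @param probe_map Data frame with columns `probe_id` and `gene` (one row
#'   per mapping; probes may appear several times).
#' @return Genes-by-patients numeric matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  probe_matrix <- as.matrix(probe_matrix)
  if (is.null(rownames(probe_matrix)))
    stop("'probe_matrix' must have probe row names", call. = FALSE)
  stopifnot(all(c("probe_id", "gene") %in% names(probe_map)))
  map <- unique(probe_map[, c("probe_id", "gene")])
  n_genes <- tapply(map$gene, map$probe_id, function(g) length(unique(g)))
  unambiguous <- names(n_genes)[n_genes == 1L]
  map <- map[map$probe_id %in% unambiguous, , drop = FALSE]
  keep <- rownames(probe_matrix) %in% map$probe_id
  if (!any(keep))
    stop("no probe maps to exactly one gene symbol", call. = FALSE)
  m <- probe_matrix[keep, , drop = FALSE]
  gene_of <- map$gene[match(rownames(m), map$probe_id)]
  gene_levels <- unique(gene_of)
  g <- factor(gene_of, levels = gene_levels)
  counts <- as.integer(table(g))
  out <- rowsum(m, g) / counts
  rownames(out) <- gene_levels
  out
}

gene_entropy <- function(v, n_bins = 16L) {
  rng <- range(v)
  if (diff(rng) == 0) return(0)
  b <- pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  p <- tabulate(b, n_bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Quartile gene filtering
#'
#' Applies three sequential filters, each recomputing its quantile threshold
#' on the current survivors: (1) drop genes with cross-patient variance
#' strictly below the `q` quantile of variances; (2) drop genes whose mean
#' absolute expression is strictly below the `q` quantile; (3) drop genes
#' whose histogram entropy (16 equal-width bins over each gene's own range;
#' a zero-range gene has entropy 0) is strictly below the `q` quantile.
#'
#' @param e Genes-by-patients numeric matrix with gene row names.
#' @param q Quantile cut per filter (default one quarter).
#' @param n_bins Histogram bins for the entropy filter.
#' @return List with `expression` (surviving genes, original order),
#'   `removed` (named removal counts per stage) and `n_input` / `n_kept`.
#' @export
filter_genes <- function(e, q = 0.25, n_bins = 16L) {
  e <- as.matrix(e)
  if (ncol(e) < 2L) stop("need at least 2 patients", call. = FALSE)
  if (nrow(e) < 4L) stop("need at least 4 genes", call. = FALSE)
  n_input <- nrow(e)
  stages <- list(
    variance = function(m) apply(m, 1, stats::var),
    expression = function(m) abs(rowMeans(m)),
    entropy = function(m) apply(m, 1, gene_entropy, n_bins = n_bins)
  )
  removed <- stats::setNames(integer(length(stages)), names(stages))
  for (nm in names(stages)) {
    vals <- stages[[nm]](e)
    thr <- stats::quantile(vals, q, names = FALSE)
    keep <- vals >= thr
    removed[nm] <- sum(!keep)
    e <- e[keep, , drop = FALSE]
    if (nrow(e) < 4L)
      stop(sprintf("fewer than 4 genes survive the %s filter", nm),
           call. = FALSE)
  }
  list(expression = e, removed = removed, n_input = n_input,
       n_kept = nrow(e))
}
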