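# Patient stratification by signature and association with tumour T stage.

t_stage_levels <- c("Tis", "T1", "T2", "T3", "T4")

#' Assemble and validate a clinical table
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param histology Histology class per patient (`squamous`, `adeno`,
#'   `other`).
#' @param t_stage Primary tumour T stage per patient, from
#'   `Tis, T1, T2, T3, T4`.
#' @return A data frame of class `clinical_table` with `t_stage` as an
#'   ordered factor.
#' @export
clinical_table <- function(patient_id, histology, t_stage) {
  if (anyDuplicated(patient_id))
    stop("patient ids must be unique", call. = FALSE)
  if (!all(t_stage %in% t_stage_levels))
    stop("t_stage values must be in Tis, T1..T4", call. = FALSE)
  out <- data.frame(patient_id = as.character(patient_id),
                    histology = factor(histology,
                                       levels = c("squamous", "adeno",
                                                  "other")),
                    t_stage = factor(t_stage, levels = t_stage_levels,
                                     ordered = TRUE))
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Cluster patients on a feature signature
#'
#' Runs k-means on the column-wise z-scored signature matrix, keeping the
#' best of `restarts` seeded initialisations by within-cluster sum of
#' squares. Labels are deterministic given the seed and invariant to feature
#' order.
#'
#' @param sig_matrix Patients-by-signature-features numeric matrix.
#' @param k Number of clusters (default 3).
#' @param restarts Number of random initial centroid sets (default 10).
#' @param max_iter Iteration cap per start (default 1000).
#' @param seed Integer seed.
#' @return Integer cluster labels named by patient, with the fitted
#'   `stats::kmeans` object in attribute `fit`.
#' @export
cluster_patients <- function(sig_matrix, k = 3L, restarts = 10L,
                             max_iter = 1000L, seed = 1L) {
  sig_matrix <- as.matrix(sig_matrix)
  if (ncol(sig_matrix) == 0L)
    stop("signature not generated", call. = FALSE)
  if (k > nrow(sig_matrix))
    stop("'k' cannot exceed the number of patients", call. = FALSE)
  z <- zscore_columns(sig_matrix, warn = FALSE)
  # order columns by name so the outcome ignores feature ordering
  z <- z[, order(colnames(z) %||% seq_len(ncol(z))), drop = FALSE]
  if (k == nrow(z)) {
    # degenerate case: every patient is its own cluster with zero WCSS
    fit <- list(cluster = seq_len(k), centers = z, totss = sum(scale(z,
                scale = FALSE)^2), withinss = rep(0, k), tot.withinss = 0)
  } else {
    fit <- with_seed(seed,
                     stats::kmeans(z, centers = k, nstart = restarts,
                                   iter.max = max_iter))
  }
  labels <- stats::setNames(fit$cluster, rownames(sig_matrix))
  attr(labels, "fit") <- fit
  labels
}

#' Chi-square test of cluster/T-stage independence
#'
#' Builds the clusters-by-observed-stages contingency table (empty stage or
#' cluster categories are dropped before computing degrees of freedom) and
#' applies Pearson's chi-square test of independence without continuity
#' correction.
#'
#' @param labels Cluster labels, one per patient.
#' @param clinical A [clinical_table()] (or data frame with a `t_stage`
#'   column) in the same patient order.
#' @return List with `statistic`, `df`, `p_value` and the contingency
#'   `table`.
#' @export
chi2_stage_association <- function(labels, clinical) {
  stage <- if (is.data.frame(clinical)) clinical$t_stage else clinical
  if (length(labels) != length(stage))
    stop("'labels' and 'clinical' must cover the same patients",
         call. = FALSE)
  tab <- table(cluster = labels, stage = factor(stage))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table is degenerate (need >= 2 clusters and >= 2 observed stages)",
         call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), table = tab)
}

#' Per-feature z-score table for signature heatmaps
#'
#' Standardises each signature feature across patients (`(x - mean) / sd`);
#' zero-variance features become all-zero columns with a warning. When
#' cluster labels are supplied, rows are ordered by cluster for heatmap
#' rendering.
#'
#' @param sig_matrix Patients-by-features numeric matrix.
#' @param labels Optional cluster labels used to order the rows.
#' @return Numeric matrix of z-scores (same column order as the input), with
#'   attribute `cluster` when labels were supplied.
#' @export
zscore_table <- function(sig_matrix, labels = NULL) {
  sig_matrix <- as.matrix(sig_matrix)
  if (nrow(sig_matrix) < 2L)
    stop("need at least 2 patients", call. = FALSE)
  z <- zscore_columns(sig_matrix, warn = TRUE)
  if (!is.null(labels)) {
    ord <- order(labels)
    z <- z[ord, , drop = FALSE]
    attr(z, "cluster") <- labels[ord]
  }
  z
}
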