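# Pre-ranked gene-set enrichment: weighted running-sum enrichment score,
# gene-subset permutation null, sign-matched NES, and signature-level
# aggregation across features.

#' Build a ranked gene list from signed correlations
#'
#' Sorts genes by signed Spearman rho, descending; ties are broken by
#' lexicographic gene symbol so the ordering is deterministic. Undefined
#' (NA) entries are dropped with a warning.
#'
#' @param rho_vector Named numeric vector: gene -> signed rho for one
#'   signature feature.
#' @param feature_id Identifier of the source feature.
#' @param min_genes Minimum ranked-universe size (default 15).
#' @return An object of class `ranked_genes` with `genes`, `metric` and
#'   `feature_id`.
#' @export
rank_genes <- function(rho_vector, feature_id = NA_character_,
                       min_genes = 15L) {
  if (is.null(names(rho_vector)))
    stop("'rho_vector' must be named by gene", call. = FALSE)
  if (anyNA(rho_vector)) {
    warning(sprintf("dropping %d gene(s) with undefined rho",
                    sum(is.na(rho_vector))), call. = FALSE)
    rho_vector <- rho_vector[!is.na(rho_vector)]
  }
  if (anyDuplicated(names(rho_vector)))
    stop("duplicate gene symbols in 'rho_vector'", call. = FALSE)
  if (length(rho_vector) < min_genes)
    stop(sprintf("ranked universe has %d genes; at least %d required",
                 length(rho_vector), min_genes), call. = FALSE)
  ord <- order(-rho_vector, names(rho_vector))
  structure(list(genes = names(rho_vector)[ord],
                 metric = unname(rho_vector[ord]),
                 feature_id = feature_id),
            class = "ranked_genes")
}

#' Weighted running-sum enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov statistic: walking down the ranked
#' list, hits increment the running sum by `|metric|^p / sum_hits |metric|^p`
#' and misses decrement it by `1 / (N - n_hits)`; the enrichment score is the
#' running-sum value of maximal absolute deviation (signed). If every hit has
#' zero metric the hit weights fall back to equal weights.
#'
#' @param rl A [rank_genes()] object.
#' @param gene_set Character vector of gene symbols.
#' @param p Weight exponent (default 1; `p = 0` gives the unweighted KS
#'   statistic).
#' @return List with `es`, the full `running` sum, and the logical `hits`
#'   vector.
#' @export
enrichment_score <- function(rl, gene_set, p = 1) {
  stopifnot(inherits(rl, "ranked_genes"))
  hits <- rl$genes %in% gene_set
  nh <- sum(hits)
  N <- length(rl$genes)
  if (nh == 0L) stop("gene set does not intersect the ranked universe",
                     call. = FALSE)
  if (nh == N) stop("gene set covers the entire ranked universe",
                    call. = FALSE)
  w <- abs(rl$metric)^p
  wh <- w * hits
  if (sum(wh) == 0) wh <- as.numeric(hits)   # all-zero hit metrics
  step <- ifelse(hits, wh / sum(wh), -1 / (N - nh))
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hits = hits)
}

# Enrichment score from sorted hit positions only (no full running sum);
# used by the permutation null. Matches enrichment_score() on the same
# positions/weights.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  wh <- w[pos]
  W <- sum(wh)
  if (W == 0) { wh <- rep(1, k); W <- k }
  cum <- cumsum(wh) / W
  miss <- 1 / (N - k)
  after <- cum - (pos - seq_len(k)) * miss
  before <- c(0, cum[-k]) - (pos - 1 - (seq_len(k) - 1)) * miss
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Permutation-normalised enrichment score
#'
#' Draws `n_perm` random gene subsets of the same size from the ranked
#' universe, computes their enrichment scores, and normalises the observed
#' score by the mean |null ES| of the null scores sharing its sign. The
#' permutation p-value is the add-one-smoothed fraction of same-sign null
#' scores at least as extreme as the observed one.
#'
#' @param rl A [rank_genes()] object.
#' @param gene_set Character vector of gene symbols.
#' @param n_perm Number of null draws (>= 100).
#' @param seed Integer seed.
#' @param p Weight exponent passed to [enrichment_score()].
#' @param set_id Label recorded on the result.
#' @return An `enrichment_result`: list with `set_id`, `es`, `nes`,
#'   `p_value`, `size` (set size after intersection with the universe),
#'   `n_perm` and `nes_defined` (FALSE when no same-sign null score exists).
#' @export
normalise_es <- function(rl, gene_set, n_perm = 1000L, seed = 1L, p = 1,
                         set_id = NA_character_) {
  if (n_perm < 100L) stop("'n_perm' must be >= 100", call. = FALSE)
  obs <- enrichment_score(rl, gene_set, p)
  nh <- sum(obs$hits)
  N <- length(rl$genes)
  w <- abs(rl$metric)^p
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      es_from_positions(sort.int(sample.int(N, nh)), w, N)
    }, numeric(1))
  })
  same <- if (obs$es >= 0) null_es[null_es > 0] else null_es[null_es < 0]
  if (!length(same)) {
    return(structure(list(set_id = set_id, es = obs$es, nes = NA_real_,
                          p_value = NA_real_, size = nh, n_perm = n_perm,
                          nes_defined = FALSE),
                     class = "enrichment_result"))
  }
  nes <- obs$es / mean(abs(same))
  pval <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  structure(list(set_id = set_id, es = obs$es, nes = nes, p_value = pval,
                 size = nh, n_perm = n_perm, nes_defined = TRUE),
            class = "enrichment_result")
}

#' Signature-level gene-set enrichment report
#'
#' For each signature feature, builds the ranked gene list restricted to the
#' genes with a significant RR for that feature (`p < alpha_rr`); when fewer
#' than `min_genes` such genes exist, the full ranking is used instead and
#' flagged. Gene sets are filtered to sizes within `size_bounds` after
#' intersection with the ranked universe, then scored with [normalise_es()].
#' A gene set "has an RR with the signature" when its permutation p-value is
#' below `alpha_go` for at least one feature; its reported NES is the
#' extreme-|NES| value over features.
#'
#' @param rho_matrix Features-by-genes matrix of signed Spearman rho.
#' @param p_matrix Matching matrix of RR p-values.
#' @param gene_sets Named list of gene symbol vectors.
#' @param size_bounds Allowed set size interval after intersection (default
#'   `c(15, 500)`).
#' @param alpha_rr RR significance threshold for restricting the ranking.
#' @param alpha_go Permutation significance threshold per gene set.
#' @param n_perm Null draws per (feature, set) score.
#' @param seed Integer seed (per-score seeds are derived from it).
#' @param weight_p Weight exponent of the running-sum statistic.
#' @param min_genes Minimum ranked-universe size before falling back to the
#'   full ranking.
#' @return List with `generated`, `results` (one row per scored
#'   feature-set pair), `per_set` (aggregated per gene set: significance,
#'   extreme NES, contributing feature) and `n_significant`.
#' @export
signature_enrichment <- function(rho_matrix, p_matrix, gene_sets,
                                 size_bounds = c(15L, 500L),
                                 alpha_rr = 0.001, alpha_go = 0.05,
                                 n_perm = 1000L, seed = 1L, weight_p = 1,
                                 min_genes = 15L) {
  if (is.null(dim(rho_matrix)) || nrow(rho_matrix) == 0L)
    return(list(generated = FALSE, results = NULL, per_set = NULL,
                n_significant = 0L))
  if (!length(gene_sets)) stop("no gene sets supplied", call. = FALSE)
  rows <- list()
  for (f in rownames(rho_matrix)) {
    rho <- rho_matrix[f, ]
    pv <- p_matrix[f, ]
    ok <- !is.na(rho)
    sig_genes <- names(rho)[ok & !is.na(pv) & pv < alpha_rr]
    fallback <- length(sig_genes) < min_genes
    universe <- if (fallback) names(rho)[ok] else sig_genes
    rl <- rank_genes(rho[universe], feature_id = f, min_genes = min_genes)
    for (s in names(gene_sets)) {
      size <- sum(gene_sets[[s]] %in% rl$genes)
      if (size < size_bounds[1] || size > size_bounds[2] ||
          size >= length(rl$genes)) next
      er <- normalise_es(rl, gene_sets[[s]], n_perm = n_perm,
                         seed = derive_seed(seed, paste(f, s)),
                         p = weight_p, set_id = s)
      rows[[length(rows) + 1L]] <-
        data.frame(set_id = s, feature_id = f, es = er$es, nes = er$nes,
                   p_value = er$p_value, size = er$size,
                   fallback_full_ranking = fallback,
                   nes_defined = er$nes_defined)
    }
  }
  if (!length(rows))
    return(list(generated = TRUE, results = NULL, per_set = NULL,
                n_significant = 0L))
  results <- do.call(rbind, rows)
  per_set <- do.call(rbind, lapply(split(results, results$set_id),
                                   function(d) {
    vals <- abs(d$nes)
    vals[!d$nes_defined | is.na(vals)] <- -Inf
    best <- d[which.max(vals), ]
    data.frame(set_id = best$set_id,
               nes = best$nes,
               feature_id = best$feature_id,
               min_p = min(d$p_value, na.rm = TRUE),
               significant = any(d$p_value < alpha_go, na.rm = TRUE))
  }))
  rownames(per_set) <- NULL
  list(generated = TRUE, results = results, per_set = per_set,
       n_significant = sum(per_set$significant))
}
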