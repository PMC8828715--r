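# Feature fusion and the three-stage signature selection chain:
# MAD filter -> mRMR -> cross-validated multinomial LASSO.

#' Construct a fused feature matrix
#'
#' @param x Patients-by-features numeric matrix with row and column names.
#' @param block Character vector of per-column block tags (`HC`, `TL`, `FT`).
#' @return An object of class `fused_features` with elements `x` and `block`.
#' @export
fused_features <- function(x, block) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || is.null(rownames(x)))
    stop("feature matrix must have row (patient) and column (feature) names",
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate feature names", call. = FALSE)
  if (length(block) == 1L) block <- rep(block, ncol(x))
  if (length(block) != ncol(x))
    stop("'block' must tag every column", call. = FALSE)
  if (!all(block %in% c("HC", "TL", "FT")))
    stop("block tags must be HC, TL or FT", call. = FALSE)
  if (any(!is.finite(x)))
    stop("feature matrix contains missing or non-finite values",
         call. = FALSE)
  structure(list(x = x, block = stats::setNames(block, colnames(x))),
            class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  tab <- table(x$block)
  cat(sprintf("<fused_features> %d patients x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

ff_subset <- function(ff, cols) {
  fused_features(ff$x[, cols, drop = FALSE], unname(ff$block[cols]))
}

#' Fuse feature blocks by column-wise concatenation
#'
#' Concatenates per-patient feature tables (e.g. the 431 handcrafted, 6144
#' transfer-learned and 6144 fine-tuned columns into a single
#' 12,719-dimensional matrix), preserving block provenance tags.
#'
#' @param blocks Named list of patients-by-features matrices; names are used
#'   as block tags unless a matrix carries a `block` attribute.
#' @return A [fused_features()] object.
#' @export
fuse <- function(blocks) {
  if (!length(blocks)) stop("no blocks to fuse", call. = FALSE)
  mats <- lapply(blocks, as.matrix)
  ids <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(rownames(m), ids))
      stop("blocks disagree on the patient set or order", call. = FALSE)
  }
  tags <- unlist(lapply(seq_along(mats), function(i) {
    tag <- attr(blocks[[i]], "block") %||% names(blocks)[i]
    rep(tag, ncol(mats[[i]]))
  }))
  x <- do.call(cbind, mats)
  fused_features(x, tags)
}

#' Drop low-dispersion features by median absolute deviation
#'
#' Computes each feature's MAD about the median across patients (unscaled)
#' and removes features whose MAD falls strictly below the `drop_quantile`
#' quantile of the MAD distribution; zero-MAD (constant) features are always
#' removed.
#'
#' @param ff A [fused_features()] object.
#' @param drop_quantile Fraction of the MAD distribution to cut (default
#'   bottom quartile).
#' @return A [fused_features()] object of the surviving columns, with a
#'   `trace` attribute recording input/output counts.
#' @export
mad_filter <- function(ff, drop_quantile = 0.25) {
  stopifnot(inherits(ff, "fused_features"))
  if (nrow(ff$x) < 2L) stop("need at least 2 patients", call. = FALSE)
  mads <- apply(ff$x, 2, function(v) stats::median(abs(v - stats::median(v))))
  thr <- stats::quantile(mads, drop_quantile, names = FALSE)
  keep <- mads >= thr & mads > 0
  if (!any(keep))
    stop("MAD filter removed every feature; lower 'drop_quantile'",
         call. = FALSE)
  out <- ff_subset(ff, which(keep))
  attr(out, "trace") <- list(n_input = ncol(ff$x), n_kept = sum(keep),
                             mad_threshold = thr)
  out
}

# Discretise each column into 3 states at mean +/- sd.
discretise3 <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  lo <- mu - sd
  hi <- mu + sd
  D <- matrix(2L, nrow(x), ncol(x))
  D[x < rep(lo, each = nrow(x))] <- 1L
  D[x > rep(hi, each = nrow(x))] <- 3L
  D
}

# Mutual information (nats) between a discrete vector g (states 1..3) and
# every column of the indicator list I3 (I3[[b]][i, j] = D[i,j] == b).
mi_against_vector <- function(I3, g, col_totals, n) {
  p <- ncol(I3[[1]])
  mi <- numeric(p)
  for (a in 1:3) {
    rows <- which(g == a)
    ra <- length(rows)
    if (ra == 0L) next
    for (b in 1:3) {
      cb <- col_totals[[b]]
      cab <- if (length(rows) == 1L) as.numeric(I3[[b]][rows, ])
             else colSums(I3[[b]][rows, , drop = FALSE])
      ok <- cab > 0 & cb > 0
      mi[ok] <- mi[ok] +
        (cab[ok] / n) * log(cab[ok] * n / (ra * cb[ok]))
    }
  }
  mi
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Discretises each feature into three states at mean +/- one standard
#' deviation, then greedily selects `k` features by the mutual-information
#' difference (MID) criterion: at each step the candidate maximising
#' `MI(feature; label) - mean MI(feature; already selected)` is added. Ties
#' are broken by original column order, so the procedure is deterministic.
#'
#' @param ff A [fused_features()] object.
#' @param histology Factor (or coercible) class label per patient with at
#'   least 2 observed classes.
#' @param k Number of features to select; if `k` exceeds the number of
#'   available features, all are retained with a warning.
#' @return A [fused_features()] object of the `k` selected columns in
#'   selection order, with attribute `mrmr_scores` (the MID score at
#'   selection time).
#' @export
mrmr_select <- function(ff, histology, k = 100L) {
  stopifnot(inherits(ff, "fused_features"))
  y <- as.integer(factor(histology))
  if (length(y) != nrow(ff$x))
    stop("'histology' must have one label per patient", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("'histology' must have at least 2 observed classes", call. = FALSE)
  p <- ncol(ff$x)
  if (k > p) {
    warning(sprintf("k = %d exceeds the %d available features; keeping all",
                    k, p), call. = FALSE)
    k <- p
  }
  n <- nrow(ff$x)
  D <- discretise3(ff$x)
  I3 <- lapply(1:3, function(b) D == b)
  col_totals <- lapply(I3, colSums)
  # label states may exceed 3; generalise the joint-count loop over classes
  relevance <- numeric(p)
  for (a in sort(unique(y))) {
    rows <- which(y == a)
    ra <- length(rows)
    for (b in 1:3) {
      cb <- col_totals[[b]]
      cab <- if (ra == 1L) as.numeric(I3[[b]][rows, ])
             else colSums(I3[[b]][rows, , drop = FALSE])
      ok <- cab > 0 & cb > 0
      relevance[ok] <- relevance[ok] +
        (cab[ok] / n) * log(cab[ok] * n / (ra * cb[ok]))
    }
  }
  selected <- integer(0)
  scores <- numeric(0)
  redundancy_sum <- numeric(p)
  for (step in seq_len(k)) {
    score <- if (step == 1L) relevance
             else relevance - redundancy_sum / length(selected)
    score[selected] <- -Inf
    best <- which.max(score)          # ties resolve to the lowest index
    selected <- c(selected, best)
    scores <- c(scores, score[best])
    if (step < k)
      redundancy_sum <- redundancy_sum +
        mi_against_vector(I3, D[, best], col_totals, n)
  }
  out <- ff_subset(ff, selected)
  attr(out, "mrmr_scores") <- stats::setNames(scores,
                                              colnames(ff$x)[selected])
  out
}

#' LASSO signature selection by cross-validated multinomial regression
#'
#' Fits an L1-penalised multinomial logistic model of the histology classes
#' on the (standardised) features along a 100-value lambda path spanning four
#' decades below the smallest all-zero penalty, chooses the penalty with
#' minimum mean cross-validated deviance over seeded, class-stratified folds,
#' and returns the features with a nonzero coefficient for any class at that
#' penalty. An empty selection is a valid outcome, returned as an empty
#' signature rather than an error.
#'
#' @param ff A [fused_features()] object.
#' @param histology Class labels (3 histology classes in the intended
#'   design), one per patient.
#' @param folds Cross-validation folds (default 10); reduced with a warning
#'   when a class has fewer members than folds.
#' @param seed Integer seed for fold assignment.
#' @param source Signature provenance tag (`FF`, `HC`, `TL` or `FT`).
#' @param lambda Optional fixed penalty; when supplied, cross-validation is
#'   skipped and the selection is read off the single fitted model.
#' @return A `feature_signature`: list with `feature_ids` (possibly empty),
#'   `source`, `lambda_min` and a `trace` of survivor counts.
#' @export
lasso_select <- function(ff, histology, folds = 10L, seed = 1L,
                         source = "FF", lambda = NULL) {
  stopifnot(inherits(ff, "fused_features"))
  y <- factor(histology)
  if (nlevels(droplevels(y)) < 2L)
    stop("histology labels are degenerate (single class)", call. = FALSE)
  y <- droplevels(y)
  x <- ff$x
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "multinomial", lambda = lambda,
                          standardize = TRUE)
    sel <- nonzero_features(fit, lambda)
    return(new_signature(colnames(x)[sel], source, lambda,
                         list(n_input = ncol(x), n_selected = length(sel))))
  }
  counts <- table(y)
  if (min(counts) < folds) {
    folds <- max(2L, as.integer(min(counts)))
    warning(sprintf("reducing folds to %d (smallest class has %d patients)",
                    folds, min(counts)), call. = FALSE)
  }
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      rows <- which(y == cl)
      foldid[rows] <- sample(rep(seq_len(folds), length.out = length(rows)))
    }
  })
  # lambda path: 100 values log-spaced over 4 decades below lambda_max
  lmax <- glmnet::glmnet(x, y, family = "multinomial", nlambda = 5,
                         standardize = TRUE)$lambda[1]
  path <- 10^seq(log10(lmax), log10(lmax) - 4, length.out = 100)
  # the tail of the 4-decade path may stop early on near-saturated fits;
  # lambda.min lies among the converged solutions, so muffle that warning
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(x, y, family = "multinomial", lambda = path,
                      foldid = foldid, type.measure = "deviance",
                      standardize = TRUE),
    warning = function(w) {
      if (grepl("Convergence for .*lambda", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sel <- nonzero_features(cv$glmnet.fit, cv$lambda.min)
  new_signature(colnames(x)[sel], source, cv$lambda.min,
                list(n_input = ncol(x), n_selected = length(sel),
                     folds = folds))
}

nonzero_features <- function(fit, lambda) {
  cf <- glmnet::coef.glmnet(fit, s = lambda)
  nz <- Reduce(`|`, lapply(cf, function(m) as.vector(m[-1, 1] != 0)))
  which(nz)
}

new_signature <- function(feature_ids, source, lambda_min, trace) {
  structure(list(feature_ids = feature_ids, source = source,
                 lambda_min = lambda_min, trace = trace),
            class = "feature_signature")
}

#' @export
print.feature_signature <- function(x, ...) {
  if (length(x$feature_ids)) {
    cat(sprintf("<%s_Sig> %d feature(s), lambda* = %.4g\n", x$source,
                length(x$feature_ids), x$lambda_min))
    cat(" ", paste(utils::head(x$feature_ids, 10), collapse = ", "),
        if (length(x$feature_ids) > 10) "..." else "", "\n")
  } else {
    cat(sprintf("<%s_Sig> not generated (no features selected)\n", x$source))
  }
  invisible(x)
}

run_selection_chain <- function(ff, histology, source, mad_quantile, k,
                                folds, seed) {
  m1 <- mad_filter(ff, mad_quantile)
  m2 <- mrmr_select(m1, histology, k = min(k, ncol(m1$x)))
  sig <- lasso_select(m2, histology, folds = folds,
                      seed = derive_seed(seed, paste0("lasso.", source)),
                      source = source)
  sig$trace <- list(n_input = ncol(ff$x),
                    n_after_mad = ncol(m1$x),
                    n_after_mrmr = ncol(m2$x),
                    n_selected = length(sig$feature_ids),
                    lambda_min = sig$lambda_min)
  sig
}

#' Build the fused and per-block feature signatures
#'
#' Runs the MAD -> mRMR -> LASSO chain on the fused matrix (FF) and on each
#' block alone (HC, TL, FT). Any chain may legitimately select nothing, in
#' which case that signature is returned empty and downstream analysis of the
#' remaining signatures proceeds.
#'
#' @param hc,tl,ft Patients-by-features matrices for the three blocks.
#' @param histology Class labels, one per patient.
#' @param mad_quantile MAD drop quantile (default bottom quartile).
#' @param k mRMR target count (default 100; capped at the block dimension).
#' @param folds LASSO cross-validation folds.
#' @param seed Integer seed controlling fold assignment.
#' @return List with `signatures` (named list `FF`, `HC`, `TL`, `FT` of
#'   `feature_signature`) and `fused` (the [fused_features()] matrix the FF
#'   signature indexes into).
#' @export
build_signatures <- function(hc, tl, ft, histology, mad_quantile = 0.25,
                             k = 100L, folds = 10L, seed = 1L) {
  fused <- fuse(list(HC = hc, TL = tl, FT = ft))
  chains <- list(
    FF = fused,
    HC = fused_features(as.matrix(hc), "HC"),
    TL = fused_features(as.matrix(tl), "TL"),
    FT = fused_features(as.matrix(ft), "FT")
  )
  sigs <- lapply(names(chains), function(src)
    run_selection_chain(chains[[src]], histology, src, mad_quantile, k,
                        folds, seed))
  names(sigs) <- names(chains)
  list(signatures = sigs, fused = fused)
}

#' Extract a signature's feature sub-matrix
#'
#' @param ff A [fused_features()] object (typically the fused matrix the
#'   signature was selected from).
#' @param sig A `feature_signature`.
#' @return Patients-by-selected-features matrix; errors if the signature is
#'   empty.
#' @export
signature_matrix <- function(ff, sig) {
  stopifnot(inherits(ff, "fused_features"),
            inherits(sig, "feature_signature"))
  if (!length(sig$feature_ids))
    stop(sprintf("%s signature not generated", sig$source), call. = FALSE)
  ff$x[, sig$feature_ids, drop = FALSE]
}
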