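# Synthetic cohorts with planted, recoverable radiogenomic structure:
# phantom volumes, clinical labels driven by tumour geometry and texture,
# gene expression rank-coupled to realised image features, and gene sets
# enriched for the planted genes.

#' Declare a planted gene-feature link
#'
#' Ground truth for a radiogenomics relationship: the named gene's expression
#' will be rank-coupled to the named image feature at the target Spearman
#' correlation.
#'
#' @param gene_id Gene symbol (unique among links).
#' @param feature_id Handcrafted feature identifier (e.g. `shape.volume`).
#' @param strength Target Spearman correlation magnitude in \[-1, 1\].
#' @param direction Sign of the link; defaults to `sign(strength)` (and +1
#'   for strength 0).
#' @return A list of class `planted_link`.
#' @export
planted_link <- function(gene_id, feature_id, strength,
                         direction = NULL) {
  if (abs(strength) > 1) stop("|strength| must be <= 1", call. = FALSE)
  if (is.null(direction)) direction <- if (strength < 0) -1 else 1
  structure(list(gene_id = as.character(gene_id),
                 feature_id = as.character(feature_id),
                 strength = abs(strength), direction = sign(direction)),
            class = "planted_link")
}

#' Generate a synthetic radiogenomic cohort
#'
#' Simulates `n_patients` textured ellipsoidal tumour phantoms with varying
#' size and texture amplitude, assigns clinical labels partially determined
#' by tumour properties (histology by texture-amplitude tertile, T stage by
#' realised tumour-volume quartile), computes the handcrafted feature matrix,
#' and generates gene expression in which each planted link's gene is
#' rank-coupled to the realised values of its target feature through a
#' Gaussian copula calibrated so the expected Spearman correlation equals the
#' link strength; all other genes are generated independently of the images.
#'
#' @param n_patients Number of patients (>= 10).
#' @param n_genes Number of genes.
#' @param links List of [planted_link()] objects (may be empty). Feature ids
#'   must name handcrafted features; gene ids must be unique and are added to
#'   the expression matrix if not among the default gene symbols.
#' @param seed Integer seed; the cohort is bit-identical per (arguments,
#'   seed).
#' @param grid_shape,spacing Phantom grid geometry.
#' @param radius_range Tumour base radius interval in mm.
#' @param texture_range Texture amplitude interval (HU-like units).
#' @param background_noise_sd Volume noise standard deviation.
#' @param hc_cfg Handcrafted extraction configuration.
#' @return A `synthetic_cohort`: list with `volumes_masks`, `clinical`
#'   ([clinical_table()]), `expression` (genes x patients), `hc_features`
#'   (patients x 431), `gene_sets` (NULL until [generate_gene_sets()] output
#'   is attached) and `truth`.
#' @export
generate_cohort <- function(n_patients, n_genes, links = list(), seed = 1L,
                            grid_shape = c(40L, 40L, 40L),
                            spacing = c(1, 1, 1),
                            radius_range = c(5, 13),
                            texture_range = c(60, 360),
                            background_noise_sd = 20,
                            hc_cfg = hc_config()) {
  if (n_patients < 10L)
    stop("'n_patients' must be at least 10", call. = FALSE)
  if (length(links)) {
    ids <- vapply(links, function(l) l$gene_id, character(1))
    if (anyDuplicated(ids))
      stop("planted link gene ids must be unique", call. = FALSE)
  }
  ids <- sprintf("P%03d", seq_len(n_patients))
  pars <- with_seed(derive_seed(seed, "cohort.params"), {
    list(radius = stats::runif(n_patients, radius_range[1], radius_range[2]),
         aniso = matrix(stats::runif(3 * n_patients, 0.85, 1.15),
                        n_patients, 3),
         texture = stats::runif(n_patients, texture_range[1],
                                texture_range[2]))
  })
  volumes <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    semi <- pmin(pars$radius[i] * pars$aniso[i, ],
                 (grid_shape - 1) * spacing / 2 - spacing)
    spec <- phantom_spec(grid_shape = grid_shape, spacing = spacing,
                         semi_axes = semi,
                         texture_scale = pars$texture[i],
                         background_noise_sd = background_noise_sd)
    volumes[[i]] <- generate_phantom(spec,
                                     derive_seed(seed, paste0("phantom.", i)),
                                     patient_id = ids[i])
  }
  hc <- extract_hc_cohort(volumes, hc_cfg)
  # histology driven by texture-amplitude tertile, T stage by volume quartile
  tex_rank <- rank(pars$texture, ties.method = "first")
  histology <- c("squamous", "adeno", "other")[
    ceiling(tex_rank / n_patients * 3)]
  vol_rank <- rank(hc[, "shape.volume"], ties.method = "first")
  t_stage <- paste0("T", ceiling(vol_rank / n_patients * 4))
  clinical <- clinical_table(ids, histology, t_stage)
  # expression: independent Gaussian genes, planted genes rank-coupled
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (length(links)) {
    planted_ids <- vapply(links, function(l) l$gene_id, character(1))
    missing <- setdiff(planted_ids, gene_ids)
    if (length(missing)) {
      slots <- which(!gene_ids %in% planted_ids)
      if (length(missing) > length(slots))
        stop("more planted genes than genes requested", call. = FALSE)
      gene_ids[slots[seq_along(missing)]] <- missing
    }
  }
  expr <- with_seed(derive_seed(seed, "cohort.expression"), {
    base_mean <- stats::runif(n_genes, 5, 11)
    base_sd <- stats::runif(n_genes, 0.4, 1.5)
    e <- base_mean + base_sd * matrix(stats::rnorm(n_genes * n_patients),
                                      n_genes, n_patients)
    dimnames(e) <- list(gene_ids, ids)
    for (l in links) {
      f <- l$feature_id
      if (!f %in% colnames(hc))
        stop(sprintf("link feature '%s' is not a handcrafted feature id", f),
             call. = FALSE)
      # Gaussian copula: normal scores of the feature ranks, plus noise
      # calibrated so E[Spearman] matches the target strength
      z <- stats::qnorm((rank(hc[, f], ties.method = "average") - 0.5) /
                          n_patients)
      z <- (z - mean(z)) / stats::sd(z)
      r <- 2 * sin(pi * l$strength / 6)      # Pearson of the latent normals
      g <- l$direction * (r * z + sqrt(max(0, 1 - r^2)) *
                            stats::rnorm(n_patients))
      row <- match(l$gene_id, gene_ids)
      e[row, ] <- base_mean[row] + base_sd[row] * g
    }
    e
  })
  truth <- list(
    links = lapply(links, function(l) l[c("gene_id", "feature_id",
                                          "strength", "direction")]),
    planted_set_ids = character(0)
  )
  structure(list(volumes_masks = volumes, clinical = clinical,
                 expression = expr, hc_features = hc,
                 gene_sets = NULL, truth = truth, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d genes, %d planted link(s)\n",
              nrow(x$hc_features), nrow(x$expression),
              length(x$truth$links)))
  invisible(x)
}

#' Generate gene sets enriched for planted genes
#'
#' Builds `n_sets` gene sets over the expression universe: `n_planted` sets
#' draw at least `planted_fraction` of their members from the planted genes
#' (the remainder uniformly from the rest), the decoy sets draw uniformly
#' from all genes. Sizes are sampled within `size_range`.
#'
#' @param expression_genes Character vector of all gene symbols.
#' @param planted_genes Character vector of planted (truth) gene symbols.
#' @param n_sets Total number of sets.
#' @param size_range Closed interval of set sizes, within
#'   \[2, length(expression_genes)\].
#' @param n_planted Number of sets flagged as planted truth (default 2; 0
#'   when no planted genes are given).
#' @param planted_fraction Minimum fraction of a planted set drawn from
#'   `planted_genes`.
#' @param seed Integer seed.
#' @return Named list of gene sets with attributes `planted_ids` and
#'   `descriptions`.
#' @export
generate_gene_sets <- function(expression_genes, planted_genes = character(0),
                               n_sets = 10L, size_range = c(15L, 30L),
                               n_planted = if (length(planted_genes)) 2L else 0L,
                               planted_fraction = 0.8, seed = 1L) {
  if (size_range[1] < 2L || size_range[2] > length(expression_genes))
    stop("'size_range' must lie within [2, number of genes]", call. = FALSE)
  if (n_planted > n_sets) stop("'n_planted' exceeds 'n_sets'", call. = FALSE)
  with_seed(derive_seed(seed, "gene.sets"), {
    sets <- list()
    descriptions <- character(0)
    for (i in seq_len(n_sets)) {
      size <- if (size_range[1] == size_range[2]) size_range[1]
              else sample(seq.int(size_range[1], size_range[2]), 1)
      if (i <= n_planted) {
        n_from_planted <- ceiling(planted_fraction * size)
        if (n_from_planted > length(planted_genes))
          stop(sprintf(
            "planted set of size %d needs %d planted genes but only %d exist",
            size, n_from_planted, length(planted_genes)), call. = FALSE)
        members <- c(sample(planted_genes, n_from_planted),
                     sample(setdiff(expression_genes, planted_genes),
                            size - n_from_planted))
        nm <- sprintf("SET_PLANTED_%02d", i)
        descriptions <- c(descriptions, "planted enriched set (synthetic)")
      } else {
        members <- sample(expression_genes, size)
        nm <- sprintf("SET_RANDOM_%02d", i)
        descriptions <- c(descriptions, "decoy set (synthetic)")
      }
      sets[[nm]] <- sort(members)
    }
    attr(sets, "planted_ids") <- names(sets)[seq_len(n_planted)]
    attr(sets, "descriptions") <- descriptions
    sets
  })
}
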