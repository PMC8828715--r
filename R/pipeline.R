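# End-to-end orchestration of the synthetic radiogenomics workflow.

#' Default pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] in one list. The
#' defaults define a complete synthetic study: a 40-patient cohort with 200
#' genes, four planted gene-feature links of Spearman strength 0.6, and ten
#' gene sets of which two are enriched for the planted genes.
#'
#' @param out_dir Output directory for all artifacts.
#' @param n_patients,n_genes Cohort size.
#' @param links Optional list of [planted_link()]; when NULL, `n_links`
#'   default links of strength `link_strength` on geometry/texture features
#'   are planted.
#' @param n_links,link_strength Default planted links.
#' @param n_sets,n_planted_sets,set_size Gene-set collection parameters.
#' @param n_enrichment_links Supplementary planted links (all on the first
#'   link's feature) that give the planted gene sets a large enough pool of
#'   truly image-coupled genes to draw 80% of their members from.
#' @param deep_width Stand-in extractor width per view (3 views concatenate
#'   to one deep block).
#' @param tl_seed,ft_seed Extractor seeds distinguishing the two deep blocks.
#' @param mad_quantile,mrmr_k,folds Selection chain parameters.
#' @param k_clusters,restarts Patient clustering parameters.
#' @param gene_quantile Gene filter quantile.
#' @param alpha_rr,alpha_go,size_bounds,n_perm Association/enrichment
#'   parameters.
#' @param grid_shape,spacing Phantom geometry.
#' @param seed Global seed; all per-stage seeds are derived from it.
#' @param write_volumes Write NIfTI volumes (disable to keep runs light).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("radiofuse_run_"),
                            n_patients = 40L, n_genes = 200L,
                            links = NULL, n_links = 4L, link_strength = 0.6,
                            n_sets = 10L, n_planted_sets = 2L,
                            set_size = c(20L, 40L),
                            n_enrichment_links = 32L,
                            deep_width = 2048L, tl_seed = 101L,
                            ft_seed = 202L,
                            mad_quantile = 0.25, mrmr_k = 100L, folds = 10L,
                            k_clusters = 3L, restarts = 10L,
                            gene_quantile = 0.25,
                            alpha_rr = 0.001, alpha_go = 0.05,
                            size_bounds = c(15L, 500L), n_perm = 200L,
                            grid_shape = c(40L, 40L, 40L),
                            spacing = c(1, 1, 1),
                            seed = 1L, write_volumes = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

default_links <- function(n_links, strength, n_genes) {
  feats <- c("shape.volume", "fo.mean", "glcm.contrast",
             "wavelet.LLL.fo.entropy", "shape.sphericity", "fo.sd")
  if (n_links > length(feats))
    stop("at most 6 default links are defined; pass 'links' explicitly",
         call. = FALSE)
  lapply(seq_len(n_links), function(i)
    planted_link(sprintf("G%04d", i), feats[i],
                 strength * (if (i %% 2) 1 else -1)))
}

#' Run the full synthetic radiogenomics pipeline
#'
#' Simulates a cohort, builds 2.5D views and the three feature blocks,
#' selects the fused and per-block signatures, associates the fused
#' signature with tumour T stage, filters genes, calls radiogenomics
#' relationships per signature, compares their strengths, runs the gene-set
#' enrichment, and scores recovery of the planted truth. Every intermediate
#' is written to `cfg$out_dir` as plain text (CSV/TSV/JSON/GMT/NIfTI) and a
#' machine-readable run report is returned and written as JSON. Reruns with
#' the same configuration reproduce the report exactly (timestamps aside).
#'
#' @param cfg A [pipeline_config()].
#' @return The run report, invisibly (a nested list; also written to
#'   `report.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed,
                 parameters = cfg[setdiff(names(cfg), "links")])
  stage <- function(name, expr) {
    message(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (earlier artifacts in %s remain usable)",
                   name, conditionMessage(e), cfg$out_dir), call. = FALSE))
  }

  links <- cfg$links %||% default_links(cfg$n_links, cfg$link_strength,
                                        cfg$n_genes)
  if (is.null(cfg$links) && cfg$n_enrichment_links > 0L && length(links)) {
    links <- c(links, lapply(seq_len(cfg$n_enrichment_links), function(i)
      planted_link(sprintf("GE%03d", i), links[[1]]$feature_id,
                   cfg$link_strength * links[[1]]$direction)))
  }
  cohort <- stage("simulate", {
    co <- generate_cohort(cfg$n_patients, cfg$n_genes, links = links,
                          seed = derive_seed(cfg$seed, "simulate"),
                          grid_shape = cfg$grid_shape, spacing = cfg$spacing)
    planted_genes <- vapply(links, function(l) l$gene_id, character(1))
    co$gene_sets <- generate_gene_sets(
      rownames(co$expression), planted_genes,
      n_sets = cfg$n_sets, size_range = cfg$set_size,
      n_planted = min(cfg$n_planted_sets, cfg$n_sets),
      seed = derive_seed(cfg$seed, "gene.sets"))
    co$truth$planted_set_ids <- attr(co$gene_sets, "planted_ids")
    write_cohort(co, cfg$out_dir, write_volumes = cfg$write_volumes)
    co
  })
  report$simulate <- list(n_patients = cfg$n_patients,
                          n_genes = cfg$n_genes,
                          n_links = length(links),
                          n_sets = length(cohort$gene_sets))

  blocks <- stage("features", {
    views <- lapply(cohort$volumes_masks, extract_views)
    tl <- extract_deep_cohort(views, filterbank_standin(cfg$tl_seed,
                                                        cfg$deep_width),
                              block = "TL")
    ft <- extract_deep_cohort(views, filterbank_standin(cfg$ft_seed,
                                                        cfg$deep_width),
                              block = "FT")
    utils::write.csv(data.frame(patient_id = rownames(tl), tl,
                                check.names = FALSE),
                     file.path(cfg$out_dir, "features_tl.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(patient_id = rownames(ft), ft,
                                check.names = FALSE),
                     file.path(cfg$out_dir, "features_ft.csv"),
                     row.names = FALSE)
    list(hc = cohort$hc_features, tl = tl, ft = ft)
  })
  report$features <- list(hc_dim = ncol(blocks$hc),
                          tl_dim = ncol(blocks$tl),
                          ft_dim = ncol(blocks$ft))

  sel <- stage("select", {
    build_signatures(blocks$hc, blocks$tl, blocks$ft,
                     cohort$clinical$histology,
                     mad_quantile = cfg$mad_quantile, k = cfg$mrmr_k,
                     folds = cfg$folds,
                     seed = derive_seed(cfg$seed, "select"))
  })
  sig_json <- lapply(sel$signatures, function(s)
    list(feature_ids = s$feature_ids, source = s$source,
         lambda_min = s$lambda_min, trace = s$trace))
  jsonlite::write_json(sig_json, file.path(cfg$out_dir, "signatures.json"),
                       auto_unbox = TRUE, digits = NA)
  report$select <- lapply(sel$signatures, function(s) s$trace)

  report$stage_association <- stage("associate-stage", {
    ff <- sel$signatures$FF
    if (!length(ff$feature_ids)) {
      list(generated = FALSE)
    } else {
      sm <- signature_matrix(sel$fused, ff)
      labels <- cluster_patients(sm, k = cfg$k_clusters,
                                 restarts = cfg$restarts,
                                 seed = derive_seed(cfg$seed, "cluster"))
      ht <- chi2_stage_association(labels, cohort$clinical)
      z <- zscore_table(sm, labels)
      utils::write.csv(data.frame(patient_id = rownames(z),
                                  cluster = attr(z, "cluster"), z,
                                  check.names = FALSE),
                       file.path(cfg$out_dir, "ff_sig_zscores.csv"),
                       row.names = FALSE)
      list(generated = TRUE, chi2 = ht$statistic, df = ht$df,
           p_value = ht$p_value,
           cluster_sizes = as.integer(table(labels)))
    }
  })

  kept <- stage("filter-genes", filter_genes(cohort$expression,
                                             q = cfg$gene_quantile))
  write_expression_tsv(kept$expression,
                       file.path(cfg$out_dir, "expression_filtered.tsv"))
  report$filter_genes <- list(n_input = kept$n_input, n_kept = kept$n_kept,
                              removed = as.list(kept$removed))

  rr <- stage("rr", {
    tabs <- list()
    for (src in names(sel$signatures)) {
      s <- sel$signatures[[src]]
      if (!length(s$feature_ids)) next
      tab <- spearman_rr(signature_matrix(sel$fused, s), kept$expression,
                         alpha = cfg$alpha_rr, source = src)
      utils::write.csv(as.data.frame(tab),
                       file.path(cfg$out_dir,
                                 sprintf("rr_%s.csv", tolower(src))),
                       row.names = FALSE)
      tabs[[src]] <- tab
    }
    tabs
  })
  report$rr <- if (length(rr)) {
    summ <- rr_summary(rr)
    cmp <- if ("FF" %in% names(rr) && length(rr) > 1L)
      lapply(rr[setdiff(names(rr), "FF")], function(b)
        compare_strengths(rr$FF, b)) else NULL
    jsonlite::write_json(list(counts = summ$counts,
                              regions = as.list(summ$regions),
                              strength_tests = cmp),
                         file.path(cfg$out_dir, "rr_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(counts = summ$counts, regions = as.list(summ$regions))
  } else list(generated = FALSE)

  report$enrichment <- stage("enrich", {
    out <- lapply(names(rr), function(src) {
      enr <- signature_enrichment(
        attr(rr[[src]], "rho_matrix"), attr(rr[[src]], "p_matrix"),
        cohort$gene_sets, size_bounds = cfg$size_bounds,
        alpha_rr = cfg$alpha_rr, alpha_go = cfg$alpha_go,
        n_perm = cfg$n_perm,
        seed = derive_seed(cfg$seed, paste0("enrich.", src)))
      if (!is.null(enr$results))
        utils::write.csv(enr$results,
                         file.path(cfg$out_dir,
                                   sprintf("enrichment_%s.csv",
                                           tolower(src))),
                         row.names = FALSE)
      list(generated = enr$generated, n_scored =
             if (is.null(enr$per_set)) 0L else nrow(enr$per_set),
           n_significant = enr$n_significant)
    })
    names(out) <- names(rr)
    out
  })

  report$recovery <- stage("recovery", {
    # truth-vs-called: Spearman test of each planted pair on the raw inputs
    called <- vapply(links, function(l) {
      sm <- spearman_matrix(cohort$hc_features[, l$feature_id, drop = FALSE],
                            cohort$expression[l$gene_id, , drop = FALSE])
      sm$p[1, 1] < cfg$alpha_rr
    }, logical(1))
    # planted-set rank by |NES| on the first planted feature's full ranking
    set_ranks <- NULL
    if (length(links)) {
      rho_all <- spearman_matrix(
        cohort$hc_features[, links[[1]]$feature_id, drop = FALSE],
        cohort$expression)$rho[1, ]
      rl <- rank_genes(rho_all, feature_id = links[[1]]$feature_id)
      nes <- vapply(names(cohort$gene_sets), function(s)
        abs(normalise_es(rl, cohort$gene_sets[[s]], n_perm = cfg$n_perm,
                         seed = derive_seed(cfg$seed, paste0("rec.", s)),
                         set_id = s)$nes), numeric(1))
      set_ranks <- rank(-nes)[cohort$truth$planted_set_ids]
    }
    list(link_sensitivity = mean(called),
         n_links_called = sum(called),
         planted_set_nes_ranks = as.numeric(set_ranks))
  })

  report_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(c(report, list(timestamp = format(Sys.time()))),
                       report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  message(sprintf("[done] report written to %s", report_path))
  invisible(report)
}
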