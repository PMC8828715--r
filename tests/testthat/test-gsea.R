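# Pre-ranked enrichment: ranking, ES, permutation NES, signature report.

ranked_fixture <- function(n = 20, seed = 1) {
  rho <- radiofuse:::with_seed(seed, {
    r <- sort(runif(n, -0.9, 0.9), decreasing = TRUE)
    names(r) <- sprintf("g%02d", seq_len(n))
    r
  })
  rank_genes(rho, feature_id = "f1")
}

test_that("rank_genes sorts descending with deterministic tie-breaks", {
  rho <- c(A = 0.9, B = -0.2, C = 0.5, D = 0.5)
  rho15 <- c(rho, setNames(seq(-0.3, -0.8, length.out = 11),
                           sprintf("z%02d", 1:11)))
  rl <- rank_genes(rho15)
  expect_identical(rl$genes[1:4], c("A", "C", "D", "B"))
  # all-equal metrics: lexicographic order
  flat <- setNames(rep(0.1, 16), sprintf("m%02d", 16:1))
  expect_identical(rank_genes(flat)$genes, sort(names(flat)))
  expect_error(rank_genes(setNames(runif(10), paste0("g", 1:10))),
               "at least 15")
  expect_warning(rank_genes(c(rho15, NAg = NA)), "undefined")
})

test_that("enrichment score reproduces hand-computed running sums", {
  rho <- c(a = 0.8, b = 0.4, c = -0.1, d = -0.7)
  rl <- structure(list(genes = names(rho), metric = unname(rho),
                       feature_id = "f"), class = "ranked_genes")
  # set = top gene: running sum peaks at +1 after position 1
  expect_equal(enrichment_score(rl, "a")$es, 1)
  # set = bottom gene: misses walk to -1 before the final hit
  expect_equal(enrichment_score(rl, "d")$es, -1)
  # running sum starts from the step values and ends at 0
  run <- enrichment_score(rl, c("a", "c"))$running
  expect_equal(run[length(run)], 0, tolerance = 1e-12)
  expect_error(enrichment_score(rl, "zzz"), "does not intersect")
  expect_error(enrichment_score(rl, names(rho)), "entire ranked universe")
})

test_that("ES at p = 0 matches the direct KS oracle and is antisymmetric", {
  rl <- ranked_fixture(20, seed = 2)
  sets <- list(c("g01", "g03", "g07"), c("g15", "g18", "g20"),
               sprintf("g%02d", c(2, 9, 11, 16)))
  for (s in sets) {
    expect_equal(enrichment_score(rl, s, p = 0)$es,
                 oracle_es(rl$genes, rl$metric, s, p = 0), tolerance = 1e-12)
    # reversing the ranked list negates the unweighted statistic
    rev_rl <- structure(list(genes = rev(rl$genes),
                             metric = rev(rl$metric),
                             feature_id = "f1"), class = "ranked_genes")
    expect_equal(enrichment_score(rev_rl, s, p = 0)$es,
                 -enrichment_score(rl, s, p = 0)$es, tolerance = 1e-12)
  }
  # weighted statistic agrees with the oracle too
  expect_equal(enrichment_score(rl, sets[[1]], p = 1)$es,
               oracle_es(rl$genes, rl$metric, sets[[1]], p = 1),
               tolerance = 1e-12)
})

test_that("ES agrees with fgsea's statistic on a shared fixture", {
  skip_if_not_installed("fgsea")
  rl <- ranked_fixture(50, seed = 3)
  stats_vec <- setNames(rl$metric, rl$genes)
  for (s in list(sprintf("g%02d", c(1, 4, 6, 9)),
                 sprintf("g%02d", c(40, 44, 48, 50)))) {
    got <- enrichment_score(rl, s)$es
    want <- fgsea::calcGseaStat(stats_vec,
                                selectedStats = match(s, names(stats_vec)),
                                gseaParam = 1, scoreType = "std")
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("fast positional ES equals the full running-sum ES", {
  rl <- ranked_fixture(200, seed = 4)
  w <- abs(rl$metric)
  for (seed in 1:5) {
    pos <- radiofuse:::with_seed(seed, sort(sample.int(200, 12)))
    set <- rl$genes[pos]
    expect_equal(radiofuse:::es_from_positions(pos, w, 200),
                 enrichment_score(rl, set)$es, tolerance = 1e-12)
  }
})

test_that("NES is seeded, sign-matched and centred near 1 under the null", {
  rl <- ranked_fixture(120, seed = 5)
  set <- radiofuse:::with_seed(9, sample(rl$genes, 20))
  a <- normalise_es(rl, set, n_perm = 500, seed = 11)
  b <- normalise_es(rl, set, n_perm = 500, seed = 11)
  expect_identical(a, b)
  expect_identical(a$size, 20L)
  # random sets on a null ranking: |NES| averages near 1
  nes <- sapply(1:25, function(i) {
    s <- radiofuse:::with_seed(100 + i, sample(rl$genes, 15))
    abs(normalise_es(rl, s, n_perm = 300, seed = 200 + i)$nes)
  })
  expect_gt(mean(nes), 0.8)
  expect_lt(mean(nes), 1.2)
})

test_that("planted top-concentrated sets score extreme NES and tiny p", {
  rl <- ranked_fixture(300, seed = 6)
  planted <- rl$genes[1:18]
  res <- normalise_es(rl, planted, n_perm = 1000, seed = 31)
  expect_gt(res$nes, 1.5)
  # no same-sign null draw reaches the observed score: p sits at the
  # add-one-smoothing floor, roughly 1 / (n_perm / 2)
  expect_lte(res$p_value, 0.0025)
})

test_that("signature-level report filters sizes and aggregates features", {
  co <- fixture_cohort40()
  feats <- co$hc_features[, c("shape.volume", "fo.mean"), drop = FALSE]
  tab <- spearman_rr(feats, co$expression, source = "FF")
  sets <- generate_gene_sets(rownames(co$expression),
                             c("G0001", "G0002", "G0003"),
                             n_sets = 6L, size_range = c(20L, 30L),
                             n_planted = 0L, seed = 8L)
  sets$TOO_BIG <- rownames(co$expression)[1:119]
  sets$TOO_SMALL <- rownames(co$expression)[1:5]
  enr <- signature_enrichment(attr(tab, "rho_matrix"),
                              attr(tab, "p_matrix"), sets,
                              size_bounds = c(15L, 100L), n_perm = 200,
                              seed = 12)
  expect_true(enr$generated)
  expect_false(any(c("TOO_BIG", "TOO_SMALL") %in% enr$results$set_id))
  expect_true(all(enr$results$size >= 15 & enr$results$size <= 100))
  # single-feature signature: the report equals that feature's results
  one <- signature_enrichment(attr(tab, "rho_matrix")[1, , drop = FALSE],
                              attr(tab, "p_matrix")[1, , drop = FALSE],
                              sets, size_bounds = c(15L, 100L),
                              n_perm = 200, seed = 12)
  sub <- enr$results[enr$results$feature_id == "shape.volume", ]
  rownames(sub) <- NULL
  expect_equal(one$results, sub)
  # empty signature: reported as not generated
  none <- signature_enrichment(matrix(numeric(0), 0, 0), NULL, sets)
  expect_false(none$generated)
})

test_that("permutation p-values are super-uniform under the null", {
  rl <- ranked_fixture(150, seed = 7)
  pv <- sapply(1:40, function(i) {
    s <- radiofuse:::with_seed(300 + i, sample(rl$genes, 15))
    normalise_es(rl, s, n_perm = 300, seed = 400 + i)$p_value
  })
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pv <= t), t + 0.12)
  }
  expect_gt(mean(pv), 0.35)
})
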