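# Radiogenomics relationship calling, summaries, strength comparison.

rr_fixture_tables <- function() {
  mk <- function(genes, rhos) {
    tab <- data.frame(feature_id = "f1", gene = genes, rho = rhos,
                      p = 1e-5, direction = ifelse(rhos >= 0, "positive",
                                                   "inverse"))
    structure(tab, class = c("rr_table", "data.frame"))
  }
  list(mk = mk)
}

test_that("Spearman rho matches hand values and Pearson-on-ranks", {
  n <- 10
  pats <- sprintf("P%02d", 1:n)
  x <- matrix(1:n, n, 1, dimnames = list(pats, "f"))
  e_lin <- matrix(2 * (1:n), 1, n, dimnames = list("g", pats))
  sm <- radiofuse:::spearman_matrix(x, e_lin)
  expect_equal(sm$rho[1, 1], 1)
  e_neg <- matrix(-(1:n), 1, n, dimnames = list("g", pats))
  expect_equal(radiofuse:::spearman_matrix(x, e_neg)$rho[1, 1], -1)
  # hand case: x = 1..4, y = (1,3,2,4) -> rho = 1 - 6*2/60 = 0.8
  x4 <- matrix(1:4, 4, 1, dimnames = list(sprintf("P%d", 1:4), "f"))
  y4 <- matrix(c(1, 3, 2, 4), 1, 4,
               dimnames = list("g", sprintf("P%d", 1:4)))
  expect_error(radiofuse:::spearman_matrix(x4, y4), "at least 5")
  x5 <- matrix(c(1:4, 5), 5, 1, dimnames = list(sprintf("P%d", 1:5), "f"))
  y5 <- matrix(c(1, 3, 2, 4, 5), 1, 5,
               dimnames = list("g", sprintf("P%d", 1:5)))
  expect_equal(radiofuse:::spearman_matrix(x5, y5)$rho[1, 1],
               1 - 6 * 2 / (5 * 24))
  # tie-free random data: rho equals Pearson on ranks to 1e-12
  xm <- radiofuse:::with_seed(5, matrix(rnorm(9 * 60), 60, 9,
    dimnames = list(sprintf("P%02d", 1:60), sprintf("f%d", 1:9))))
  em <- radiofuse:::with_seed(6, matrix(rnorm(12 * 60), 12, 60,
    dimnames = list(sprintf("g%02d", 1:12), sprintf("P%02d", 1:60))))
  sm2 <- radiofuse:::spearman_matrix(xm, em)
  for (i in c(1, 5, 9)) for (j in c(2, 7, 12)) {
    expect_equal(sm2$rho[i, j], cor(rank(xm[, i]), rank(em[j, ])),
                 tolerance = 1e-12)
    expect_equal(sm2$p[i, j],
                 cor.test(xm[, i], em[j, ], method = "spearman",
                          exact = FALSE)$p.value, tolerance = 1e-9)
  }
})

test_that("spearman_rr keeps only sub-alpha pairs and flags direction", {
  co <- fixture_cohort40()
  feats <- co$hc_features[, c("shape.volume", "fo.mean"), drop = FALSE]
  tab <- spearman_rr(feats, co$expression, alpha = 0.001, source = "HC")
  expect_s3_class(tab, "rr_table")
  expect_true(all(tab$p < 0.001))
  expect_identical(tab$direction, ifelse(tab$rho >= 0, "positive",
                                         "inverse"))
  expect_true(all(abs(tab$rho) <= 1))
  # planted links on these features must be called
  expect_true(all(c("G0001", "G0002") %in% tab$gene))
  # zero-variance gene is skipped with a warning
  e2 <- co$expression[1:10, ]
  e2[3, ] <- 1
  expect_warning(spearman_rr(feats, e2), "zero-variance")
})

test_that("rr_summary counts rows, genes and Venn regions", {
  f <- rr_fixture_tables()
  a <- f$mk(c("g1", "g2", "g2"), c(0.5, 0.4, -0.6))
  expect_identical(rr_summary(list(A = a))$counts$n_rr, 3L)
  expect_identical(rr_summary(list(A = a))$counts$n_genes, 2L)
  b <- f$mk(c("g2", "g3", "g4"), c(0.7, -0.2, 0.1))
  two <- rr_summary(list(A = a, B = b))
  expect_identical(unname(two$regions[c("A", "B", "A+B")]), c(1L, 2L, 1L))
  # identical tables: all mass in the intersection
  same <- rr_summary(list(A = a, B = a))
  expect_identical(unname(same$regions["A+B"]), 2L)
  expect_identical(unname(same$regions["A"]), 0L)
  # disjoint tables
  c2 <- f$mk(c("g8", "g9", "g10"), c(0.2, 0.3, 0.4))
  disj <- rr_summary(list(A = a, C = c2))
  expect_identical(unname(disj$regions[c("A", "C", "A+C")]), c(2L, 3L, 0L))
})

test_that("directional strength comparison is a one-sided Welch test", {
  f <- rr_fixture_tables()
  a <- f$mk(sprintf("g%d", 1:40),
            radiofuse:::with_seed(1, c(runif(20, 0.85, 0.95),
                                       -runif(20, 0.85, 0.95))))
  b <- f$mk(sprintf("h%d", 1:40),
            radiofuse:::with_seed(2, c(runif(20, 0.05, 0.15),
                                       -runif(20, 0.05, 0.15))))
  res <- compare_strengths(a, b)
  expect_identical(res$direction, c("positive", "inverse"))
  expect_true(all(res$p < 1e-6))
  # cross-check against stats::t.test on the positive stratum
  tt <- t.test(abs(a$rho[a$direction == "positive"]),
               abs(b$rho[b$direction == "positive"]),
               alternative = "greater")
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-12)
  # identical tables: no advantage, one-sided p >= 0.5
  self <- compare_strengths(a, a)
  expect_true(all(self$p >= 0.5))
  # empty stratum: untestable but the other direction still runs
  b_pos <- f$mk(sprintf("h%d", 1:10),
                radiofuse:::with_seed(3, runif(10, 0.1, 0.2)))
  res2 <- compare_strengths(a, b_pos)
  expect_false(res2$testable[res2$direction == "inverse"])
  expect_true(res2$testable[res2$direction == "positive"])
})
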