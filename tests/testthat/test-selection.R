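# Fusion and the MAD -> mRMR -> LASSO selection chain.

make_matrix <- function(n, p, seed = 1, prefix = "f") {
  radiofuse:::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("P%03d", seq_len(n)),
                                sprintf("%s%03d", prefix, seq_len(p))))
    m
  })
}

test_that("fusion concatenates blocks and checks patients and names", {
  hc <- make_matrix(10, 4, 1, "hc")
  tl <- make_matrix(10, 3, 2, "tl")
  ff <- fuse(list(HC = hc, TL = tl))
  expect_identical(ncol(ff$x), 7L)
  expect_identical(unname(ff$block), c(rep("HC", 4), rep("TL", 3)))
  one <- fuse(list(HC = hc))
  expect_identical(one$x, hc)
  bad <- tl
  rownames(bad) <- rev(rownames(bad))
  expect_error(fuse(list(HC = hc, TL = bad)), "patient")
  dup <- hc
  expect_error(fuse(list(HC = hc, TL = dup)), "[Dd]uplicate")
})

test_that("MAD filter drops constants and the bottom quantile", {
  x <- cbind(const = rep(5, 8),
             low = rep(c(0, 0.001), 4),
             a = c(1, 2, 3, 4, 5, 6, 7, 8),
             b = c(0, 10, 0, 10, 0, 10, 0, 10))
  rownames(x) <- sprintf("P%03d", 1:8)
  ff <- fused_features(x, "HC")
  kept <- mad_filter(ff, drop_quantile = 0.25)
  expect_false("const" %in% colnames(kept$x))
  expect_true(all(c("a", "b") %in% colnames(kept$x)))
  # hand value: MAD of {1..5} about its median is 1
  mads <- apply(matrix(1:5), 2, function(v) median(abs(v - median(v))))
  expect_equal(mads, 1)
  # scale equivariance of the criterion
  mad1 <- radiofuse:::with_seed(3, {
    v <- rnorm(20)
    c(median(abs(v - median(v))), median(abs(3 * v - median(3 * v))))
  })
  expect_equal(mad1[2], 3 * mad1[1])
  expect_error(mad_filter(fused_features(matrix(1, 5, 2,
    dimnames = list(paste0("P", 1:5), c("u", "v"))), "HC")),
    "every feature")
})

test_that("mRMR picks the label-matching feature first and shuns duplicates", {
  y <- rep(c("a", "b", "c"), each = 10)
  x <- radiofuse:::with_seed(4, {
    # the strongest feature is informative but noisy: its duplicate then
    # scores relevance minus self-information < 0 at step 2, while an
    # independent informative feature keeps a positive MID score
    strong <- 3 * (y == "a") + rnorm(30, sd = 1.2)
    informative <- 3 * (y == "c") + rnorm(30, sd = 1.2)
    cbind(strong = strong, duplicate = strong,
          informative = informative, noise1 = rnorm(30),
          noise2 = rnorm(30))
  })
  rownames(x) <- sprintf("P%03d", 1:30)
  ff <- fused_features(x, "HC")
  sel <- mrmr_select(ff, y, k = 3L)
  expect_identical(colnames(sel$x)[1], "strong")
  expect_identical(colnames(sel$x)[2], "informative")
  expect_false("duplicate" %in% colnames(sel$x))
})

test_that("mRMR greedy trace matches the exhaustive MID oracle", {
  for (seed in c(11, 12)) {
    x <- make_matrix(40, 8, seed)
    y <- radiofuse:::with_seed(seed + 100,
                               sample(c("a", "b", "c"), 40, replace = TRUE))
    # give two features real signal so relevance is not pure noise
    x[, 1] <- x[, 1] + 2 * (y == "a")
    x[, 5] <- x[, 5] - 2 * (y == "c")
    got <- colnames(mrmr_select(fused_features(x, "HC"), y, k = 8L)$x)
    want <- colnames(x)[oracle_mrmr(x, y, 8L)]
    expect_identical(got, want)
  }
})

test_that("mRMR warns and keeps everything when k exceeds the dimension", {
  x <- make_matrix(20, 3, 2)
  y <- rep(c("a", "b"), 10)
  expect_warning(sel <- mrmr_select(fused_features(x, "HC"), y, k = 10L),
                 "keeping all")
  expect_identical(ncol(sel$x), 3L)
  expect_error(mrmr_select(fused_features(x, "HC"), rep("a", 20), k = 2L),
               "2 observed classes")
})

test_that("LASSO recovers a planted separating feature and can return empty", {
  n <- 90
  y <- rep(c("squamous", "adeno", "other"), each = 30)
  x <- make_matrix(n, 20, 7)
  x[, 5] <- c(rep(-4, 30), rep(0, 30), rep(4, 30)) +
    radiofuse:::with_seed(8, rnorm(n, sd = 0.3))
  ff <- fused_features(x, "HC")
  sig <- lasso_select(ff, y, seed = 21, source = "HC")
  expect_s3_class(sig, "feature_signature")
  expect_true("f005" %in% sig$feature_ids)
  # full shrinkage yields a valid empty signature
  empty <- lasso_select(ff, y, lambda = 1e6, source = "TL")
  expect_length(empty$feature_ids, 0L)
  expect_identical(empty$source, "TL")
  expect_error(lasso_select(ff, rep("a", n)), "single class")
})

test_that("signature chain traces are monotone and deterministic", {
  co <- fixture_cohort40()
  hc <- co$hc_features
  tl <- make_matrix(40, 150, 31, "tl")
  rownames(tl) <- rownames(hc)
  ft <- make_matrix(40, 150, 32, "ft")
  rownames(ft) <- rownames(hc)
  suppressWarnings({
    sel1 <- build_signatures(hc, tl, ft, co$clinical$histology, k = 40L,
                             seed = 5L)
    sel2 <- build_signatures(hc, tl, ft, co$clinical$histology, k = 40L,
                             seed = 5L)
  })
  expect_identical(sel1$signatures$FF$feature_ids,
                   sel2$signatures$FF$feature_ids)
  for (s in sel1$signatures) {
    tr <- s$trace
    expect_lte(tr$n_after_mad, tr$n_input)
    expect_lte(tr$n_after_mrmr, tr$n_after_mad)
    expect_lte(tr$n_selected, tr$n_after_mrmr)
  }
  expect_identical(ncol(sel1$fused$x), 431L + 150L + 150L)
})

test_that("permuted labels carry no histology signal into the deviance", {
  co <- fixture_cohort40()
  ff <- mad_filter(fused_features(co$hc_features, "HC"))
  ff <- mrmr_select(ff, co$clinical$histology, k = 30L)
  y <- co$clinical$histology
  yp <- radiofuse:::with_seed(99, sample(as.character(y)))
  # intercept-only deviance: multinomial log-loss of the class frequencies
  pr <- as.numeric(table(yp) / length(yp))
  dev0 <- -2 * sum(table(yp) * log(pr))
  foldid <- radiofuse:::with_seed(100, sample(rep(1:5, length.out = 40)))
  cv <- suppressWarnings(
    glmnet::cv.glmnet(ff$x, factor(yp), family = "multinomial",
                      foldid = foldid, type.measure = "deviance"))
  # the best cross-validated deviance should not beat the intercept model
  # by a meaningful margin once the labels are shuffled
  expect_gt(min(cv$cvm), (dev0 / 40) * 0.85)
})
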