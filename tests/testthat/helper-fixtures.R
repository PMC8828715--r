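# Shared fixtures, built once per test session and cached. All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A mid-size textured phantom used across feature tests.
fixture_phantom <- function() fixture("phantom", function() {
  generate_phantom(phantom_spec(grid_shape = c(25L, 25L, 25L),
                                semi_axes = c(9, 8, 10),
                                texture_scale = 180),
                   seed = 42, patient_id = "PH01")
})

# Small random ROI volumes for oracle comparisons (at most 6^3).
random_small_vm <- function(seed, shape = c(5L, 5L, 5L)) {
  with_seed <- radiofuse:::with_seed
  with_seed(seed, {
    x <- array(runif(prod(shape), 0, 100), shape)
    m <- array(runif(prod(shape)) < 0.7, shape)
    if (sum(m) < 3) m[1:3] <- TRUE
    volume_mask(x, m, c(1, 1, 1), sprintf("RND%02d", seed))
  })
}

# 40-patient cohort with planted links of strength 0.6 (shared by several
# recovery tests).
fixture_cohort40 <- function() fixture("cohort40", function() {
  links <- list(planted_link("G0001", "shape.volume", 0.6),
                planted_link("G0002", "fo.mean", -0.6),
                planted_link("G0003", "glcm.contrast", 0.6))
  generate_cohort(40L, 120L, links = links, seed = 2024L)
})

# Link-free cohort for null-calibration suites.
fixture_null_cohort <- function() fixture("null_cohort", function() {
  generate_cohort(40L, 25000L, links = list(), seed = 77L)
})

# Large planted cohort for the recovery acceptance suite: 80 patients,
# 32 links of strength 0.6 (20 of them on one feature to support the
# planted-enrichment check).
fixture_cohort80 <- function() fixture("cohort80", function() {
  links <- c(
    lapply(1:12, function(i)
      planted_link(sprintf("G%04d", i),
                   c("shape.volume", "fo.mean", "glcm.contrast",
                     "wavelet.LLL.fo.entropy")[(i - 1) %% 4 + 1],
                   0.6 * (if (i %% 2) 1 else -1))),
    lapply(1:20, function(i)
      planted_link(sprintf("GE%03d", i), "shape.volume", 0.6))
  )
  generate_cohort(80L, 400L, links = links, seed = 4242L)
})

fixture_views80 <- function() fixture("views80", function() {
  lapply(fixture_cohort80()$volumes_masks, extract_views)
})
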