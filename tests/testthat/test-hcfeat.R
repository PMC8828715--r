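# Handcrafted radiomics: first-order, shape, GLCM, wavelet, full catalogue.

vm_from_values <- function(values, dims) {
  n <- length(values)
  x <- array(0, dims)
  m <- array(FALSE, dims)
  m[seq_len(n)] <- TRUE
  x[seq_len(n)] <- values
  volume_mask(x, m, c(1, 1, 1), "VAL")
}

test_that("first-order statistics match hand-computed values", {
  fo <- first_order(vm_from_values(c(10, 20, 30), c(3L, 2L, 2L)))
  expect_length(fo, 19L)
  expect_equal(unname(fo["fo.mean"]), 20)
  expect_equal(unname(fo["fo.median"]), 20)
  expect_equal(unname(fo["fo.range"]), 20)
  # MAD about median of {1..5}: medians of |x - 3| = {2,1,0,1,2} -> 1
  fo5 <- first_order(vm_from_values(1:5, c(5L, 2L, 2L)))
  expect_equal(unname(fo5["fo.mad_median"]), 1)
  # constant ROI degenerates cleanly
  foc <- first_order(vm_from_values(rep(7, 8), c(2L, 2L, 2L)))
  expect_equal(unname(foc["fo.variance"]), 0)
  expect_equal(unname(foc["fo.entropy"]), 0)
  expect_equal(unname(foc["fo.uniformity"]), 1)
})

test_that("shape features match the exposed-face convention on blocks", {
  dims <- c(6L, 6L, 6L)
  m1 <- array(FALSE, dims); m1[3, 3, 3] <- TRUE
  sv <- shape_features(volume_mask(array(1, dims), m1, c(1, 1, 1)))
  expect_length(sv, 17L)
  expect_equal(unname(sv["shape.volume"]), 1)
  expect_equal(unname(sv["shape.surface_area"]), 6)
  m2 <- array(FALSE, dims); m2[3:4, 3, 3] <- TRUE
  sv2 <- shape_features(volume_mask(array(1, dims), m2, c(1, 1, 1)))
  expect_equal(unname(sv2["shape.volume"]), 2)
  expect_equal(unname(sv2["shape.surface_area"]), 10)
  expect_equal(unname(sv2["shape.max_diameter_3d"]), 1)
})

test_that("digital-ball shape features agree with a brute-force V/A oracle", {
  vm <- generate_phantom(phantom_spec(grid_shape = c(25L, 25L, 25L),
                                      semi_axes = c(10, 10, 10)), seed = 2)
  sv <- shape_features(vm)
  # independent voxel-count volume and face-count area
  m <- vm$mask
  V <- sum(m)
  d <- dim(m)
  A <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
      p <- c(i, j, k) + off
      if (any(p < 1) || any(p > d) || !m[p[1], p[2], p[3]]) A <- A + 1
    }
  }
  expect_equal(unname(sv["shape.volume"]), V)
  expect_equal(unname(sv["shape.surface_area"]), A)
  expect_equal(unname(sv["shape.sphericity"]),
               pi^(1 / 3) * (6 * V)^(2 / 3) / A, tolerance = 1e-12)
  # exposed-face area of a digitised ball converges to 1.5x the analytic
  # sphere area, so sphericity under this convention plateaus near 2/3
  expect_gt(unname(sv["shape.sphericity"]), 0.60)
  expect_lt(unname(sv["shape.sphericity"]), 0.75)
})

test_that("GLCM features match the brute-force pair-enumeration oracle", {
  for (seed in c(1, 2, 3)) {
    vm <- random_small_vm(seed)
    nb <- 4L
    got <- glcm_features(vm, n_bins = nb)
    P <- oracle_glcm_matrix(vm$intensities, vm$mask, nb, glcm_offsets_13())
    want <- oracle_glcm_stats(P)
    expect_equal(got[names(want)], want, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("GLCM handles the documented toy and degenerate cases", {
  # 2x2 plane [[0,0],[1,1]] with offset (0,1): pairs (0,0) and (1,1) only
  x <- array(c(0, 1, 0, 1), c(2L, 2L, 1L))
  m <- array(TRUE, c(2L, 2L, 1L))
  vm <- volume_mask(x, m, c(1, 1, 1))
  g <- glcm_features(vm, n_bins = 2L, offsets = rbind(c(0L, 1L, 0L)))
  expect_equal(unname(g["glcm.contrast"]), 0)
  expect_equal(unname(g["glcm.maximum_probability"]), 0.5)
  # constant ROI: single occupied cell
  vmc <- vm_from_values(rep(5, 8), c(2L, 2L, 2L))
  gc <- glcm_features(vmc, n_bins = 8L)
  expect_equal(unname(gc["glcm.energy"]), 1)
  expect_equal(unname(gc["glcm.entropy"]), 0)
  expect_equal(unname(gc["glcm.mcc"]), 1)
  # normalised matrix sums to 1 and is symmetric by construction
  P <- radiofuse:::glcm_matrix(vm$intensities, vm$mask, 2L,
                               glcm_offsets_13())
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))
  # single-voxel ROI has no pairs
  expect_error(glcm_features(vm_from_values(1, c(3L, 3L, 3L))), "2 voxels")
})

test_that("wavelet bands match a direct separable convolution oracle", {
  with_seed <- radiofuse:::with_seed
  arr <- with_seed(11, array(rnorm(7 * 7 * 7), c(7L, 7L, 7L)))
  bands <- swt3_bands(arr)
  lo <- radiofuse:::coif1_lo
  hi <- radiofuse:::coif1_hi
  expect_equal(bands$LLL, oracle_conv3(arr, lo, lo, lo), tolerance = 1e-12)
  expect_equal(bands$HLH, oracle_conv3(arr, hi, lo, hi), tolerance = 1e-12)
  expect_equal(bands$HHH, oracle_conv3(arr, hi, hi, hi), tolerance = 1e-12)
})

test_that("wavelet features: detail bands of a constant volume vanish", {
  vm <- vm_from_values(rep(100, 8 * 8 * 8), c(8L, 8L, 8L))
  wf <- wavelet_features(vm)
  expect_length(wf, 368L)
  for (band in c("LLH", "LHL", "HLL", "LHH", "HLH", "HHL", "HHH")) {
    expect_equal(unname(wf[sprintf("wavelet.%s.fo.mean", band)]), 0,
                 tolerance = 1e-9)
  }
  expect_error(swt3_bands(array(0, c(4L, 8L, 8L))), "shorter")
})

test_that("the full handcrafted catalogue has 431 stable, finite features", {
  vm <- fixture_phantom()
  hc <- extract_hc(vm)
  expect_length(hc, 431L)
  expect_false(anyDuplicated(names(hc)) > 0)
  expect_true(all(is.finite(hc)))
  expect_identical(names(extract_hc(vm)), names(hc))
  # intensity scaling moves intensity features but not shape
  vm2 <- vm
  vm2$intensities <- vm$intensities * 2
  hc2 <- extract_hc(vm2)
  shape_ids <- grep("^shape\\.", names(hc), value = TRUE)
  expect_identical(hc[shape_ids], hc2[shape_ids])
  expect_false(isTRUE(all.equal(hc["fo.mean"], hc2["fo.mean"])))
})

test_that("rotation-invariant features survive axis-aligned rotation", {
  vm <- fixture_phantom()
  rot <- function(a) aperm(a[, dim(a)[2]:1, ], c(2, 1, 3))  # 90 deg about z
  vmr <- volume_mask(rot(vm$intensities), rot(vm$mask), vm$spacing, "ROT")
  fo <- first_order(vm); fo_r <- first_order(vmr)
  expect_equal(fo, fo_r, tolerance = 1e-9)
  sh <- shape_features(vm); sh_r <- shape_features(vmr)
  inv <- c("shape.volume", "shape.surface_area", "shape.sphericity",
           "shape.max_diameter_3d", "shape.major_axis", "shape.elongation")
  expect_equal(sh[inv], sh_r[inv], tolerance = 1e-9)
})

test_that("all 431 features stay finite across fuzzed phantoms", {
  for (seed in 1:4) {
    spec <- phantom_spec(grid_shape = c(20L, 20L, 20L),
                         semi_axes = 3 + 5 * ((seed %% 3) + 1) / 3 * c(1, 0.9, 1.1),
                         texture_scale = 50 * seed,
                         background_noise_sd = 10 * seed)
    hc <- extract_hc(generate_phantom(spec, seed))
    expect_true(all(is.finite(hc)))
    expect_length(hc, 431L)
  }
})
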