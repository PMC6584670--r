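unit_roi <- function(intens, mask, spacing = c(1, 1, 1))
  lesion_roi(intens, mask, spacing)

test_that("lesion volume is voxel count times voxel volume", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  roi <- unit_roi(array(0, c(3, 3, 3)), m)
  expect_equal(roi_volume(roi), 1)

  m2 <- array(FALSE, c(4, 4, 4)); m2[2:3, 2:3, 2:3] <- TRUE
  roi2 <- unit_roi(array(0, c(4, 4, 4)), m2, c(0.5, 0.5, 2.5))
  expect_equal(roi_volume(roi2), 8 * 0.625)

  set.seed(7)
  m3 <- array(runif(6 * 5 * 4) < 0.3, c(6, 5, 4))
  m3[1, 1, 1] <- TRUE
  roi3 <- unit_roi(array(0, dim(m3)), m3, c(0.7, 1.1, 2))
  expect_equal(roi_volume(roi3), sum(m3) * 0.7 * 1.1 * 2)
  expect_error(lesion_roi(array(0, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
               "empty")
})

test_that("surface area is accurate on spheres and scales with spacing", {
  ph <- make_phantom(radius_mm = 20, texture = "constant")
  truth <- attr(ph, "truth")
  expect_equal(roi_surface_area(ph), truth$surface_mm2, tolerance = 0.03)
  expect_equal(roi_volume(ph), truth$volume_mm3, tolerance = 0.01)

  # single voxel: boundary-face fallback gives the 6 faces of the cube
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  expect_equal(roi_surface_area(unit_roi(array(0, c(3, 3, 3)), m)), 6)

  # isotropic spacing scale s: area scales as s^2, volume as s^3
  ph1 <- make_phantom(radius_mm = 8, spacing = c(1, 1, 1))
  ph2 <- lesion_roi(ph1$intensities, ph1$mask, c(2, 2, 2))
  expect_equal(roi_surface_area(ph2), 4 * roi_surface_area(ph1),
               tolerance = 1e-10)
  expect_equal(roi_volume(ph2), 8 * roi_volume(ph1))
})

test_that("features are invariant to translation and padding", {
  ph <- make_phantom(radius_mm = 6, texture = "constant")
  d <- dim(ph$mask)
  big <- array(FALSE, d + c(6, 4, 2))
  bigI <- array(0, d + c(6, 4, 2))
  big[6 + seq_len(d[1]), 4 + seq_len(d[2]), 2 + seq_len(d[3])] <- ph$mask
  bigI[6 + seq_len(d[1]), 4 + seq_len(d[2]), 2 + seq_len(d[3])] <-
    ph$intensities
  shifted <- lesion_roi(bigI, big, ph$spacing)
  expect_equal(roi_volume(shifted), roi_volume(ph))
  expect_equal(roi_surface_area(shifted), roi_surface_area(ph),
               tolerance = 1e-10)
  expect_equal(suppressWarnings(roi_histogram_features(shifted)),
               suppressWarnings(roi_histogram_features(ph)))
})

test_that("histogram features match their degenerate and analytic cases", {
  m <- array(TRUE, c(4, 4, 4))
  const <- unit_roi(array(77, c(4, 4, 4)), m)
  h <- suppressWarnings(roi_histogram_features(const))
  expect_equal(h$density, 77)
  expect_equal(h$entropy, 0)

  # uniform occupancy of 2^k distinct bins -> entropy k bits
  k <- 4
  vals <- rep(10 * (seq_len(2^k) - 1) + 5, each = 64 / 2^k)
  u <- unit_roi(array(vals, c(4, 4, 4)), m)
  expect_equal(roi_histogram_features(u)$entropy, k)

  # symmetric intensities -> skewness ~ 0; gaussian phantom kurtosis ~ 3
  set.seed(8)
  ph <- make_phantom(radius_mm = 12, texture = "gaussian")
  h2 <- roi_histogram_features(ph)
  expect_equal(h2$skewness_pos, 0, tolerance = 0.05)
  expect_equal(h2$kurtosis_pos, 3, tolerance = 0.15)
  expect_equal(roi_histogram_features(ph, excess_kurtosis = TRUE)$kurtosis_pos,
               h2$kurtosis_pos - 3)

  # fewer than 3 positive voxels -> NA moments with a warning
  neg <- array(-100, c(3, 3, 3)); neg[1, 1, 1] <- 50
  expect_warning(h3 <- roi_histogram_features(
    unit_roi(neg, array(TRUE, c(3, 3, 3)))), "positive")
  expect_true(is.na(h3$skewness_pos) && is.na(h3$kurtosis_pos))
})

test_that("core entropy erodes the rim and falls back when overeroded", {
  set.seed(9)
  ph <- make_phantom(radius_mm = 10, texture = "core_rim", rim_mm = 3)
  full <- roi_histogram_features(ph)$entropy
  core <- roi_entropy_inner(ph, margin_mm = 4)
  expect_lt(as.numeric(core), full)          # noisy rim excluded
  expect_false(attr(core, "fallback"))

  none <- roi_entropy_inner(ph, margin_mm = 0)
  expect_equal(as.numeric(none), full)

  deep <- roi_entropy_inner(ph, margin_mm = 50)
  expect_true(attr(deep, "fallback"))
  expect_equal(as.numeric(deep), full)
  expect_error(roi_entropy_inner(ph, margin_mm = -1), "nonnegative")
})

test_that("lesion aggregation is volume weighted and permutation invariant", {
  f1 <- c(volume = 10, density = 10, entropy = 2)
  f2 <- c(volume = 10, density = 30, entropy = 4)
  agg <- aggregate_lesions(list(f1, f2))
  expect_equal(agg[["volume"]], 20)
  expect_equal(agg[["density"]], 20)
  expect_equal(aggregate_lesions(list(f1)), f1)

  set.seed(10)
  fl <- lapply(1:3, function(i)
    c(volume = runif(1, 5, 50), density = rnorm(1, 40, 5),
      entropy = runif(1, 1, 6)))
  agg3 <- aggregate_lesions(fl)
  vols <- sapply(fl, `[[`, "volume"); w <- vols / sum(vols)
  expect_equal(agg3[["density"]], sum(w * sapply(fl, `[[`, "density")))
  expect_equal(agg3[["entropy"]], sum(w * sapply(fl, `[[`, "entropy")))
  expect_equal(aggregate_lesions(fl[c(3, 1, 2)]), agg3)
  expect_error(aggregate_lesions(list()), "empty")
  expect_error(aggregate_lesions(rep(list(f1), 6)), "at most 5")
})

test_that("phantoms are reproducible and NIfTI io preserves features", {
  set.seed(20); a <- make_phantom(8, texture = "gaussian")
  set.seed(20); b <- make_phantom(8, texture = "gaussian")
  expect_identical(a, b)

  set.seed(22)
  ph <- make_phantom(6, spacing = c(1, 1, 2), texture = "gaussian")
  img <- tempfile(fileext = ".nii.gz"); msk <- tempfile(fileext = ".nii.gz")
  nii <- RNifti::asNifti(ph$intensities); RNifti::pixdim(nii) <- ph$spacing
  nmk <- RNifti::asNifti(ph$mask * 1); RNifti::pixdim(nmk) <- ph$spacing
  RNifti::writeNifti(nii, img)
  RNifti::writeNifti(nmk, msk)
  back <- read_lesion_nifti(img, msk)
  expect_equal(back$spacing, ph$spacing)
  expect_equal(roi_volume(back), roi_volume(ph))
  expect_equal(roi_features(back), roi_features(ph), tolerance = 1e-6)
})
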