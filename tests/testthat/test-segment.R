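# easy high-contrast phantom at the binned working resolution (3.2 um):
# lesions span several inter-sinusoid spacings there, which is the scale the
# lesion detector is designed for
easy_spec <- function(shape = 96L, lesion = 0.3, noise = 0, seed = 11)
  phantom_spec(shape = rep(shape, 3L), voxel_size_um = 3.2,
               lesion_target_fraction = lesion,
               sinusoid_radius_healthy_um = 5,
               sinusoid_radius_lesion_um = 10,
               sinusoid_fraction_healthy = 0.12,
               sinusoid_fraction_lesion = 0.06,
               n_vessels = 1L, vessel_radius_um = 20,
               bias_gradient = c(0, 0, 0), artifact_density = 0,
               noise_sd = noise, seed = seed)

test_that("dice coefficient has its closed-form values", {
  d <- c(6, 6, 6)
  a <- array(FALSE, d); a[1:2, 1, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, d); b[1, 2:3, 1] <- TRUE
  expect_equal(dice(a, b), 0)
  a8 <- array(FALSE, d); a8[1:8] <- TRUE
  b8 <- array(FALSE, d); b8[5:12] <- TRUE
  expect_equal(dice(a8, b8), 0.5)
  expect_equal(dice(array(FALSE, d), array(FALSE, d)), 1)
  expect_error(dice(a, array(FALSE, c(5, 5, 5))), "shape")
})

test_that("lumen segmentation thresholds with polarity and size filtering", {
  v <- volume3d(array(0.5, c(20, 20, 20)), 1)
  expect_warning(m <- segment_lumen(v, segmenter_config()), "constant")
  expect_false(any(m))

  # two-level volume: dark tube in bright tissue
  a <- array(1, c(24, 24, 24))
  a[10:14, 10:14, ] <- 0
  v2 <- volume3d(a, 1)
  m2 <- segment_lumen(v2, segmenter_config())
  expect_equal(m2, a == 0)
  m2b <- segment_lumen(v2, segmenter_config(polarity = "lumen_bright",
                                            min_object_voxels = 1L))
  expect_equal(m2b, a == 1)

  # speckles below min_object_voxels are dropped
  a[1, 1, 1] <- 0
  m3 <- segment_lumen(volume3d(a, 1), segmenter_config(min_object_voxels = 8L))
  expect_false(m3[1, 1, 1])
  expect_true(all(m3[10:14, 10:14, ]))
})

test_that("vessel splitting assigns thick structures by local thickness", {
  d <- c(40, 40, 40)
  thin <- array(FALSE, d); thin[10:11, 10:11, ] <- TRUE  # radius ~1 voxel
  sv <- split_vessels(thin, voxel_size_um = 1.6,
                      segmenter_config(vessel_min_radius_um = 15))
  expect_false(any(sv$vessel))
  expect_equal(sv$sinusoid, thin)

  g <- expand.grid(z = 0:39, y = 0:39, x = 0:39)
  cyl <- array((g$z - 20)^2 + (g$y - 20)^2 < 12^2, d)  # radius 12 vox
  sv2 <- split_vessels(cyl, voxel_size_um = 1.6,
                       segmenter_config(vessel_min_radius_um = 15))
  expect_false(any(sv2$sinusoid))
  expect_equal(sum(sv2$vessel), sum(cyl))
  expect_false(any(sv2$sinusoid & sv2$vessel))
})

test_that("vessels in rendered phantoms are recovered with high recall", {
  p <- generate_phantom(easy_spec(lesion = 0, seed = 3))
  vol <- preprocess_volume(p$volume)
  cfg <- segmenter_config()
  lumen <- segment_lumen(vol, cfg)
  expect_gt(dice(lumen, p$truth$masks$sinusoid | p$truth$masks$vessel), 0.95)
  sv <- split_vessels(lumen, vol$voxel_size_um, cfg)
  tv <- p$truth$masks$vessel
  expect_gt(sum(sv$vessel & tv) / sum(tv), 0.9)
})

test_that("lesion detection is near-empty without structural contrast", {
  p <- generate_phantom(easy_spec(lesion = 0, seed = 4))
  vol <- preprocess_volume(p$volume)
  m <- segment_volume(vol, segmenter_config())
  expect_lte(mean(m$lesion), 0.02)
})

test_that("lesion masks never overlap vessels and region invariants hold", {
  p <- generate_phantom(easy_spec(seed = 6))
  vol <- preprocess_volume(p$volume)
  m <- segment_volume(vol, segmenter_config())
  expect_s3_class(m, "region_masks")
  expect_false(any(m$lesion & m$vessel))
  expect_false(any(m$sinusoid & m$vessel))
})

test_that("segmentation quality degrades monotonically with noise", {
  scores <- vapply(c(0, 0.1, 0.3), function(ns) {
    p <- generate_phantom(easy_spec(noise = ns, seed = 8))
    vol <- preprocess_volume(p$volume)
    lumen <- segment_lumen(vol, segmenter_config())
    dice(lumen, p$truth$masks$sinusoid | p$truth$masks$vessel)
  }, 0.0)
  expect_true(all(diff(scores) <= 0.02))
})
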