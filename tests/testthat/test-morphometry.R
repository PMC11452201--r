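test_that("local thickness follows the open-ball single-voxel convention", {
  o <- array(FALSE, c(9, 9, 9))
  o[5, 5, 5] <- TRUE
  tm <- local_thickness(o, voxel_size_um = 2)
  expect_equal(tm$values[5, 5, 5], 2)
  expect_true(all(is.na(tm$values[-which(o)])))
  expect_error(local_thickness(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("local thickness matches the exhaustive sphere search exactly", {
  set.seed(101)
  for (rep in 1:12) {
    d <- sample(6:16, 3, replace = TRUE)
    obj <- random_mask(d, p = runif(1, 0.2, 0.6),
                       mode = sample(c("noise", "balls"), 1))
    if (!any(obj)) next
    expect_identical(local_thickness(obj, 1)$values, oracle_thickness(obj))
  }
})

test_that("digital ball center and slab interior reproduce known radii", {
  g <- expand.grid(z = 0:31, y = 0:31, x = 0:31)
  ball <- array((g$z - 16)^2 + (g$y - 16)^2 + (g$x - 16)^2 < 36,
                c(32, 32, 32))
  tm <- local_thickness(ball, 1)
  expect_lt(abs(tm$values[17, 17, 17] - 6), 0.5)

  slab <- array(FALSE, c(30, 30, 15))
  slab[6:25, 6:25, 6:10] <- TRUE
  tm2 <- local_thickness(slab, 1)$values
  bf <- oracle_thickness(slab)
  interior <- array(FALSE, c(30, 30, 15))
  interior[12:19, 12:19, 8] <- TRUE
  expect_identical(tm2, bf)
  expect_equal(length(unique(tm2[interior])), 1L)
})

test_that("thickness is monotone under dilation and exactly scale-equivariant", {
  set.seed(202)
  for (rep in 1:8) {
    d <- sample(8:14, 3, replace = TRUE)
    a <- random_mask(d, p = 0.3)
    b <- a | random_mask(d, p = 0.15)
    if (!any(a)) next
    ta <- local_thickness(a, 1)$values
    tb <- local_thickness(b, 1)$values
    sel <- which(a)
    expect_true(all(tb[sel] >= ta[sel]))
    expect_identical(local_thickness(a, 3)$values, 3 * ta)
  }
})

test_that("anisotropic voxels use physical distances", {
  o <- array(FALSE, c(10, 12, 12))
  o[3:8, 2:11, 2:11] <- TRUE
  sp <- c(2.5, 1, 1.5)
  expect_equal(local_thickness(o, sp)$values, oracle_thickness(o, sp),
               tolerance = 1e-12)
})

test_that("volume proportions are exact integer-count ratios", {
  set.seed(7)
  d <- c(16, 16, 16)
  for (rep in 1:6) {
    lesion <- random_mask(d, 0.3)
    vessel <- random_mask(d, 0.1) & !lesion
    domain <- array(TRUE, d)
    lp <- lesion_volume_proportion(lesion, vessel, domain)
    num <- 0L; den <- 0L
    for (i in seq_along(lesion)) {
      if (domain[i] && !vessel[i]) {
        den <- den + 1L
        if (lesion[i]) num <- num + 1L
      }
    }
    expect_identical(lp, num / den)
    sin <- random_mask(d, 0.2)
    expect_identical(sinusoid_volume_proportion(sin, lesion),
                     sum(sin & lesion) / sum(lesion))
  }
  expect_equal(lesion_volume_proportion(array(FALSE, d),
                                        array(FALSE, d), array(TRUE, d)), 0)
  dom <- array(TRUE, d)
  expect_equal(lesion_volume_proportion(dom, array(FALSE, d), dom), 1)
  expect_error(sinusoid_volume_proportion(dom, array(FALSE, d)), "empty")
  expect_error(lesion_volume_proportion(dom, dom, dom), "empty")
})

test_that("lesion proportion and its complement partition to one", {
  set.seed(8)
  d <- c(12, 12, 12)
  lesion <- random_mask(d, 0.4)
  vessel <- random_mask(d, 0.1) & !lesion
  domain <- array(TRUE, d)
  rest <- domain & !vessel & !lesion
  expect_identical(lesion_volume_proportion(lesion, vessel, domain) +
                     lesion_volume_proportion(rest, vessel, domain), 1)
})

test_that("region thickness stats summarize only the selected voxels", {
  d <- c(10, 10, 10)
  sin <- array(FALSE, d); sin[3:6, 3:6, 3:6] <- TRUE
  tmap <- structure(list(values = array(NA_real_, d),
                         voxel_size_um = rep(1, 3)),
                    class = "thickness_map")
  tmap$values[sin] <- 4
  region <- array(TRUE, d)
  st <- region_thickness_stats(tmap, sin, region)
  expect_equal(st$mean, 4)
  expect_equal(st$median, 4)
  expect_equal(st$n_voxels, sum(sin))
  expect_error(region_thickness_stats(tmap, sin, array(FALSE, d)),
               "no sinusoid voxels")
})

test_that("quantify_sample handles lesion-free samples and is deterministic", {
  p <- generate_phantom(tiny_spec(lesion_target_fraction = 0, seed = 5))
  q <- quantify_sample(p$truth$masks, sample_id = "s0")
  expect_equal(q$lesion_volume_proportion, 0)
  expect_true(is.na(q$sinusoid_volume_proportion_lesion))
  expect_true(is.na(q$thickness_mean_lesion))
  expect_true(q$sinusoid_volume_proportion_healthy >= 0 &&
                q$sinusoid_volume_proportion_healthy <= 1)
  q2 <- quantify_sample(p$truth$masks, sample_id = "s0")
  expect_identical(q, q2)
})
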