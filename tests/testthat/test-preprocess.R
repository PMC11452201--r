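mkvol <- function(a, vs = 1) volume3d(a, voxel_size_um = vs)

test_that("binning averages blocks exactly and scales the voxel size", {
  v <- mkvol(array(5, c(4, 4, 4)), vs = 1.6)
  b <- bin_volume(v, 2)
  expect_true(all(b$data == 5))
  expect_equal(b$voxel_size_um, rep(3.2, 3))

  v2 <- mkvol(array(0:7, c(2, 2, 2)))
  expect_equal(as.numeric(bin_volume(v2, 2)$data), 3.5)

  set.seed(1)
  a <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(bin_volume(mkvol(a), 2)$data, oracle_bin(a, 2))
  expect_identical(bin_volume(mkvol(a), 4)$data, oracle_bin(a, 4))
  expect_error(bin_volume(mkvol(a), 0), "positive")
})

test_that("binning preserves the global mean and commutes with offsets", {
  set.seed(2)
  a <- array(rnorm(6 * 8 * 4), c(6, 8, 4))
  b <- bin_volume(mkvol(a), 2)
  expect_equal(mean(b$data), mean(a), tolerance = 1e-12)
  b2 <- bin_volume(mkvol(a + 3), 2)
  expect_equal(b2$data, b$data + 3, tolerance = 1e-12)
})

test_that("non-divisible dimensions are cropped and logged", {
  set.seed(3)
  a <- array(rnorm(7 * 8 * 9), c(7, 8, 9))
  b <- bin_volume(mkvol(a), 2)
  expect_equal(dim(b$data), c(3L, 4L, 4L))
  expect_identical(b$data, oracle_bin(a[1:6, 1:8, 1:8], 2))
  last <- b$provenance[[length(b$provenance)]]
  expect_true(isTRUE(last$cropped))
})

test_that("bias correction removes a model-matched linear field", {
  d <- c(12, 14, 16)
  x <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  ramp <- array(100 * (1 + 0.01 * x), d)
  out <- correct_bias(mkvol(ramp))
  expect_lt(max(abs(out$data - mean(out$data))) / mean(out$data), 1e-6)
  expect_equal(mean(out$data), mean(ramp), tolerance = 1e-8)

  flat <- mkvol(array(7, d))
  expect_equal(correct_bias(flat)$data, flat$data, tolerance = 1e-12)
})

test_that("bias correction flattens a textured ramp to below 1% residual slope", {
  set.seed(4)
  d <- c(16, 16, 16)
  tex <- array(runif(prod(d), 0.5, 1.5), d)
  z <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  y <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  x <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  slope_in <- 0.03
  biased <- tex * (1 + slope_in * array(x, d))
  out <- correct_bias(mkvol(biased))
  for (coord in list(z, y, x)) {
    fit <- lm(as.numeric(out$data) ~ coord)
    expect_lt(abs(coef(fit)[2]) / mean(out$data), 0.01 * slope_in)
  }
})

test_that("bias correction rejects degenerate fits and non-positive volumes", {
  d <- c(8, 8, 8)
  m <- array(FALSE, d); m[4, , ] <- TRUE  # single slice: z not identifiable
  set.seed(5)
  v <- mkvol(array(runif(prod(d), 1, 2), d))
  expect_error(correct_bias(v, m), "degenerate")
  neg <- v; neg$data[1] <- -1
  expect_error(correct_bias(neg), "positive")
})

test_that("bright-artifact suppression clamps only the in-mask tail", {
  d <- c(10, 10, 10)
  a <- array(1, d)
  expect_equal(suppress_bright(mkvol(a), percentile = 99)$data, a)

  a[5, 5, 5] <- 50
  out <- suppress_bright(mkvol(a), percentile = 99.5)
  thr <- quantile(a, 0.995, names = FALSE)
  expect_equal(out$data[5, 5, 5], thr)
  expect_true(all(out$data[-which(a == 50)] == 1))

  set.seed(6)
  r <- array(rnorm(16^3), c(16, 16, 16))
  pct <- 98
  out2 <- suppress_bright(mkvol(r), percentile = pct)
  expect_true(all(out2$data <= r + 1e-15))
  n_mod <- sum(out2$data != r)
  expect_lte(n_mod, (100 - pct) / 100 * length(r) + 1)
})

test_that("normalization anchors the 1st/99th percentiles at 0/1", {
  set.seed(7)
  a <- array(rnorm(20^3, 10, 4), c(20, 20, 20))
  out <- normalize_intensity(mkvol(a))
  p <- quantile(out$data, c(0.01, 0.99), names = FALSE)
  expect_lt(abs(p[1] - 0), 1e-6)
  expect_lt(abs(p[2] - 1), 1e-6)
  expect_true(all(out$data >= 0 & out$data <= 1))

  out2 <- normalize_intensity(mkvol(2.5 * a + 7))
  expect_equal(out2$data, out$data, tolerance = 1e-12)

  expect_error(normalize_intensity(mkvol(array(3, c(8, 8, 8)))), "spread")
})

test_that("the preprocessing chain records its provenance in order", {
  set.seed(8)
  a <- array(runif(8^3, 0.5, 1.5), c(8, 8, 8))
  out <- preprocess_volume(mkvol(a), factor = 2, percentile = 99)
  ops <- vapply(out$provenance, `[[`, "", "op")
  expect_equal(ops, c("bin_volume", "correct_bias", "suppress_bright",
                      "normalize_intensity"))
})
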