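test_that("phantom specs are validated", {
  expect_error(phantom_spec(shape = c(8, 8, 8)), ">= 16")
  expect_error(phantom_spec(lesion_target_fraction = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(noise_sd = -1), "non-negative")
  expect_silent(validate_phantom_spec <- phantom_spec(seed = 3))
})

test_that("degenerate targets force empty masks", {
  p0 <- generate_phantom(tiny_spec(lesion_target_fraction = 0, seed = 2))
  expect_false(any(p0$truth$masks$lesion))
  expect_identical(p0$truth$achieved_lesion_fraction, 0)

  ps <- generate_phantom(tiny_spec(sinusoid_fraction_healthy = 0,
                                   sinusoid_fraction_lesion = 0, seed = 2))
  expect_false(any(ps$truth$masks$sinusoid))
})

test_that("phantoms are bit-deterministic in volume and masks", {
  s <- tiny_spec(lesion_target_fraction = 0.25, seed = 42)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$masks, b$truth$masks)
})

test_that("mask invariants hold and truth fractions are recomputable", {
  p <- generate_phantom(tiny_spec(lesion_target_fraction = 0.3, seed = 9))
  m <- p$truth$masks
  expect_false(any(m$vessel & m$lesion))
  expect_false(any(m$vessel & m$sinusoid))
  expect_true(all(!m$sinusoid | m$domain))
  expect_true(all(!m$lesion | m$domain))
  nonvessel <- sum(m$domain & !m$vessel)
  expect_identical(p$truth$achieved_lesion_fraction,
                   sum(m$lesion) / nonvessel)
  expect_identical(p$truth$achieved_sinusoid_fraction_lesion,
                   sum(m$sinusoid & m$lesion) / sum(m$lesion))
  healthy <- m$domain & !m$lesion & !m$vessel
  expect_identical(p$truth$achieved_sinusoid_fraction_healthy,
                   sum(m$sinusoid & healthy) / sum(healthy))
})

test_that("achieved fractions land inside the tolerance bands", {
  p <- generate_phantom(tiny_spec(lesion_target_fraction = 0.3, seed = 13))
  expect_lt(abs(p$truth$achieved_lesion_fraction - 0.3), 0.03)
  expect_lt(abs(p$truth$achieved_sinusoid_fraction_healthy - 0.12), 0.02)
  expect_lt(abs(p$truth$achieved_sinusoid_fraction_lesion - 0.07), 0.02)
})

test_that("unreachable targets fail explicitly reporting the achieved value", {
  expect_error(
    generate_phantom(phantom_spec(shape = c(16, 16, 16),
                                  lesion_target_fraction = 0.98,
                                  n_vessels = 0L, seed = 1)),
    "unreachable.*achieved")
})

test_that("the inverse caliber contrast is supported for negative controls", {
  p <- generate_phantom(tiny_spec(lesion_target_fraction = 0.3,
                                  sinusoid_radius_healthy_um = 8,
                                  sinusoid_radius_lesion_um = 4,
                                  seed = 21))
  m <- p$truth$masks
  tm <- local_thickness(m$sinusoid, p$truth$spec$voxel_size_um)
  healthy <- m$domain & !m$lesion & !m$vessel
  expect_gt(mean(tm$values[m$sinusoid & healthy]),
            mean(tm$values[m$sinusoid & m$lesion]))
})

test_that("cohort generation is deterministic and stage-resolved", {
  sch <- cohort_schedule("one", 0.2, n_replicates = 2, base_seed = 5)
  c1 <- generate_cohort(sch, tiny_spec())
  c2 <- generate_cohort(sch, tiny_spec())
  expect_identical(c1[[1]]$volume$data, c2[[1]]$volume$data)
  expect_identical(c1[[2]]$truth$masks, c2[[2]]$truth$masks)
  expect_false(identical(c1[[1]]$volume$data, c1[[2]]$volume$data))
})

test_that("the default timeline preset yields increasing lesion burden", {
  cohort <- generate_cohort(nif_timeline(n_replicates = 2, base_seed = 3),
                            phantom_spec(shape = c(64, 96, 96)))
  labs <- vapply(cohort, `[[`, "", "label")
  fr <- vapply(cohort, function(s) s$truth$achieved_lesion_fraction, 0.0)
  stage_means <- tapply(fr, factor(labs, levels = c("4wk", "6wk", "8wk")),
                        mean)
  expect_true(all(diff(stage_means) > 0))
  expect_lt(abs(stage_means[["4wk"]] - 0.05), 0.03)
  expect_lt(abs(stage_means[["8wk"]] - 0.40), 0.03)
})

test_that("stage context is attached to generation failures", {
  sch <- cohort_schedule("bad", 0.9, n_replicates = 1, base_seed = 1)
  expect_error(
    generate_cohort(sch, phantom_spec(shape = c(16, 16, 16), n_vessels = 0L)),
    "stage 'bad'")
})
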