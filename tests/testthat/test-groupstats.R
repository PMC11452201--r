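mk_table <- function(values, groups, metric = "m",
                     region = NA_character_) {
  sample_table(data.frame(
    sample_id = paste0("s", seq_along(values)), phenotype = "NIF",
    age_group = groups, region = region, metric = metric, value = values,
    stringsAsFactors = FALSE))
}

mk_table2 <- function(df) {
  df$sample_id <- paste0("s", seq_len(nrow(df)))
  df$phenotype <- "NIF"
  df$metric <- "m"
  sample_table(df)
}

test_that("kruskal-wallis handles ties, degeneracy and known statistics", {
  tb <- mk_table(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  r <- kruskal_dunn(tb, "m", "age_group")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_match(r$flags, "degenerate")

  tb2 <- mk_table(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  r2 <- kruskal_dunn(tb2, "m", "age_group", exact_max_n = 0L)
  # direct rank-formula evaluation: R1 = 6, R2 = 15, N = 6
  H_direct <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(r2$statistic, H_direct)

  expect_error(kruskal_dunn(mk_table(1:4, c("a", "a", "a", "b")), "m",
                            "age_group"), "fewer than 2")
})

test_that("small-sample kruskal-wallis p equals the exhaustive permutation null", {
  set.seed(31)
  cases <- list(
    list(n = c(3, 3, 3)), list(n = c(4, 4)), list(n = c(3, 4, 3)),
    list(n = c(2, 2, 3)), list(n = c(4, 4, 4)))
  for (cs in cases) {
    g <- rep(letters[seq_along(cs$n)], cs$n)
    v <- round(rnorm(sum(cs$n)), 2)  # rounding introduces occasional ties
    r <- kruskal_dunn(mk_table(v, g), "m", "age_group")
    expect_equal(r$p, oracle_kw_perm(v, g), tolerance = 1e-12)
  }
})

test_that("dunn comparisons carry valid family-wise adjustment", {
  set.seed(32)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  r <- kruskal_dunn(mk_table(v, g), "m", "age_group")
  expect_equal(nrow(r$comparisons), 3L)
  expect_true(all(r$comparisons$p_adjusted >= r$comparisons$p_raw - 1e-15))
  expect_true(all(r$comparisons$p_adjusted <= 1))
  expect_equal(r$comparisons$p_adjusted,
               pmin(1, r$comparisons$p_raw * 3))
})

test_that("dunnett with two groups collapses to the pooled t-test", {
  set.seed(33)
  v <- c(rnorm(8), rnorm(8, 1))
  g <- rep(c("ctrl", "trt"), each = 8)
  r <- dunnett_test(mk_table(v, g), "m", "age_group", control_level = "ctrl")
  tt <- t.test(v[g == "trt"], v[g == "ctrl"], var.equal = TRUE)
  expect_equal(r$comparisons$p_adjusted, tt$p.value, tolerance = 1e-6)
})

test_that("dunnett degenerates gracefully and validates its control level", {
  tb <- mk_table(rep(2, 12), rep(c("a", "b", "c"), each = 4))
  r <- dunnett_test(tb, "m", "age_group", control_level = "a")
  expect_true(all(r$comparisons$p_adjusted == 1))
  expect_error(dunnett_test(tb, "m", "age_group", control_level = "zz"),
               "absent")
})

test_that("anova fallback takes the two-way branch without interaction", {
  set.seed(34)
  df <- expand.grid(age_group = c("w4", "w6", "w8"),
                    region = c("healthy", "lesion"), rep = 1:6)
  df$value <- rnorm(nrow(df), sd = 0.3) +
    2 * (df$region == "lesion")  # pure region effect, no interaction
  r <- anova_with_fallback(mk_table2(df), "m", factor_a = "age_group",
                           factor_b = "region")
  expect_equal(r$branch, "two_way")
  expect_lt(r$p_main[["region"]], 0.001)
  expect_gte(r$p, 0.05)
})

test_that("anova fallback switches to stratified one-way under interaction", {
  set.seed(35)
  df <- expand.grid(age_group = c("w4", "w6", "w8"),
                    region = c("healthy", "lesion"), rep = 1:6)
  df$value <- rnorm(nrow(df), sd = 0.3) +
    3 * (df$region == "lesion") * (df$age_group == "w8")
  r <- anova_with_fallback(mk_table2(df), "m", factor_a = "age_group",
                           factor_b = "region", control_level = "w4")
  expect_equal(r$branch, "one_way_fallback")
  expect_lt(r$p, 0.05)
  expect_true(any(grepl("one-way", r$comparisons$comparison)))
  expect_true(any(grepl("w8 vs w4", r$comparisons$comparison)))
})

test_that("anova fallback reports empty design cells", {
  df <- data.frame(age_group = c("w4", "w4", "w6", "w6"),
                   region = c("healthy", "healthy", "healthy", "lesion"),
                   value = rnorm(4))
  expect_error(anova_with_fallback(mk_table2(df), "m",
                                   factor_a = "age_group",
                                   factor_b = "region"),
               "empty design cells")
})

test_that("interaction p-values are uniform under a balanced null", {
  set.seed(36)
  grid <- expand.grid(age_group = c("a", "b", "c"), region = c("x", "y"),
                      rep = 1:4)
  ps <- replicate(400, {
    grid$value <- rnorm(nrow(grid))
    anova_with_fallback(mk_table2(grid), "m", factor_a = "age_group",
                        factor_b = "region")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bonferroni pairwise t-tests respect the declared family", {
  set.seed(37)
  v <- rnorm(20); g <- rep(c("a", "b", "c", "d"), each = 5)
  one <- pairwise_t_bonferroni(mk_table(v, g), "m", "age_group",
                               pairs = matrix(c("a", "b"), 2))
  expect_equal(one$comparisons$p_adjusted, one$comparisons$p_raw)

  all6 <- pairwise_t_bonferroni(mk_table(v, g), "m", "age_group")
  expect_equal(nrow(all6$comparisons), 6L)
  expect_equal(all6$comparisons$p_adjusted,
               pmin(1, all6$comparisons$p_raw * 6))
})

test_that("scan averaging collapses pseudo-replicates", {
  df <- data.frame(sample_id = c("m1", "m1", "m2"), phenotype = "NIF",
                   age_group = "w4", region = "lesion", metric = "m",
                   value = c(1, 3, 5), stringsAsFactors = FALSE)
  expect_error(sample_table(df), "duplicate")
  avg <- average_scans(df)
  expect_equal(sort(avg$value), c(2, 5))
})

test_that("test reports flatten to tidy rows", {
  set.seed(38)
  r <- kruskal_dunn(mk_table(rnorm(15), rep(c("a", "b", "c"), each = 5)),
                    "m", "age_group")
  df <- as.data.frame(r)
  expect_true(all(c("test", "comparison", "p_raw", "p_adjusted") %in%
                    names(df)))
  expect_equal(nrow(df), 4L)  # omnibus row + 3 comparisons
})
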