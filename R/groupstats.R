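#' Tidy sample table for group comparisons
#'
#' Long-format container for per-sample morphometry values: one row per
#' (sample, metric, region). Columns: `sample_id`, `phenotype`, `age_group`,
#' `region` (`"lesion"`, `"healthy"` or `NA` for whole-sample metrics),
#' `metric`, `value`.
#'
#' @param df data frame with the columns above.
#' @return The validated data frame (class `sample_table`).
#' @export
sample_table <- function(df) {
  needed <- c("sample_id", "phenotype", "age_group", "region", "metric",
              "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("sample table lacks columns: ", paste(missing_cols, collapse = ", "))
  key <- paste(df$sample_id, df$metric,
               ifelse(is.na(df$region), "<whole>", df$region))
  if (anyDuplicated(key))
    stop("duplicate (sample, metric, region) rows; average scans first ",
         "(see average_scans())")
  class(df) <- unique(c("sample_table", class(df)))
  df
}

#' Average repeated scans to one value per sample
#'
#' Multiple scans of the same specimen are pseudo-replicates; by default they
#' are averaged to a single value per (sample, metric, region) before any
#' group test. Scan-level analysis remains available by skipping this step.
#'
#' @param df long-format data frame with the [sample_table()] columns (rows
#'   may repeat per scan).
#' @return A [sample_table()] with one row per (sample, metric, region).
#' @export
average_scans <- function(df) {
  agg <- aggregate(value ~ sample_id + phenotype + age_group + region +
                     metric, data = df, FUN = mean, na.action = stats::na.omit)
  sample_table(agg)
}

new_test_report <- function(test, metric, factors, statistic, df, p,
                            comparisons, adjust_method, trace,
                            flags = character()) {
  structure(list(test = test, metric = metric, factors = factors,
                 statistic = statistic, df = df, p = p,
                 comparisons = comparisons, adjust_method = adjust_method,
                 trace = trace, flags = flags),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("test_report: %s on '%s' (%s)\n", x$test, x$metric,
              paste(x$factors, collapse = " x ")))
  cat(sprintf("  statistic %.4g, p = %.4g\n", x$statistic, x$p))
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat(sprintf("  %d comparisons, %s-adjusted\n", nrow(x$comparisons),
                x$adjust_method))
    print(x$comparisons, row.names = FALSE)
  }
  for (tr in x$trace) cat("  trace:", tr, "\n")
  invisible(x)
}

#' @export
as.data.frame.test_report <- function(x, ...) {
  base <- data.frame(test = x$test, metric = x$metric,
                     factors = paste(x$factors, collapse = ":"),
                     statistic = x$statistic, p = x$p,
                     comparison = NA_character_, p_raw = NA_real_,
                     p_adjusted = NA_real_,
                     adjust_method = x$adjust_method,
                     stringsAsFactors = FALSE)
  if (is.null(x$comparisons) || !nrow(x$comparisons)) return(base)
  cmp <- data.frame(test = x$test, metric = x$metric,
                    factors = paste(x$factors, collapse = ":"),
                    statistic = x$comparisons$statistic,
                    p = x$p,
                    comparison = x$comparisons$comparison,
                    p_raw = x$comparisons$p_raw,
                    p_adjusted = x$comparisons$p_adjusted,
                    adjust_method = x$adjust_method,
                    stringsAsFactors = FALSE)
  rbind(base, cmp)
}

extract_groups <- function(table, metric, factor, min_per_group = 2L) {
  sub <- table[table$metric == metric & !is.na(table$value), , drop = FALSE]
  if (!nrow(sub)) stop("no observations for metric '", metric, "'")
  g <- factor(sub[[factor]])
  sizes <- table(g)
  small <- names(sizes)[sizes < min_per_group]
  if (length(small))
    stop("group(s) with fewer than ", min_per_group, " observations: ",
         paste(small, collapse = ", "))
  list(value = sub$value, g = droplevels(g))
}

# tie-corrected Kruskal-Wallis H from rank sums
kw_h_stat <- function(r, g) {
  N <- length(r)
  Ri <- tapply(r, g, sum)
  ni <- tabulate(g)
  H0 <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) return(NA_real_)
  H0 / C
}

# exact permutation distribution of H by exhaustive enumeration of all
# distinct assignments of the observations to the group sizes
kw_exact_p <- function(value, g) {
  r <- rank(value)
  ni <- tabulate(g)
  k <- length(ni)
  H_obs <- kw_h_stat(r, g)
  N <- length(r)
  count_ge <- 0L
  count_all <- 0L
  # exhaustive enumeration via recursion over combinations
  assign_labels <- function(avail, gi, labels) {
    if (gi == k) {
      labels[avail] <- k
      h <- kw_h_stat(r, factor(labels, levels = seq_len(k)))
      count_all <<- count_all + 1L
      if (h >= H_obs - 1e-10) count_ge <<- count_ge + 1L
      return(invisible(NULL))
    }
    combs <- utils::combn(avail, ni[gi])
    for (ci in seq_len(ncol(combs))) {
      sel <- combs[, ci]
      labels2 <- labels
      labels2[sel] <- gi
      assign_labels(setdiff(avail, sel), gi + 1L, labels2)
    }
    invisible(NULL)
  }
  assign_labels(seq_len(N), 1L, integer(N))
  list(p = count_ge / count_all, n_perm = count_all, H = H_obs)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis omnibus test across the levels of a grouping
#' factor, followed by Dunn's pairwise z tests on mean ranks with a
#' family-wise adjustment over all pairs. For small samples (total n at or
#' below `exact_max_n`) the omnibus p-value is computed by exhaustive
#' permutation of the group assignment instead of the chi-squared
#' approximation.
#'
#' @param table a [sample_table()].
#' @param metric metric name to test.
#' @param factor column name of the grouping factor.
#' @param p_adjust family-wise adjustment for the Dunn comparisons (any
#'   method of [stats::p.adjust()]; default Bonferroni, the standard reading
#'   of a "Dunn's multiple comparisons" correction).
#' @param exact_max_n largest total sample size for which the exact
#'   permutation null is enumerated.
#' @return A `test_report`.
#' @export
kruskal_dunn <- function(table, metric, factor = "age_group",
                         p_adjust = "bonferroni", exact_max_n = 12L) {
  gr <- extract_groups(table, metric, factor)
  value <- gr$value; g <- gr$g
  k <- nlevels(g); N <- length(value)
  if (k < 2L) stop("need at least 2 groups")
  flags <- character(); trace <- character()

  if (length(unique(value)) == 1L) {
    H <- 0; p <- 1
    flags <- "degenerate: all observations identical; p reported as 1"
    trace <- "all values tied"
  } else if (N <= exact_max_n) {
    ex <- kw_exact_p(value, g)
    H <- ex$H; p <- ex$p
    trace <- sprintf("exact permutation null (%d assignments)", ex$n_perm)
  } else {
    kt <- kruskal.test(value, g)
    H <- unname(kt$statistic); p <- kt$p.value
    trace <- "chi-squared approximation"
  }

  # Dunn pairwise z statistics on mean ranks, tie-corrected
  r <- rank(value)
  Rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2L)
  cmp <- data.frame(comparison = character(0), statistic = numeric(0),
                    p_raw = numeric(0), p_adjusted = numeric(0))
  if (length(unique(value)) > 1L) {
    zs <- apply(pairs, 2L, function(pr) {
      i <- match(pr[1], levels(g)); j <- match(pr[2], levels(g))
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
      (Rbar[i] - Rbar[j]) / se
    })
    p_raw <- 2 * pnorm(-abs(zs))
    cmp <- data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                      statistic = as.numeric(zs), p_raw = p_raw,
                      p_adjusted = p.adjust(p_raw, p_adjust),
                      stringsAsFactors = FALSE)
  } else {
    cmp <- data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                      statistic = 0, p_raw = 1, p_adjusted = 1,
                      stringsAsFactors = FALSE)
  }
  new_test_report("kruskal_dunn", metric, factor, H, k - 1L, p, cmp,
                  p_adjust, trace, flags)
}

# Dunnett many-to-one comparisons via single-step multivariate-t adjustment
dunnett_core <- function(value, g, control_level) {
  g <- droplevels(factor(g))
  if (!control_level %in% levels(g))
    stop("control level '", control_level, "' absent")
  g <- stats::relevel(g, ref = control_level)
  means <- tapply(value, g, mean)
  dat <- data.frame(value = value, g = g)
  if (isTRUE(all.equal(var(value), 0)) ||
      sum(tapply(value, g, var), na.rm = TRUE) == 0) {
    # zero residual variance: identical constants within groups
    others <- setdiff(levels(g), control_level)
    p <- ifelse(abs(means[others] - means[[control_level]]) < 1e-12, 1, 0)
    return(data.frame(
      comparison = paste(others, control_level, sep = " vs "),
      statistic = ifelse(p == 1, 0, Inf), p_raw = p, p_adjusted = p,
      stringsAsFactors = FALSE))
  }
  fit <- aov(value ~ g, data = dat)
  gh <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gh, test = multcomp::adjusted("single-step"))
  tt <- sm$test
  others <- setdiff(levels(g), control_level)
  p_raw <- 2 * pt(-abs(tt$tstat), df = fit$df.residual)
  data.frame(comparison = paste(others, control_level, sep = " vs "),
             statistic = as.numeric(tt$tstat), p_raw = as.numeric(p_raw),
             p_adjusted = pmin(pmax(as.numeric(tt$pvalues),
                                    as.numeric(p_raw)), 1),
             stringsAsFactors = FALSE)
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Compares every group mean with a declared control level using the
#' single-step Dunnett procedure (multivariate-t critical values, via
#' `multcomp`). With two groups this collapses to the ordinary two-sided
#' pooled-variance t-test.
#'
#' @param table a [sample_table()].
#' @param metric metric to test.
#' @param factor grouping factor column.
#' @param control_level level used as control.
#' @return A `test_report`.
#' @export
dunnett_test <- function(table, metric, factor = "age_group",
                         control_level) {
  gr <- extract_groups(table, metric, factor)
  if (nlevels(gr$g) < 2L) stop("need at least 2 groups")
  cmp <- dunnett_core(gr$value, gr$g, control_level)
  new_test_report("dunnett", metric, factor,
                  statistic = max(abs(cmp$statistic)), df = NA_real_,
                  p = min(cmp$p_adjusted), cmp, "single-step Dunnett",
                  trace = sprintf("control level '%s'", control_level))
}

#' Two-way ANOVA with interaction-triggered one-way fallback
#'
#' Fits a two-way ANOVA with interaction on two crossed factors. If the
#' interaction is significant at `alpha`, main effects are not interpretable
#' and the analysis falls back to separate one-way ANOVAs across `factor_a`
#' within each level of `factor_b`, each followed by Dunnett comparisons
#' against the declared control level of `factor_a`. The decision trace
#' records which branch ran.
#'
#' @param table a [sample_table()].
#' @param metric metric to test.
#' @param factor_a factor of interest (Dunnett-compared in the fallback).
#' @param factor_b stratifying factor.
#' @param alpha significance threshold for the interaction test.
#' @param control_level control level of `factor_a` for the fallback Dunnett
#'   comparisons; defaults to the first level.
#' @return A `test_report`; `p` is the interaction p-value, main-effect and
#'   per-stratum results are in `comparisons` and `trace`.
#' @export
anova_with_fallback <- function(table, metric, factor_a = "age_group",
                                factor_b = "region", alpha = 0.05,
                                control_level = NULL) {
  sub <- table[table$metric == metric & !is.na(table$value), , drop = FALSE]
  if (!nrow(sub)) stop("no observations for metric '", metric, "'")
  A <- droplevels(factor(sub[[factor_a]]))
  B <- droplevels(factor(sub[[factor_b]]))
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("both factors need at least 2 levels")
  cells <- table(A, B)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cells: ",
         paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  if (is.null(control_level)) control_level <- levels(A)[1]
  dat <- data.frame(value = sub$value, A = A, B = B)
  fit <- aov(value ~ A * B, data = dat)
  sm <- summary(fit)[[1]]
  rn <- trimws(rownames(sm))
  p_a <- sm[rn == "A", "Pr(>F)"]
  p_b <- sm[rn == "B", "Pr(>F)"]
  p_int <- sm[rn == "A:B", "Pr(>F)"]
  if (is.na(p_int))
    stop("interaction not estimable (no replication within cells)")

  main <- data.frame(
    comparison = c(paste0("main:", factor_a), paste0("main:", factor_b),
                   "interaction"),
    statistic = sm[match(c("A", "B", "A:B"), rn), "F value"],
    p_raw = c(p_a, p_b, p_int), p_adjusted = c(p_a, p_b, p_int),
    stringsAsFactors = FALSE)

  if (p_int < alpha) {
    trace <- sprintf(
      "interaction p=%.4g < alpha=%.3g: one-way ANOVA within each %s level",
      p_int, alpha, factor_b)
    cmp <- main
    for (lev in levels(B)) {
      di <- dat[dat$B == lev, , drop = FALSE]
      di$A <- droplevels(di$A)
      if (nlevels(di$A) < 2L) next
      f1 <- aov(value ~ A, data = di)
      p1 <- summary(f1)[[1]][1, "Pr(>F)"]
      cmp <- rbind(cmp, data.frame(
        comparison = sprintf("one-way %s | %s=%s", factor_a, factor_b, lev),
        statistic = summary(f1)[[1]][1, "F value"],
        p_raw = p1, p_adjusted = p1, stringsAsFactors = FALSE))
      dn <- dunnett_core(di$value, di$A, control_level)
      dn$comparison <- sprintf("%s | %s=%s", dn$comparison, factor_b, lev)
      cmp <- rbind(cmp, dn)
    }
    branch <- "one_way_fallback"
  } else {
    trace <- sprintf(
      "interaction p=%.4g >= alpha=%.3g: two-way main effects reported",
      p_int, alpha)
    cmp <- main
    branch <- "two_way"
  }
  rep <- new_test_report("anova_with_fallback", metric,
                         c(factor_a, factor_b),
                         statistic = main$statistic[3], df = NA_real_,
                         p = p_int, cmp, "none", trace)
  rep$branch <- branch
  rep$p_main <- c(setNames(p_a, factor_a), setNames(p_b, factor_b))
  rep
}

#' Multiple unpaired t-tests with Bonferroni correction
#'
#' Unpaired two-sided t-tests for a declared family of group pairs, with
#' Bonferroni adjustment over the family ("Bonferroni-Dunn" in common
#' statistical software).
#'
#' @param table a [sample_table()].
#' @param metric metric to test.
#' @param factor grouping factor column.
#' @param pairs 2-column matrix or list of length-2 vectors of factor levels;
#'   defaults to all pairs.
#' @param var_equal use the pooled-variance t statistic (classic unpaired
#'   Student test) rather than Welch.
#' @return A `test_report`.
#' @export
pairwise_t_bonferroni <- function(table, metric, factor = "age_group",
                                  pairs = NULL, var_equal = TRUE) {
  gr <- extract_groups(table, metric, factor)
  value <- gr$value; g <- gr$g
  if (is.null(pairs)) pairs <- utils::combn(levels(g), 2L)
  if (is.list(pairs)) pairs <- do.call(cbind, pairs)
  if (is.matrix(pairs) && ncol(pairs) == 2L && nrow(pairs) != 2L)
    pairs <- t(pairs)
  m <- ncol(pairs)
  res <- apply(pairs, 2L, function(pr) {
    x <- value[g == pr[1]]; y <- value[g == pr[2]]
    if (length(x) < 2L || length(y) < 2L)
      stop("pair ", pr[1], " vs ", pr[2], " has a group with < 2 values")
    if (stats::var(c(x, y)) == 0) return(c(0, 1))
    tt <- t.test(x, y, var.equal = var_equal)
    c(unname(tt$statistic), tt$p.value)
  })
  p_raw <- res[2, ]
  cmp <- data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                    statistic = res[1, ], p_raw = p_raw,
                    p_adjusted = pmin(1, p_raw * m),
                    stringsAsFactors = FALSE)
  new_test_report("pairwise_t_bonferroni", metric, factor,
                  statistic = max(abs(cmp$statistic)), df = NA_real_,
                  p = min(cmp$p_adjusted), cmp, "bonferroni",
                  trace = sprintf("%d declared pairs", m))
}
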