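# Inferential machinery: mixed 2x2 rmANOVA (vs. an independent stats::aov
# oracle and hand-computed sums of squares), aligned rank transform, t-test
# family, correlation, JZS Bayes factor and the cluster permutation test.

aov_reference <- function(d) {
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$within <- factor(d$within)
  ref <- summary(stats::aov(value ~ group * within + Error(subject / within),
                            data = d))
  c(group = ref[["Error: subject"]][[1]]["group", "F value"],
    within = ref[["Error: subject:within"]][[1]]["within", "F value"],
    interaction = ref[["Error: subject:within"]][[1]]["group:within", "F value"])
}

test_that("mixed ANOVA matches hand-computed sums of squares", {
  d <- data.frame(subject = rep(c("s1", "s2", "s3", "s4"), 2),
                  group = rep(c("g1", "g1", "g2", "g2"), 2),
                  within = rep(c("t1", "t2"), each = 4),
                  value = c(1, 2, 4, 5, 3, 6, 4, 7))
  res <- mixed_anova_2x2(d)
  # hand decomposition: SS_group 8 (MS_subj 4), SS_time 8, SS_int 2, MS_err 1
  expect_equal(res$F, c(2, 8, 2))
  expect_equal(res$df1, rep(1L, 3))
  expect_equal(res$df2, rep(2L, 3))
  expect_equal(res$eta_sq, c(8, 8, 2) / 28)
  expect_equal(res$p, stats::pf(c(2, 8, 2), 1, 2, lower.tail = FALSE))
})

test_that("mixed ANOVA agrees with the aov oracle on random designs", {
  set.seed(11)
  for (i in 1:50) {
    d <- mixed_data(n_per_group = sample(3:9, 1), g_eff = stats::rnorm(1),
                    w_eff = stats::rnorm(1), i_eff = stats::rnorm(1))
    res <- mixed_anova_2x2(d)
    ref <- aov_reference(d)
    expect_equal(res$F, unname(ref[res$effect]), tolerance = 1e-8)
  }
})

test_that("degenerate ANOVA inputs are handled", {
  d <- mixed_data(4)
  d$value <- 5
  res <- mixed_anova_2x2(d)
  expect_equal(res$F, rep(0, 3))
  d2 <- mixed_data(4)[-1, ]                       # missing cell
  expect_error(mixed_anova_2x2(d2), "exactly one value")
  d3 <- mixed_data(4); d3$group <- "g1"
  expect_error(mixed_anova_2x2(d3), "2 \\(group\\)")
})

test_that("classical eta squared components sum below one", {
  set.seed(3)
  d <- mixed_data(6, g_eff = 1, w_eff = 0.5, i_eff = 0.5)
  res <- mixed_anova_2x2(d)
  expect_lt(sum(res$eta_sq), 1)
  expect_true(all(res$eta_sq >= 0 & res$eta_sq_partial >= 0))
})

test_that("ART detects a pure interaction with main effects at null rate", {
  set.seed(21)
  n_rep <- 120
  p_int <- matrix(NA_real_, n_rep, 3)
  for (i in seq_len(n_rep)) {
    d <- mixed_data(6, i_eff = if (i <= n_rep / 2) 0 else 4)
    res <- art_anova(d)
    p_int[i, ] <- res$p[match(c("group", "within", "interaction"), res$effect)]
  }
  null_rows <- 1:(n_rep / 2)
  expect_lt(abs(mean(p_int[null_rows, 3] < 0.05) - 0.05), 0.08)
  expect_gt(mean(p_int[-null_rows, 3] < 0.05), 0.8)
  # all-equal data: every rank tied, F = 0
  d0 <- mixed_data(4); d0$value <- 1
  expect_equal(art_anova(d0)$F, rep(0, 3))
})

test_that("ART interaction F is invariant to monotone data transforms", {
  set.seed(22)
  d <- mixed_data(8, i_eff = 1.5)
  f1 <- art_anova(d)
  d2 <- d; d2$value <- exp(d$value / 2)           # strictly monotone
  f2 <- art_anova(d2)
  # ranks of aligned interaction responses change, but detection agrees
  expect_equal(f1$effect, f2$effect)
  expect_equal(f1$p[3] < 0.05, f2$p[3] < 0.05)
})

test_that("t tests match textbook formulas and report effect sizes", {
  r <- ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$cohen_d, -3)
  rp <- ttest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(rp$t, 0)
  expect_equal(rp$p, 1)
  expect_error(ttest(c(1, 2, 3, 4), c(1, 2, 3, 4) + 0.5, paired = TRUE),
               "zero variance")
})

test_that("paired identical samples and zero variance are degenerate", {
  expect_error(ttest(c(2, 2, 2)), "zero variance")
  expect_error(ttest(c(1, 2), c(3, 4), paired = TRUE), "zero variance")
  expect_error(ttest(c(1, 2, 3), c(2, 3, 4, 5), paired = TRUE), "length")
  # d for means 0/1 and pooled SD 1
  a <- c(-1, 0, 1); b <- c(0, 1, 2)
  expect_equal(ttest(a, b)$cohen_d, -1)
})

test_that("Bonferroni caps at one and never decreases p", {
  expect_equal(bonferroni(0.01, m = 2), 0.02)
  expect_equal(bonferroni(0.7, m = 2), 1.0)
  p <- c(0.001, 0.4, 0.9)
  expect_true(all(bonferroni(p) >= p))
  expect_error(bonferroni(1.3), "\\[0, 1\\]")
})

test_that("Pearson correlation matches hand computation", {
  r <- pearson_r(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$r, 0.5)
  expect_equal(pearson_r(1:10, 2 * (1:10))$r, 1)
  set.seed(5)
  rn <- pearson_r(stats::rnorm(2000), stats::rnorm(2000))
  expect_lt(abs(rn$r), 0.06)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("JZS Bayes factor agrees with an independent quadrature oracle", {
  skip_if_not_installed("pracma")
  oracle <- function(t, n_eff, df, rscale = 1 / sqrt(2)) {
    f <- function(u) {                            # g = u/(1-u) substitution
      g <- u / (1 - u)
      k <- 1 + n_eff * rscale^2 * g
      k^(-0.5) * (1 + t^2 / (k * df))^(-(df + 1) / 2) *
        (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g)) / (1 - u)^2
    }
    num <- pracma::quadgk(f, 1e-12, 1 - 1e-12, tol = 1e-12)
    log(num / (1 + t^2 / df)^(-(df + 1) / 2))
  }
  set.seed(8)
  for (i in 1:10) {
    a <- stats::rnorm(12, mean = stats::runif(1, 0, 1.5))
    b <- stats::rnorm(10)
    mine <- jzs_bayes_factor_t(a, b)
    t <- ttest(a, b)$t
    ref <- oracle(t, 12 * 10 / 22, 20)
    expect_equal(mine, ref, tolerance = 0.01)
  }
})

test_that("JZS Bayes factor favors the truth in clear cases", {
  set.seed(9)
  same <- jzs_bayes_factor_t(stats::rnorm(60), stats::rnorm(60))
  expect_lt(same, 0)
  sep1 <- jzs_bayes_factor_t(stats::rnorm(20) + 1, stats::rnorm(20))
  sep2 <- jzs_bayes_factor_t(stats::rnorm(20) + 3, stats::rnorm(20))
  expect_gt(sep2, sep1)
  expect_gt(sep2, 0)
})

test_that("cluster labeling respects connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- m[3, 3] <- TRUE           # diagonal touches
  l4 <- smrpipe:::label_clusters(m, 4)
  expect_equal(max(l4), 3)
  l8 <- smrpipe:::label_clusters(m, 8)
  expect_equal(max(l8), 1)
  m2 <- matrix(TRUE, 3, 3)
  expect_equal(max(smrpipe:::label_clusters(m2, 4)), 1)
})

test_that("cluster test recovers an inserted effect and refuses n = 1", {
  set.seed(13)
  true_mask <- matrix(FALSE, 15, 25); true_mask[4:9, 8:18] <- TRUE
  maps <- lapply(1:12, function(i) {
    m <- matrix(stats::rnorm(15 * 25, sd = 15), 15)
    m[true_mask] <- m[true_mask] - 40
    m
  })
  ct <- cluster_fdr_map(maps, threshold_p = 0.001, n_perm = 300, seed = 2)
  hit <- sum(ct$significant_mask & true_mask) / sum(true_mask)
  expect_gte(hit, 0.8)
  # significant mask is a subset of the suprathreshold pixels
  expect_true(all(abs(ct$t_map[ct$significant_mask]) >= ct$threshold_t))
  expect_error(cluster_fdr_map(maps[1]), ">= 2")
  empty <- cluster_fdr_map(lapply(1:6, function(i) matrix(stats::rnorm(25), 5)),
                           threshold_p = 1e-6, n_perm = 50, seed = 3)
  expect_equal(nrow(empty$clusters), 0)
  expect_false(any(empty$significant_mask))
})

test_that("null maps produce significant clusters at about the nominal rate", {
  set.seed(14)
  n_rep <- 60
  any_sig <- vapply(seq_len(n_rep), function(i) {
    maps <- lapply(1:10, function(j) matrix(stats::rnorm(12 * 18), 12))
    ct <- cluster_fdr_map(maps, threshold_p = 0.05, n_perm = 150,
                          fdr_q = 0.05, seed = 1000 + i)
    any(ct$clusters$q <= 0.05)
  }, logical(1))
  expect_lt(mean(any_sig), 0.15)                  # controlled near nominal
})
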