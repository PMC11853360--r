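test_that("paired t matches the textbook formula and handles degenerate input", {
  # alternating differences cancel: t = 0, p = 1
  r0 <- paired_t(c(2, 1, 2, 1), c(1, 2, 1, 2))
  expect_equal(r0$mean_diff, 0)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # hand-computed: d = (0.1, 0.3, 0.2), t = dbar / (s_d / sqrt(3))
  d <- c(0.1, 0.3, 0.2)
  r <- paired_t(d, rep(0, 3))
  expect_equal(r$mean_diff, 0.2)
  expect_equal(r$t, 0.2 / (sd(d) / sqrt(3)))
  expect_equal(r$df, 2)
  # a unit location shift plus zero-mean noise recovers the shift
  withr::with_seed(5, {
    y <- rnorm(200)
    r1 <- paired_t(y + 1 + rnorm(200, sd = 0.3), y)
    expect_equal(r1$mean_diff, 1, tolerance = 0.1)
    expect_lt(r1$p, 1e-10)
  })
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "Zero-variance")
})

test_that("correlations match hand-evaluated coefficients and invariances", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r <- method_correlation(x, y, "pearson")
  expect_equal(r$r, 3 / sqrt(2 * 14 / 3)) # hand covariance formula
  expect_equal(r$r_squared, r$r^2)
  expect_equal(method_correlation(x, 2 * x, "pearson")$r, 1)
  expect_equal(method_correlation(x, 2 * x, "pearson")$r_squared, 1)
  # Spearman flips sign under a strictly decreasing transform
  withr::with_seed(8, {
    a <- runif(30)
    expect_equal(method_correlation(a, exp(-a), "spearman")$r, -1)
    # Pearson is invariant under affine maps, Spearman under monotone maps
    b <- rnorm(30)
    expect_equal(method_correlation(a, b, "pearson")$r,
                 method_correlation(5 * a - 2, 0.1 * b + 7, "pearson")$r)
    expect_equal(method_correlation(a, b, "spearman")$r,
                 method_correlation(a^3, exp(b), "spearman")$r)
  })
  expect_error(method_correlation(c(1, 1, 1), c(1, 2, 3)), "Zero variance")
})

test_that("Bland-Altman bias, SD and limits satisfy their identities", {
  b0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(b0$bias, 0); expect_equal(b0$sd, 0)
  expect_equal(c(b0$lower, b0$upper), c(0, 0))
  b1 <- bland_altman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(b1$bias, 1)
  expect_equal(c(b1$lower, b1$upper), c(1, 1))
  withr::with_seed(12, {
    for (i in 1:10) {
      a <- rnorm(25); b <- rnorm(25)
      ba <- bland_altman(a, b)
      expect_equal(ba$upper - ba$lower, 2 * 1.96 * ba$sd)
      expect_equal(ba$lower, 2 * ba$bias - ba$upper)
      expect_equal(ba$bias, mean(a - b))
    }
  })
  expect_error(bland_altman(1:3, 1:4), "equal length")
  g <- glance(bland_altman(c(1, 2), c(0, 1)))
  expect_equal(g$bias, 1)
  expect_equal(g$n, 2L)
})

test_that("the normality gate follows Shapiro-Wilk and variance homogeneity", {
  withr::with_seed(100, {
    # with two Shapiro tests and one F test each gated at alpha = 0.05,
    # clean normal data passes all three about 0.95^3 ~ 86% of the time
    picks <- replicate(150, {
      g <- list(a = rnorm(40), b = rnorm(40))
      normality_gate(g)$choice
    })
    expect_gte(mean(picks == "anova"), 0.75)
    picks_skew <- replicate(60, {
      g <- list(a = rnorm(40), b = exp(rnorm(40) * 1.5))
      normality_gate(g)$choice
    })
    expect_gte(mean(picks_skew == "kruskal"), 0.9)
    # location shifts never change the gate decision
    g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    g_shift <- lapply(seq_along(g), function(i) g[[i]] + 10 * i)
    expect_identical(normality_gate(g)$choice, normality_gate(g_shift)$choice)
  })
  expect_error(normality_gate(list(a = 1:2, b = 1:10)), "at least 3")
  # Levene alternative runs and returns gate evidence
  withr::with_seed(3, {
    gl <- normality_gate(list(a = rnorm(20), b = rnorm(20)), var_method = "levene")
    expect_true(gl$variance$method == "levene")
    expect_true(is.finite(gl$variance$p))
  })
})

test_that("Kruskal-Wallis H matches the hand formula, with and without ties", {
  # hand: groups {1,2} and {3,4}: H = 12/(4*5) * (2*1.5^2 + 2*3.5^2) - 3*5 = 2.4
  expect_equal(kruskal_wallis(list(c(1, 2), c(3, 4)))$H, 2.4)
  # independent oracle coded from the tie-corrected definition
  hand_H <- function(groups) {
    v <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
    N <- length(v); r <- rank(v)
    H <- 12 / (N * (N + 1)) * sum(tapply(r, g, function(x) length(x) * mean(x)^2)) -
      3 * (N + 1)
    tie <- table(v)
    H / (1 - sum(tie^3 - tie) / (N^3 - N))
  }
  withr::with_seed(21, {
    for (i in 1:5) {
      groups <- list(sample(1:6, 5, TRUE), sample(1:6, 6, TRUE), sample(1:6, 4, TRUE))
      expect_equal(kruskal_wallis(groups)$H, hand_H(groups))
    }
  })
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("Kruskal-Wallis agrees with its own statistic under label permutation", {
  # permuting group labels of fixed data must reproduce the oracle H each time
  hand_H <- function(v, g) {
    N <- length(v); r <- rank(v)
    H <- 12 / (N * (N + 1)) * sum(tapply(r, g, function(x) length(x) * mean(x)^2)) -
      3 * (N + 1)
    tie <- table(v)
    H / (1 - sum(tie^3 - tie) / (N^3 - N))
  }
  v <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  perms <- combn(6, 2)
  for (c in seq_len(ncol(perms))) {
    g <- rep(2L, 6); g[perms[, c]] <- 1L
    ours <- kruskal_wallis(split(v, g))$H
    expect_equal(ours, hand_H(v, g))
  }
})

test_that("Dunn z statistics match the hand formula and Bonferroni doctrine", {
  # two identical groups: z = 0, p = 1
  d0 <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)
  # hand: {1,2},{3,4},{5,6}: mean ranks 1.5, 3.5, 5.5; sigma2 = 6*7/12 = 3.5
  d <- dunn_posthoc(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(nrow(d), 3L)
  z13 <- (1.5 - 5.5) / sqrt(3.5 * (1 / 2 + 1 / 2))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], z13)
  expect_equal(d$p_adj, pmin(1, d$p * 3))
  expect_true(all(d$p_adj >= d$p))
  # unadjusted option
  dn <- dunn_posthoc(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)), adjust = "none")
  expect_equal(dn$p_adj, dn$p)
})

test_that("one-way ANOVA matches hand computation and the two-group t identity", {
  # {1,2} vs {5,6}: MSB/MSW = 16 / 0.5 = 32
  a <- one_way_anova(list(c(1, 2), c(5, 6)))
  expect_equal(a$F, 32)
  withr::with_seed(30, {
    x <- rnorm(12); y <- rnorm(15) + 0.5
    f <- one_way_anova(list(x, y))
    t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
    expect_equal(f$F, unname(t2))
    # equal-mean groups give a large p
    z1 <- rnorm(50); z2 <- rnorm(50)
    expect_gt(one_way_anova(list(z1, z2 - mean(z2) + mean(z1)))$p, 0.2)
  })
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "Zero within-group")
})

test_that("significance stars follow the alpha = 0.05 convention", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009)), c("ns", "*", "**", "***"))
})

test_that("compare_groups wires the gate, omnibus and post-hoc together", {
  withr::with_seed(44, {
    df <- tibble::tibble(
      value = c(rnorm(10), rnorm(10) + 0.2, exp(rnorm(10))),
      grp = rep(c("a", "b", "c"), each = 10)
    )
    gt <- compare_groups(df, value, grp)
    expect_s3_class(gt, "group_test")
    expect_true(gt$test %in% c("anova", "kruskal-wallis"))
    expect_equal(nrow(gt$pairwise), 3L)
    expect_equal(nrow(gt$gate$shapiro), 3L)
    g <- glance(gt)
    expect_equal(g$n, 30L)
    expect_identical(tidy(gt), gt$pairwise)
  })
})
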