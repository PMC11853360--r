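#' Paired t-test on matched values
#'
#' Classical two-sided paired t on `d = x - y` with `n - 1` degrees of
#' freedom, as used for left-versus-right symmetry testing.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return one-row tibble: `mean_diff`, `t`, `df`, `p`, `n`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (stats::sd(d) == 0) {
    abort("Zero-variance differences: paired t-test is degenerate.")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    mean_diff = unname(ht$estimate), t = unname(ht$statistic),
    df = unname(ht$parameter), p = ht$p.value, n = length(x)
  )
}

#' Correlation between two quantification methods
#'
#' Pearson correlation on values or Spearman on ranks (average ranks for
#' ties), with the squared coefficient reported alongside.
#'
#' @param x,y numeric vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return one-row tibble: `method`, `r`, `r_squared`, `p`, `n`.
#' @export
method_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance in one of the inputs: correlation undefined.")
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ht$estimate)
  tibble::tibble(method = method, r = r, r_squared = r^2, p = ht$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` (oriented fixed minus hotspot in the pipeline)
#' against pair means. Bias is the mean difference; the 95% limits of
#' agreement are `bias +/- 1.96 * SD(d)`, so `upper - lower = 3.92 * SD`
#' and `lower = 2 * bias - upper` always hold.
#'
#' @param a,b matched numeric vectors (n >= 2).
#' @return a `bland_altman` object: list with `bias`, `sd`, `lower`,
#'   `upper`, `n`, and `data` (tibble of pair means and differences).
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(1.1, 2.3, 2.9))
#' glance(ba)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must be matched pairs of equal length.")
  stopifnot(length(a) >= 2L)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      bias = bias, sd = s,
      lower = bias - 1.96 * s, upper = bias + 1.96 * s, n = length(d),
      data = tibble::tibble(mean = (a + b) / 2, diff = d)
    ),
    class = "bland_altman"
  )
}

#' Limits of agreement from bias and SD
#'
#' The symmetric-limits construction `bias +/- 1.96 * SD`. Useful for
#' reconstructing a missing limit from a reported bias and one limit, via
#' `sd = (upper - bias) / 1.96`.
#'
#' @param bias mean difference.
#' @param sd standard deviation of the differences.
#' @return named numeric: `lower`, `upper`.
#' @examples
#' # reconstruct a lower limit from bias -0.147 and upper limit 0.117
#' loa_limits(-0.147, sd = (0.117 - (-0.147)) / 1.96)["lower"]
#' @export
loa_limits <- function(bias, sd) {
  c(lower = bias - 1.96 * sd, upper = bias + 1.96 * sd)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d bias=%.4f SD=%.4f LoA=[%.4f, %.4f]\n",
              x$n, x$bias, x$sd, x$lower, x$upper))
  invisible(x)
}

#' Choose between ANOVA and Kruskal-Wallis
#'
#' The parametric gate used before group comparison: one-way ANOVA is
#' selected only when every group passes Shapiro-Wilk normality (p >= alpha)
#' and variance homogeneity holds (p >= alpha); otherwise Kruskal-Wallis.
#' Homogeneity uses the classical two-group variance-ratio F test, extended
#' to more groups by testing the pair with the largest variance ratio;
#' Levene's test (via the car package) is available as an alternative.
#'
#' @param groups named list of numeric vectors, each n >= 3.
#' @param alpha gate significance level. Default 0.05.
#' @param var_method `"fmax"` (variance-ratio F on the extreme pair) or
#'   `"levene"`.
#' @return list with `choice` (`"anova"` or `"kruskal"`), `shapiro`
#'   (tibble of per-group p-values), and `variance` (tibble: method,
#'   statistic, p).
#' @export
normality_gate <- function(groups, alpha = 0.05, var_method = c("fmax", "levene")) {
  var_method <- match.arg(var_method)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 3L)) {
    abort("Every group needs at least 3 observations for the normality gate.")
  }
  nm <- names(groups) %||% as.character(seq_along(groups))
  sw <- tibble::tibble(
    group = nm,
    n = vapply(groups, length, 1L),
    shapiro_p = vapply(groups, function(g) stats::shapiro.test(g)$p.value, 1.0)
  )
  if (var_method == "fmax") {
    v <- vapply(groups, stats::var, 1.0)
    hi <- which.max(v); lo <- which.min(v)
    if (hi == lo) {
      vt <- tibble::tibble(method = "fmax", statistic = 1, p = 1)
    } else {
      ft <- stats::var.test(groups[[hi]], groups[[lo]])
      vt <- tibble::tibble(method = "fmax", statistic = unname(ft$statistic), p = ft$p.value)
    }
  } else {
    if (!requireNamespace("car", quietly = TRUE)) {
      abort("var_method = \"levene\" requires the car package.")
    }
    df <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(nm, vapply(groups, length, 1L)))
    )
    lt <- car::leveneTest(value ~ group, data = df)
    vt <- tibble::tibble(method = "levene", statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"])
  }
  choice <- if (all(sw$shapiro_p >= alpha) && vt$p >= alpha) "anova" else "kruskal"
  list(choice = choice, shapiro = sw, variance = vt)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `length(groups) - 1` degrees of freedom (delegates to
#' [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 4).
#' @return one-row tibble: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L, sum(lengths(groups)) >= 4L)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    abort("All values identical: Kruskal-Wallis H undefined.")
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(vals, g)
  tibble::tibble(H = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis omnibus:
#' `z_ij = (rbar_i - rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` with
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`. Raw p-values are two-sided
#' normal; the default adjustment is Bonferroni
#' (`p_adj = min(1, p * n_comparisons)`).
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return tibble: `group1`, `group2`, `z`, `p`, `p_adj`, `stars`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2L)
  nm <- names(groups) %||% as.character(seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  rk <- rank(vals)
  gi <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(rk, gi, mean)
  tie_tab <- table(vals)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  sig2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(groups), 2L)
  m <- ncol(pairs)
  out <- vector("list", m)
  for (c in seq_len(m)) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    se <- sqrt(sig2 * (1 / lengths(groups)[[i]] + 1 / lengths(groups)[[j]]))
    z <- if (se == 0) 0 else unname((rbar[[i]] - rbar[[j]]) / se)
    p <- 2 * stats::pnorm(-abs(z))
    out[[c]] <- tibble::tibble(group1 = nm[i], group2 = nm[j], z = z, p = p)
  }
  out <- dplyr::bind_rows(out)
  out$p_adj <- if (adjust == "bonferroni") pmin(1, out$p * m) else out$p
  out$stars <- p_stars(out$p_adj)
  out
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F ratio (equal variances assumed),
#' via [stats::oneway.test()].
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return one-row tibble: `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L, all(lengths(groups) >= 2L))
  if (all(vapply(groups, stats::var, 1.0) == 0)) {
    abort("Zero within-group variance everywhere: F undefined.")
  }
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  tibble::tibble(
    F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
    df2 = unname(ht$parameter[2]), p = ht$p.value
  )
}

#' Significance stars
#'
#' The conventional annotation: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star annotations (`"ns"` when p >= 0.05).
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Gated group comparison with post-hoc tests
#'
#' Runs the full comparison battery on a tidy table: the
#' [normality_gate()] picks ANOVA or Kruskal-Wallis, the chosen omnibus is
#' computed, and Dunn's pairwise post-hoc comparisons are attached.
#'
#' @param data data frame with one row per subject.
#' @param value,group columns (tidy-eval) holding the measurement and the
#'   group label.
#' @param alpha gate level.
#' @param adjust Dunn adjustment, `"bonferroni"` or `"none"`.
#' @return a `group_test` object; see [tidy.group_test()] and
#'   [glance.group_test()].
#' @export
compare_groups <- function(data, value, group, alpha = 0.05,
                           adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  groups <- split(v[keep], as.character(g[keep]))
  gate <- normality_gate(groups, alpha = alpha)
  omnibus <- if (gate$choice == "anova") {
    dplyr::rename(one_way_anova(groups), statistic = "F")
  } else {
    dplyr::rename(kruskal_wallis(groups), statistic = "H")
  }
  structure(
    list(
      test = if (gate$choice == "anova") "anova" else "kruskal-wallis",
      statistic = omnibus$statistic[1], p = omnibus$p[1],
      omnibus = omnibus, gate = gate,
      pairwise = dunn_posthoc(groups, adjust = adjust),
      groups = groups, alpha = alpha
    ),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: statistic=%.3f p=%.4g %s\n",
              x$test, x$statistic, x$p, p_stars(x$p)))
  print(x$pairwise, ...)
  invisible(x)
}
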