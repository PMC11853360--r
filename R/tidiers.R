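#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Bland-Altman result
#'
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @return the per-pair tibble of means and differences.
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' One-row summary of a Bland-Altman result
#'
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @return tibble: `bias`, `sd`, `loa_lower`, `loa_upper`, `n`.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd = x$sd, loa_lower = x$lower,
                 loa_upper = x$upper, n = x$n)
}

#' Tidy a gated group comparison
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return the pairwise Dunn tibble (`group1`, `group2`, `z`, `p`, `p_adj`,
#'   `stars`).
#' @export
tidy.group_test <- function(x, ...) x$pairwise

#' One-row summary of a gated group comparison
#'
#' @param x a [compare_groups()] result.
#' @param ... unused.
#' @return tibble: `test`, `statistic`, `p`, `stars`, `n_groups`, `n`.
#' @export
glance.group_test <- function(x, ...) {
  tibble::tibble(
    test = x$test, statistic = x$statistic, p = x$p, stars = p_stars(x$p),
    n_groups = length(x$groups), n = sum(lengths(x$groups))
  )
}

#' Tidy a method comparison
#'
#' @param x a [compare_methods()] result.
#' @param ... unused.
#' @return the per-muscle (plus pooled) summary tibble.
#' @export
tidy.method_comparison <- function(x, ...) x$summary
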