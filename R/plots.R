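#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_jitter
#'   geom_boxplot labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Differences against pair means with the bias and 95% limits of
#' agreement drawn as horizontal lines.
#'
#' @param object a [bland_altman()] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot(object$data, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = object$bias, linetype = "solid", colour = "#2c7fb8") +
    geom_hline(yintercept = c(object$lower, object$upper),
               linetype = "dashed", colour = "#de2d26") +
    labs(
      x = "Mean of methods", y = "Difference (fixed - hotspot)",
      title = sprintf("Bias %.3f, LoA [%.3f, %.3f]",
                      object$bias, object$lower, object$upper)
    ) +
    theme_minimal()
}

#' Group comparison plot
#'
#' Box-and-jitter plot of the per-group values with the omnibus result in
#' the title.
#'
#' @param object a [compare_groups()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.group_test <- function(object, ...) {
  df <- tibble::tibble(
    group = rep(names(object$groups), lengths(object$groups)),
    value = unlist(object$groups, use.names = FALSE)
  )
  df$group <- factor(df$group, levels = names(object$groups))
  ggplot(df, aes(x = .data$group, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.15, alpha = 0.7) +
    labs(
      x = NULL, y = "SUVpeak",
      title = sprintf("%s: statistic = %.2f, p = %.3g %s",
                      object$test, object$statistic, object$p, p_stars(object$p))
    ) +
    theme_minimal()
}

#' Method agreement scatter plot
#'
#' Fixed-VOI against hotspot-VOI values for one muscle (or pooled), with
#' the identity line.
#'
#' @param averaged tibble from [average_lr()].
#' @param muscle muscle to plot, or `"pooled"` for all rows.
#' @param value column (tidy-eval) holding the quantity; default `suv_peak`.
#' @return a ggplot.
#' @export
plot_method_agreement <- function(averaged, muscle = "pooled", value = suv_peak) {
  qv <- rlang::enquo(value)
  d <- averaged
  if (!identical(muscle, "pooled")) d <- dplyr::filter(d, .data$muscle == !!muscle)
  wide <- d |>
    dplyr::select("scan_id", "muscle", "method", value = !!qv) |>
    tidyr::pivot_wider(names_from = "method", values_from = "value")
  ggplot(wide, aes(x = .data$hotspot, y = .data$fixed)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "Hotspot VOI SUVpeak", y = "Fixed VOI SUVpeak",
         title = sprintf("Method agreement (%s)", muscle)) +
    theme_minimal()
}
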