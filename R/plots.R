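#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_errorbar geom_hline facet_wrap labs scale_fill_viridis_c
#'   stat_summary theme_minimal
NULL

#' Plot a parameter map slice
#'
#' @param object a `param_maps` object.
#' @param measure `"MK"`, `"MD"` or `"FA"`.
#' @param slice axial (z) slice index; defaults to the middle slice.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.param_maps <- function(object, measure = c("MK", "MD", "FA"),
                                slice = NULL, ...) {
  measure <- match.arg(measure)
  m <- switch(measure, MD = object$md, FA = object$fa, MK = object$mk)
  slice <- slice %||% ceiling(dim(m)[3L] / 2)
  df <- tidyr::expand_grid(x = seq_len(dim(m)[1L]), y = seq_len(dim(m)[2L]))
  df$value <- m[cbind(df$x, df$y, slice)]
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey20") +
    labs(title = sprintf("%s map, slice %d", measure, slice), fill = measure) +
    theme_minimal()
}

#' Plot group-by-time trajectories of a longitudinal table
#'
#' Group means with standard-error bars over the ordered time points, one
#' facet per measure (the usual trajectory figure for longitudinal ROI
#' summaries).
#'
#' @param table longitudinal tibble.
#' @param value_col `"value"` or `"normalized_value"`.
#' @return a ggplot.
#' @export
plot_longitudinal <- function(table, value_col = "value") {
  check_longitudinal(table)
  ggplot(table, aes(x = .data$time, y = .data[[value_col]],
                    colour = .data$group, group = .data$group)) +
    stat_summary(fun = mean, geom = "line") +
    stat_summary(fun = mean, geom = "point") +
    stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar", width = 0.15) +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = NULL, y = value_col) +
    theme_minimal()
}

#' Plot a post-hoc comparison series
#'
#' @param object a [fisher_lsd()] tibble.
#' @param ... unused.
#' @return a ggplot of per-time group differences with significance marks.
#' @export
autoplot.fisher_lsd <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$time <- factor(df$time, levels = df$time)
  ggplot(df, aes(x = .data$time, y = .data$estimate)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbar(aes(ymin = .data$estimate - .data$se,
                      ymax = .data$estimate + .data$se), width = 0.15) +
    geom_point(aes(colour = .data$significant), size = 2.5) +
    labs(x = NULL, y = "group mean difference",
         colour = sprintf("p < %.2g", attr(object, "alpha") %||% 0.05)) +
    theme_minimal()
}
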