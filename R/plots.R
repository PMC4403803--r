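#' Box-and-whisker comparison of plot-level variables by vegetation type
#'
#' Richness, PD, percentage alien, density and Mantel r side by side for
#' forest and grassland plots.
#'
#' @param summaries A [plot_summaries()] tibble.
#' @param variables Summary columns to show.
#' @return A ggplot.
#' @export
plot_vegetation_comparison <- function(summaries,
                                       variables = c("richness", "pd", "pct_alien",
                                                     "density", "mantel_r")) {
  variables <- intersect(variables, names(summaries))
  long <- tidyr::pivot_longer(
    dplyr::select(summaries, dplyr::all_of(c("plot_id", "vegetation", variables))),
    cols = dplyr::all_of(variables), names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$vegetation, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Mantel r against plot-level covariates
#'
#' One panel per covariate, vegetation types distinguished by shape, with
#' a dashed reference line at the largest r still significant at `alpha`
#' (points above it are plots whose Mantel test rejected).
#'
#' @param summaries A [plot_summaries()] tibble with Mantel columns.
#' @param covariates Covariate columns for the x axes.
#' @param alpha Significance level for the reference line.
#' @return A ggplot.
#' @export
plot_mantel_covariates <- function(summaries,
                                   covariates = c("richness", "pd", "density",
                                                  "log_pct_alien"),
                                   alpha = 0.05) {
  covariates <- intersect(covariates, names(summaries))
  dat <- summaries[!is.na(summaries$mantel_r), , drop = FALSE]
  long <- tidyr::pivot_longer(
    dplyr::select(dat, dplyr::all_of(c("plot_id", "vegetation", "mantel_r",
                                       "mantel_significant", covariates))),
    cols = dplyr::all_of(covariates), names_to = "covariate", values_to = "value")
  r_cut <- suppressWarnings(max(dat$mantel_r[!dat$mantel_significant], na.rm = TRUE))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$mantel_r,
                                          shape = .data$vegetation)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Mantel r", shape = "Vegetation")
  if (is.finite(r_cut)) {
    p <- p + ggplot2::geom_hline(yintercept = r_cut, linetype = "dashed")
  }
  p
}

#' PD null results at a glance
#'
#' Observed PD against richness with the null expectation, coloured by
#' classification.
#'
#' @param pd_null Output of [pd_null_tests()] (one configuration).
#' @return A ggplot.
#' @export
plot_pd_null <- function(pd_null) {
  ggplot2::ggplot(pd_null, ggplot2::aes(x = .data$richness, y = .data$observed_pd,
                                        colour = .data$classification,
                                        shape = .data$vegetation)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean, group = 1),
                       colour = "grey40", linetype = "dotted") +
    ggplot2::labs(x = "Species richness", y = "Faith's PD (Ma)",
                  colour = "Classification", shape = "Vegetation")
}
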