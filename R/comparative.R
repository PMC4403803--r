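#' Log transform for percentage-alien covariates
#'
#' `ln(pct + offset)` with a default offset of 1, so plots without alien
#' plants map to 0 and the transform is defined on the whole 0-100 range.
#'
#' @param pct Percentage in \[0, 100\].
#' @param offset Added before the log (default 1).
#' @return Transformed value(s).
#' @export
log_pct_alien <- function(pct, offset = 1) {
  if (any(pct < 0, na.rm = TRUE)) {
    abort("Percentages must be non-negative.", class = "phylospace_domain_error")
  }
  log(pct + offset)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: the ratio of between-group to
#' within-group mean squares referred to the F distribution.
#'
#' @param values Numeric response, one element per plot.
#' @param groups Group labels (e.g. vegetation types).
#' @return One-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    abort("Need at least two groups with at least two observations each.",
          class = "phylospace_parameter_error")
  }
  fit <- stats::lm(values ~ groups)
  # suppress the "essentially perfect fit" chatter; the degenerate case is
  # detected and reported as an error right below
  tab <- suppressWarnings(stats::anova(fit))
  # guard float residue: treat within-group variance as zero relative to scale
  if (tab["Residuals", "Mean Sq"] <= 1e-12 * max(stats::var(values), .Machine$double.xmin)) {
    abort("Zero within-group variance; F is undefined.",
          class = "phylospace_degenerate_matrix")
  }
  tibble(
    statistic = tab[1, "F value"],
    df_between = tab[1, "Df"],
    df_within = tab["Residuals", "Df"],
    p_value = tab[1, "Pr(>F)"]
  )
}

#' Per-plot summary table
#'
#' Assembles the plot-level table feeding the comparative stage: richness,
#' Faith's PD, stem density, percentage (and log-percentage) of alien
#' individuals, and — when supplied — each plot's Mantel statistics and PD
#' null classification.
#'
#' @param stem_map A `stem_map` tibble.
#' @param tree Tree from [read_ultrametric_tree()].
#' @param mantel Optional output of [mantel_tests()].
#' @param pd_null Optional output of [pd_null_tests()] (or the `full`
#'   configuration of [run_pd_suite()]).
#' @return Tibble of class `plot_summary`, one row per plot.
#' @export
plot_summaries <- function(stem_map, tree, mantel = NULL, pd_null = NULL) {
  base <- stem_map |>
    dplyr::group_by(.data$plot_id, .data$vegetation) |>
    dplyr::summarise(richness = dplyr::n_distinct(.data$species), .groups = "drop")
  pd_vals <- stem_map |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(pd = faith_pd(tree, unique(.data$species)), .groups = "drop")
  out <- base |>
    dplyr::left_join(pd_vals, by = "plot_id") |>
    dplyr::left_join(plant_density(stem_map), by = "plot_id") |>
    dplyr::left_join(
      dplyr::select(percent_alien(stem_map), dplyr::all_of(c("plot_id", "pct_alien"))),
      by = "plot_id") |>
    dplyr::mutate(log_pct_alien = log_pct_alien(.data$pct_alien))
  if (!is.null(mantel)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(mantel, dplyr::all_of(c("plot_id", "r", "p_value", "significant"))) |>
        dplyr::rename(mantel_r = "r", mantel_p = "p_value",
                      mantel_significant = "significant"),
      by = "plot_id")
  }
  if (!is.null(pd_null)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(pd_null, dplyr::all_of(c("plot_id", "ses", "classification"))) |>
        dplyr::rename(pd_ses = "ses", pd_classification = "classification"),
      by = "plot_id")
  }
  class(out) <- c("plot_summary", class(out))
  out
}

#' Vegetation-type ANOVAs over plot-level variables
#'
#' One-way ANOVA between vegetation types for each plot-level response
#' present in the summary table (richness, PD, density, percentage alien,
#' and Mantel r when available).
#'
#' @param summaries A [plot_summaries()] tibble.
#' @param responses Character vector of summary columns to test.
#' @return Tibble with one row per response.
#' @export
vegetation_anovas <- function(summaries,
                              responses = c("richness", "pd", "density",
                                            "pct_alien", "mantel_r")) {
  responses <- intersect(responses, names(summaries))
  skip_with_warning <- function(v) function(e) {
    warn(sprintf("ANOVA for %s skipped: %s", v, conditionMessage(e)))
    tibble(statistic = NA_real_, df_between = NA_integer_,
           df_within = NA_integer_, p_value = NA_real_)
  }
  purrr::map_dfr(responses, function(v) {
    res <- tryCatch(
      anova_oneway(summaries[[v]], summaries$vegetation),
      phylospace_parameter_error = skip_with_warning(v),
      phylospace_degenerate_matrix = skip_with_warning(v))
    dplyr::mutate(res, response = v, .before = 1)
  })
}

#' Gaussian GLMs for Mantel r against plot-level covariates
#'
#' Fits one Gaussian (identity-link) generalized linear model per
#' covariate: `mantel_r ~ vegetation * covariate`, i.e. intercept,
#' vegetation main effect, covariate main effect, and their interaction —
#' four models over the default covariates (richness, PD, density,
#' log-percentage alien), hence twelve non-intercept coefficient p-values
#' in total. With identity link and Gaussian errors these are ordinary
#' least-squares fits with classical standard errors. A single model with
#' all covariates at once is available via `full_model = TRUE`, though
#' twenty plots rarely support it.
#'
#' @param summaries A [plot_summaries()] tibble including `mantel_r`.
#' @param covariates Covariate columns (default the four above).
#' @param full_model Also fit `mantel_r ~ vegetation * (all covariates)`.
#' @return Object of class `mantel_glms`: a named list of `glm` fits.
#'   Use [tidy.mantel_glms()] / [glance.mantel_glms()] for tables.
#' @export
fit_mantel_glms <- function(summaries,
                            covariates = c("richness", "pd", "density",
                                           "log_pct_alien"),
                            full_model = FALSE) {
  dat <- summaries[!is.na(summaries$mantel_r), , drop = FALSE]
  if (nrow(dat) < 6) {
    abort("Need at least 6 plots with a defined Mantel r.",
          class = "phylospace_parameter_error")
  }
  missing_cov <- setdiff(covariates, names(dat))
  if (length(missing_cov)) {
    abort(sprintf("Covariate(s) not in summaries: %s",
                  paste(missing_cov, collapse = ", ")),
          class = "phylospace_schema_error")
  }
  dat$vegetation <- factor(dat$vegetation)
  fits <- lapply(covariates, function(cv) {
    f <- stats::reformulate(sprintf("vegetation * %s", cv), response = "mantel_r")
    fit <- stats::glm(f, data = dat, family = stats::gaussian())
    if (any(is.na(stats::coef(fit)))) {
      abort(sprintf("Singular fit for model mantel_r ~ vegetation * %s", cv),
            class = "phylospace_singular_fit")
    }
    fit
  })
  names(fits) <- covariates
  if (full_model) {
    f <- stats::reformulate(sprintf("vegetation * (%s)",
                                    paste(covariates, collapse = " + ")),
                            response = "mantel_r")
    fits$full <- stats::glm(f, data = dat, family = stats::gaussian())
  }
  structure(fits, class = "mantel_glms")
}

#' @export
print.mantel_glms <- function(x, ...) {
  cat(sprintf("<mantel_glms> %d Gaussian GLM(s): %s\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Coefficient table for a set of Mantel GLMs
#'
#' @param x A `mantel_glms` object.
#' @param ... Unused.
#' @return Tibble of per-term estimates with a `model` column; one row per
#'   coefficient (broom's `tidy.glm` columns).
#' @export
tidy.mantel_glms <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(fit, nm)
    dplyr::mutate(broom::tidy(fit), model = nm, .before = 1))
}

#' Model-level summaries for a set of Mantel GLMs
#'
#' @inheritParams tidy.mantel_glms
#' @return Tibble with one row per model (broom's `glance.glm` columns).
#' @export
glance.mantel_glms <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(fit, nm)
    dplyr::mutate(broom::glance(fit), model = nm, .before = 1))
}
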