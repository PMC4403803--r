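#' Build a run configuration
#'
#' Either the three input paths (`tree`, `plants`, `plots_meta`) or a
#' `sim` list of [sim_params()] arguments must be supplied, not both.
#' Defaults follow the analysis conventions of this kind of survey: 999
#' Mantel permutations, 10,000 PD null replicates, alpha 0.05.
#'
#' @param tree,plants,plots_meta Input paths (newick; stem-map CSV; plot
#'   metadata CSV).
#' @param sim Named list passed to [sim_params()] for a simulated run.
#' @param n_perm Mantel permutations (>= 99).
#' @param n_rep PD null replicates (>= 999).
#' @param alpha Significance level.
#' @param seed Integer seed for the whole run.
#' @param exclude_status,exclude_families Optional upfront filters.
#' @param graminoid_families Families treated as graminoids in the PD
#'   sensitivity rerun.
#' @param include_conspecific Keep conspecific pairs in Mantel matrices.
#' @param genus_fallback Allow genus-level tip matching.
#' @param out Output directory (NULL: nothing written).
#' @return List of class `run_config`.
#' @export
run_config <- function(tree = NULL, plants = NULL, plots_meta = NULL, sim = NULL,
                       n_perm = 999, n_rep = 10000, alpha = 0.05, seed = NULL,
                       exclude_status = NULL, exclude_families = NULL,
                       graminoid_families = "Poaceae",
                       include_conspecific = TRUE, genus_fallback = FALSE,
                       out = NULL) {
  has_paths <- !is.null(tree) || !is.null(plants) || !is.null(plots_meta)
  if (has_paths && !is.null(sim)) {
    abort("Supply input paths or simulation parameters, not both.",
          class = "phylospace_parameter_error")
  }
  if (has_paths && (is.null(tree) || is.null(plants) || is.null(plots_meta))) {
    abort("All three of `tree`, `plants`, `plots_meta` are required for a file run.",
          class = "phylospace_parameter_error")
  }
  if (!has_paths && is.null(sim)) {
    abort("Supply either input paths or simulation parameters.",
          class = "phylospace_parameter_error")
  }
  if (n_perm < 99) abort("`n_perm` must be at least 99.", class = "phylospace_parameter_error")
  if (n_rep < 999) abort("`n_rep` must be at least 999.", class = "phylospace_parameter_error")
  structure(
    list(tree = tree, plants = plants, plots_meta = plots_meta, sim = sim,
         n_perm = n_perm, n_rep = n_rep, alpha = alpha, seed = seed,
         exclude_status = exclude_status, exclude_families = exclude_families,
         graminoid_families = graminoid_families,
         include_conspecific = include_conspecific,
         genus_fallback = genus_fallback, out = out),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "phylospace_parameter_error")
  }
  do.call(run_config, raw)
}

#' Run the full spatial-phylogenetic analysis
#'
#' Orchestrates the pipeline: read (or simulate) the tree and stem maps,
#' build the per-plot pair-distance matrices, run per-plot Mantel tests,
#' run the PD null suite (full data, aliens removed, graminoids removed),
#' assemble the plot-summary table, and fit the vegetation ANOVAs and the
#' Mantel-r GLMs. Per-plot failures are recorded in the respective result
#' tables and the run continues; stages that need more structure than the
#' data offers (ANOVA with a single vegetation type, GLMs with too few
#' plots) are skipped with a warning.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @return List of class `phylospace_run`: `stem_map`, `tree`, `mantel`,
#'   `pd_suite`, `summaries`, `anovas`, `glms` (possibly NULL), `config`.
#'   When `config$out` is set, CSV/JSON reports are also written there.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$sim)) {
    sim <- simulate_study(do.call(sim_params, config$sim), seed = config$seed)
    stem_map <- sim$stem_map
    tree <- sim$tree
  } else {
    tree <- read_ultrametric_tree(config$tree)
    stem_map <- read_stem_maps(config$plants, config$plots_meta)
  }
  if (!is.null(config$exclude_status) || !is.null(config$exclude_families)) {
    stem_map <- filter_plants(stem_map, config$exclude_status, config$exclude_families)
  }
  seeds <- derive_seeds(config$seed %||% NULL, 2)
  mantel <- mantel_tests(stem_map, tree, n_perm = config$n_perm,
                         alpha = config$alpha, seed = seeds[[1]],
                         include_conspecific = config$include_conspecific,
                         genus_fallback = config$genus_fallback)
  pd_suite <- run_pd_suite(stem_map, tree, n_rep = config$n_rep,
                           alpha = config$alpha, seed = seeds[[2]],
                           graminoid_families = config$graminoid_families)
  summaries <- plot_summaries(stem_map, tree, mantel = mantel,
                              pd_null = pd_suite[pd_suite$configuration == "full", ])
  anovas <- if (dplyr::n_distinct(summaries$vegetation) < 2 ||
                min(table(summaries$vegetation)) < 2) {
    warn("ANOVA skipped: need two vegetation types with at least two plots each.")
    NULL
  } else {
    vegetation_anovas(summaries)
  }
  skip_glms <- function(e) {
    warn(sprintf("GLMs skipped: %s", conditionMessage(e)))
    NULL
  }
  glms <- tryCatch(
    fit_mantel_glms(summaries),
    phylospace_parameter_error = skip_glms,
    phylospace_singular_fit = skip_glms)
  run <- structure(
    list(stem_map = stem_map, tree = tree, mantel = mantel, pd_suite = pd_suite,
         summaries = summaries, anovas = anovas, glms = glms, config = config),
    class = "phylospace_run"
  )
  if (!is.null(config$out)) write_run(run, config$out)
  run
}

#' @export
print.phylospace_run <- function(x, ...) {
  cat(sprintf("<phylospace_run> %d plots, %d individuals\n",
              nrow(x$summaries), nrow(x$stem_map)))
  sig <- sum(x$mantel$significant, na.rm = TRUE)
  cat(sprintf("  Mantel: %d/%d plots significant (alpha = %g)\n",
              sig, nrow(x$mantel), x$config$alpha))
  full <- x$pd_suite[x$pd_suite$configuration == "full", ]
  cat(sprintf("  PD null: %d clustered, %d overdispersed, %d neither\n",
              sum(full$classification == "clustered", na.rm = TRUE),
              sum(full$classification == "overdispersed", na.rm = TRUE),
              sum(full$classification == "neither", na.rm = TRUE)))
  invisible(x)
}

# Write the CSV/JSON report of a finished run.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$summaries, file.path(dir, "plot_summaries.csv"))
  readr::write_csv(run$mantel, file.path(dir, "mantel_tests.csv"))
  readr::write_csv(run$pd_suite, file.path(dir, "pd_null_suite.csv"))
  if (!is.null(run$anovas)) {
    readr::write_csv(run$anovas, file.path(dir, "vegetation_anovas.csv"))
  }
  if (!is.null(run$glms)) {
    readr::write_csv(tidy.mantel_glms(run$glms), file.path(dir, "mantel_glm_terms.csv"))
  }
  report <- list(
    n_plots = nrow(run$summaries),
    n_individuals = nrow(run$stem_map),
    alpha = run$config$alpha,
    n_perm = run$config$n_perm,
    n_rep = run$config$n_rep,
    seed = run$config$seed,
    anovas = run$anovas,
    glm_terms = if (!is.null(run$glms)) tidy.mantel_glms(run$glms)
  )
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
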