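#' Read stem-map and plot-metadata tables
#'
#' Reads a delimited stem-map table (one row per individual plant) and a
#' plot-metadata table, validates them, and returns one flat tibble of
#' individuals with their plot's metadata joined on. Required stem-map
#' columns: `plot_id`, `species`, `status`, `x`, `y` (header names matched
#' case-insensitively; comma-separated UTF-8 with "." decimal). Optional:
#' `individual_id` (generated when absent), `family`, `genus`. Required
#' metadata columns: `plot_id`, `vegetation`; optional `width`, `height`
#' (default 5 m each, the usual quadrat for this kind of census).
#'
#' Rows whose coordinates fall outside `[0, width] x [0, height]` are
#' rejected with their row numbers. `status` must be `indigenous` or
#' `alien`, `vegetation` must be `forest` or `grassland`, and a species may
#' not carry both statuses (possible with genus-level labels and a sign of
#' a data problem).
#'
#' @param plants_path Path to the stem-map CSV.
#' @param meta_path Path to the plot-metadata CSV.
#' @return A tibble of class `stem_map` with columns `plot_id`,
#'   `individual_id`, `species`, `family`, `status`, `x`, `y`,
#'   `vegetation`, `width`, `height`.
#' @export
read_stem_maps <- function(plants_path, meta_path) {
  plants <- readr::read_csv(plants_path, show_col_types = FALSE,
                            locale = readr::locale(decimal_mark = "."))
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  names(plants) <- tolower(names(plants))
  names(meta) <- tolower(names(meta))

  need <- c("plot_id", "species", "status", "x", "y")
  missing_cols <- setdiff(need, names(plants))
  if (length(missing_cols)) {
    abort(sprintf("Stem map is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "phylospace_schema_error")
  }
  need_meta <- c("plot_id", "vegetation")
  missing_meta <- setdiff(need_meta, names(meta))
  if (length(missing_meta)) {
    abort(sprintf("Plot metadata is missing required column(s): %s",
                  paste(missing_meta, collapse = ", ")),
          class = "phylospace_schema_error")
  }
  if (!"width" %in% names(meta)) meta$width <- 5
  if (!"height" %in% names(meta)) meta$height <- 5
  if (!"family" %in% names(plants)) plants$family <- NA_character_
  if (!"individual_id" %in% names(plants)) {
    plants <- plants |>
      dplyr::group_by(.data$plot_id) |>
      dplyr::mutate(individual_id = sprintf("ind%04d", dplyr::row_number())) |>
      dplyr::ungroup()
  }
  plants <- dplyr::mutate(plants,
    plot_id = as.character(.data$plot_id),
    individual_id = as.character(.data$individual_id),
    species = as.character(.data$species),
    status = tolower(as.character(.data$status))
  )
  meta <- dplyr::mutate(meta,
    plot_id = as.character(.data$plot_id),
    vegetation = tolower(as.character(.data$vegetation))
  )
  validate_stem_map(plants, meta)
}

# Shared validation used by the reader and the simulator's writer round-trip.
validate_stem_map <- function(plants, meta) {
  bad_veg <- setdiff(unique(meta$vegetation), c("forest", "grassland"))
  if (length(bad_veg)) {
    abort(sprintf("Unknown vegetation label(s): %s", paste(bad_veg, collapse = ", ")),
          class = "phylospace_validation_error")
  }
  if (any(meta$width <= 0) || any(meta$height <= 0)) {
    abort("Plot width and height must be positive.",
          class = "phylospace_validation_error")
  }
  orphan <- setdiff(unique(plants$plot_id), meta$plot_id)
  if (length(orphan)) {
    abort(sprintf("Plot(s) in stem map absent from metadata: %s",
                  paste(orphan, collapse = ", ")),
          class = "phylospace_join_error")
  }
  bad_status <- setdiff(unique(plants$status), c("indigenous", "alien"))
  if (length(bad_status)) {
    abort(sprintf("Unknown status label(s): %s", paste(bad_status, collapse = ", ")),
          class = "phylospace_validation_error")
  }
  two_status <- plants |>
    dplyr::distinct(.data$species, .data$status) |>
    dplyr::count(.data$species) |>
    dplyr::filter(.data$n > 1)
  if (nrow(two_status)) {
    abort(sprintf("Species recorded with both statuses: %s",
                  paste(two_status$species, collapse = ", ")),
          class = "phylospace_validation_error")
  }
  joined <- dplyr::inner_join(plants, meta, by = "plot_id")
  out_of_plot <- which(
    joined$x < 0 | joined$x > joined$width | joined$y < 0 | joined$y > joined$height
  )
  if (length(out_of_plot)) {
    warn(sprintf("Rejected %d row(s) with coordinates outside the plot: rows %s",
                 length(out_of_plot),
                 paste(out_of_plot, collapse = ", ")),
         class = "phylospace_row_rejection")
    joined <- joined[-out_of_plot, , drop = FALSE]
  }
  if (nrow(joined) == 0) {
    abort("No valid plant records remain.", class = "phylospace_validation_error")
  }
  dup <- joined |>
    dplyr::count(.data$plot_id, .data$individual_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort("`individual_id` must be unique within each plot.",
          class = "phylospace_validation_error")
  }
  out <- joined |>
    dplyr::select(dplyr::all_of(c("plot_id", "individual_id", "species", "family",
                                  "status", "x", "y", "vegetation", "width", "height"))) |>
    as_tibble()
  class(out) <- c("stem_map", class(out))
  out
}

#' Write a stem map back to CSV files
#'
#' Inverse of [read_stem_maps()]: splits the flat stem-map tibble into a
#' stem-map CSV and a plot-metadata CSV, so simulated and real data flow
#' through identical files.
#'
#' @param stem_map A `stem_map` tibble.
#' @param plants_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_stem_maps <- function(stem_map, plants_path, meta_path) {
  plants <- dplyr::select(stem_map, dplyr::all_of(
    c("plot_id", "individual_id", "species", "family", "status", "x", "y")))
  meta <- dplyr::distinct(stem_map, .data$plot_id, .data$vegetation,
                          .data$width, .data$height)
  readr::write_csv(plants, plants_path)
  readr::write_csv(meta, meta_path)
  invisible(c(plants_path, meta_path))
}

#' Per-plot stem density
#'
#' @param stem_map A `stem_map` tibble (or any data frame with `plot_id`,
#'   `width`, `height`).
#' @return Tibble with `plot_id`, `n_individuals`, `density` (plants per m^2).
#' @export
plant_density <- function(stem_map) {
  stem_map |>
    dplyr::group_by(.data$plot_id, .data$width, .data$height) |>
    dplyr::summarise(n_individuals = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(density = .data$n_individuals / (.data$width * .data$height)) |>
    dplyr::select(dplyr::all_of(c("plot_id", "n_individuals", "density")))
}

#' Per-plot percentage of alien individuals
#'
#' @inheritParams plant_density
#' @return Tibble with `plot_id`, `n_individuals`, `n_alien`, `pct_alien`
#'   (0-100).
#' @export
percent_alien <- function(stem_map) {
  stem_map |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      n_alien = sum(.data$status == "alien"),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_alien = 100 * .data$n_alien / .data$n_individuals)
}

#' Filter individuals by status and/or family
#'
#' Drops individuals whose `status` is in `exclude_status` or whose
#' `family` is in `exclude_families`; plot metadata is untouched. Used for
#' the sensitivity reruns (aliens removed; graminoids removed). Errors if
#' a filter would empty the whole data set; plots emptied individually are
#' simply absent from the result (callers mark them unevaluable).
#'
#' @inheritParams plant_density
#' @param exclude_status Character vector of statuses to drop (or NULL).
#' @param exclude_families Character vector of families to drop (or NULL),
#'   e.g. `c("Poaceae")` for a grass-removal rerun, or
#'   `c("Poaceae", "Cyperaceae")` for all graminoids.
#' @return Filtered `stem_map` tibble.
#' @export
filter_plants <- function(stem_map, exclude_status = NULL, exclude_families = NULL) {
  out <- stem_map
  if (!is.null(exclude_status)) {
    out <- dplyr::filter(out, !.data$status %in% tolower(exclude_status))
  }
  if (!is.null(exclude_families)) {
    out <- dplyr::filter(out, is.na(.data$family) | !.data$family %in% exclude_families)
  }
  if (nrow(out) == 0) {
    abort("Filter removed every individual; downstream statistics are undefined.",
          class = "phylospace_empty_plot_error")
  }
  out
}

#' Study-wide summary counts
#'
#' Totals over all plots: individuals, alien individuals, distinct species,
#' alien species, and distinct genera and families where those columns (or
#' a binomial species name to take the genus from) are available.
#'
#' @inheritParams plant_density
#' @return One-row tibble of totals.
#' @export
study_summary <- function(stem_map) {
  genus <- if ("genus" %in% names(stem_map)) {
    stem_map$genus
  } else {
    vapply(strsplit(stem_map$species, "[ _]"), `[[`, "", 1)
  }
  sp <- dplyr::distinct(
    tibble(species = stem_map$species, status = stem_map$status, genus = genus,
           family = stem_map[["family"]] %||% NA_character_))
  tibble(
    n_individuals = nrow(stem_map),
    n_alien_individuals = sum(stem_map$status == "alien"),
    n_species = dplyr::n_distinct(stem_map$species),
    n_alien_species = dplyr::n_distinct(stem_map$species[stem_map$status == "alien"]),
    n_genera = dplyr::n_distinct(sp$genus),
    n_alien_genera = dplyr::n_distinct(sp$genus[sp$status == "alien"]),
    n_families = if (all(is.na(sp$family))) NA_integer_ else
      dplyr::n_distinct(sp$family[!is.na(sp$family)]),
    n_plots = dplyr::n_distinct(stem_map$plot_id)
  )
}

#' Species abundance and plot-presence table
#'
#' Per-species total abundance and the number of forest and grassland plots
#' in which it occurs — the machine-readable shape of a study's summary
#' table of most-abundant species.
#'
#' @inheritParams plant_density
#' @return Tibble with `species`, `status`, `family`, `total_abundance`,
#'   `forest_plots`, `grassland_plots`, sorted by descending abundance.
#' @export
species_abundance <- function(stem_map) {
  stem_map |>
    dplyr::group_by(.data$species, .data$status, .data$family) |>
    dplyr::summarise(
      total_abundance = dplyr::n(),
      forest_plots = dplyr::n_distinct(.data$plot_id[.data$vegetation == "forest"]),
      grassland_plots = dplyr::n_distinct(.data$plot_id[.data$vegetation == "grassland"]),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total_abundance))
}

#' Read a species-by-plot representation table
#'
#' Accepts either a long table (`species`, `plot_id`, `abundance`, plus
#' optional `status`, `family`) or a wide table (one `species` column, one
#' column per plot holding abundances). Combined with a plot-metadata
#' table this reconstructs abundance-level (though not coordinate-level)
#' stem maps: each individual is materialised without coordinates, which
#' is enough for counting summaries and PD but not for distances.
#'
#' @param path Path to the CSV.
#' @param meta Plot metadata tibble (`plot_id`, `vegetation`), or path to it.
#' @return A tibble with one row per species-plot combination
#'   (`species`, `status`, `family`, `plot_id`, `vegetation`, `abundance`).
#' @export
read_species_table <- function(path, meta) {
  if (is.character(meta)) {
    meta <- readr::read_csv(meta, show_col_types = FALSE)
  }
  names(meta) <- tolower(names(meta))
  meta <- dplyr::mutate(meta, plot_id = as.character(.data$plot_id),
                        vegetation = tolower(.data$vegetation))
  tab <- readr::read_csv(path, show_col_types = FALSE)
  # normalise annotation headers only: in the wide shape the remaining
  # columns are plot ids whose case must survive
  ann <- tolower(names(tab)) %in% c("species", "status", "family", "genus",
                                    "plot_id", "abundance")
  names(tab)[ann] <- tolower(names(tab))[ann]
  if (!"species" %in% names(tab)) {
    abort("Species table needs a `species` column.", class = "phylospace_schema_error")
  }
  if (!all(c("plot_id", "abundance") %in% names(tab))) {
    # wide shape: every non-annotation column is a plot
    id_cols <- intersect(names(tab), c("species", "status", "family", "genus"))
    tab <- tidyr::pivot_longer(tab, cols = -dplyr::all_of(id_cols),
                               names_to = "plot_id", values_to = "abundance")
  }
  tab <- tab |>
    dplyr::mutate(plot_id = as.character(.data$plot_id)) |>
    dplyr::filter(!is.na(.data$abundance), .data$abundance > 0)
  if (!"status" %in% names(tab)) tab$status <- "indigenous"
  if (!"family" %in% names(tab)) tab$family <- NA_character_
  orphan <- setdiff(unique(tab$plot_id), meta$plot_id)
  if (length(orphan)) {
    abort(sprintf("Plot(s) in species table absent from metadata: %s",
                  paste(orphan, collapse = ", ")),
          class = "phylospace_join_error")
  }
  tab |>
    dplyr::mutate(status = tolower(.data$status)) |>
    dplyr::inner_join(meta[, c("plot_id", "vegetation")], by = "plot_id") |>
    dplyr::select(dplyr::all_of(c("species", "status", "family", "plot_id",
                                  "vegetation", "abundance")))
}

#' Expand a species-by-plot table to individual records
#'
#' Materialises `abundance` rows per species-plot combination so counting
#' summaries ([study_summary()], [species_abundance()]) apply unchanged to
#' representation tables that lack coordinates.
#'
#' @param species_table Output of [read_species_table()].
#' @return A coordinate-free stem-map-shaped tibble.
#' @export
expand_species_table <- function(species_table) {
  out <- species_table[rep(seq_len(nrow(species_table)), species_table$abundance), ]
  out |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::mutate(individual_id = sprintf("ind%04d", dplyr::row_number()),
                  x = NA_real_, y = NA_real_, width = 5, height = 5) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("plot_id", "individual_id", "species", "family",
                                  "status", "x", "y", "vegetation", "width", "height")))
}
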