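# Distribute a summary table of per-species total abundance and per-
# vegetation plot-presence counts into a long species-by-plot table whose
# marginals reproduce the summary exactly: each species gets its abundance
# split as evenly as possible over the plots it is present in. Any valid
# split preserves the marginals, so recomputing them downstream is a
# genuine round-trip through the counting code.
presence_table_to_long <- function(summary_tab, n_forest = 10, n_grassland = 10) {
  rows <- list()
  for (i in seq_len(nrow(summary_tab))) {
    r <- summary_tab[i, ]
    plots <- c(
      if (r$forest_plots > 0) sprintf("F%02d", seq_len(r$forest_plots)),
      if (r$grassland_plots > 0) sprintf("G%02d", seq_len(r$grassland_plots))
    )
    k <- length(plots)
    ab <- rep(r$total_abundance %/% k, k)
    extra <- r$total_abundance %% k
    if (extra > 0) ab[seq_len(extra)] <- ab[seq_len(extra)] + 1
    rows[[i]] <- tibble::tibble(
      species = r$species, status = r$status, family = r$family,
      plot_id = plots, abundance = ab
    )
  }
  dplyr::bind_rows(rows)
}

presence_meta <- function(n_forest = 10, n_grassland = 10) {
  tibble::tibble(
    plot_id = c(sprintf("F%02d", seq_len(n_forest)),
                sprintf("G%02d", seq_len(n_grassland))),
    vegetation = c(rep("forest", n_forest), rep("grassland", n_grassland))
  )
}

table1_path <- function() {
  system.file("extdata", "table1_abundance.csv", package = "phylospace")
}
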