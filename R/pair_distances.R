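#' Pairwise physical distances among individuals of one plot
#'
#' Plain 2-D Euclidean distances between mapped stem coordinates; no edge
#' correction, since plots are analysed with raw within-plot coordinates.
#'
#' @param plot_plants Rows of a `stem_map` tibble belonging to one plot
#'   (needs `individual_id`, `x`, `y`).
#' @return Symmetric n x n matrix (metres) with individual ids as dimnames.
#' @export
physical_distances <- function(plot_plants) {
  n <- nrow(plot_plants)
  if (n < 2) {
    abort("At least two individuals are needed for pairwise distances.",
          class = "phylospace_insufficient_individuals")
  }
  d <- as.matrix(stats::dist(cbind(plot_plants$x, plot_plants$y)))
  dimnames(d) <- list(plot_plants$individual_id, plot_plants$individual_id)
  d
}

#' Matched physical and phylogenetic distance matrices for one plot
#'
#' The pipeline's central data structure: for every unordered pair of
#' individual plants in a plot, the physical distance between their mapped
#' positions (metres) and the patristic distance between their species
#' (Ma). Conspecific pairs have phylogenetic distance 0 and are kept by
#' default — the zero-distance pairs are what couples conspecific spatial
#' aggregation into the statistic; `include_conspecific = FALSE` masks
#' them (as NA) so downstream correlation uses heterospecific pairs only.
#'
#' @param plot_plants Rows of a `stem_map` tibble for a single plot.
#' @param sdm Species-level patristic matrix from [patristic_matrix()]
#'   covering every species present.
#' @param include_conspecific Keep conspecific pairs (default TRUE).
#' @return Object of class `pair_dist`: list with `plot_id`,
#'   `individual_ids`, `physical`, `phylogenetic` (NA-masked when
#'   conspecifics are excluded), `pair_count` (unmasked pairs), `n`.
#' @export
build_pair_distances <- function(plot_plants, sdm, include_conspecific = TRUE) {
  stopifnot(length(unique(plot_plants$plot_id)) == 1)
  missing_sp <- setdiff(unique(plot_plants$species), rownames(sdm))
  if (length(missing_sp)) {
    abort(sprintf("Species missing from the distance matrix: %s",
                  paste(missing_sp, collapse = ", ")),
          class = "phylospace_lookup_error")
  }
  phys <- physical_distances(plot_plants)
  n <- nrow(plot_plants)
  phy <- sdm[plot_plants$species, plot_plants$species, drop = FALSE]
  dimnames(phy) <- dimnames(phys)
  diag(phy) <- 0
  if (!include_conspecific) {
    consp <- outer(plot_plants$species, plot_plants$species, `==`)
    diag(consp) <- FALSE
    if (all(consp[upper.tri(consp)])) {
      abort("All individuals are conspecific; masking conspecific pairs leaves no data.",
            class = "phylospace_degenerate_matrix")
    }
    phy[consp] <- NA_real_
  }
  structure(
    list(
      plot_id = plot_plants$plot_id[[1]],
      individual_ids = plot_plants$individual_id,
      physical = phys,
      phylogenetic = phy,
      pair_count = sum(!is.na(upper_tri_values(phy))),
      n = n
    ),
    class = "pair_dist"
  )
}

#' @export
print.pair_dist <- function(x, ...) {
  cat(sprintf("<pair_dist> plot %s: %d individuals, %d pairs (%s conspecific pairs)\n",
              x$plot_id, x$n, x$pair_count,
              if (anyNA(x$phylogenetic)) "masked" else "including"))
  invisible(x)
}

#' Tidy a pair_dist into one row per unordered pair
#'
#' @param x A `pair_dist` object.
#' @param ... Unused.
#' @return Tibble with `plot_id`, `id_i`, `id_j`, `physical`, `phylogenetic`.
#' @export
tidy.pair_dist <- function(x, ...) {
  ut <- upper.tri(x$physical)
  idx <- which(ut, arr.ind = TRUE)
  tibble(
    plot_id = x$plot_id,
    id_i = x$individual_ids[idx[, 1]],
    id_j = x$individual_ids[idx[, 2]],
    physical = x$physical[ut],
    phylogenetic = x$phylogenetic[ut]
  )
}

#' Scatterplot of phylogenetic against physical pair distances
#'
#' @param object A `pair_dist` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pair_dist <- function(object, ...) {
  df <- tidy.pair_dist(object)
  ggplot2::ggplot(df[!is.na(df$phylogenetic), ],
                  ggplot2::aes(x = .data$physical, y = .data$phylogenetic)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::labs(
      x = "Physical distance (m)", y = "Phylogenetic distance (Ma)",
      title = sprintf("Plot %s", object$plot_id)
    )
}
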