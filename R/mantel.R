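#' Pearson correlation over the unmasked pairs of a pair_dist
#'
#' Vectorises the upper triangles of the matched physical and phylogenetic
#' matrices and returns their Pearson correlation. Errors (rather than
#' silently returning 0) when either vector has zero variance, e.g. a
#' single-species plot.
#'
#' @param pd A `pair_dist` from [build_pair_distances()].
#' @return Pearson r.
#' @export
pairwise_pearson <- function(pd) {
  x <- upper_tri_values(pd$physical)
  y <- upper_tri_values(pd$phylogenetic)
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    abort("Fewer than 3 unmasked pairs; correlation not defined.",
          class = "phylospace_degenerate_matrix")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance in a distance vector; correlation undefined.",
          class = "phylospace_degenerate_matrix")
  }
  stats::cor(x, y)
}

#' Mantel permutation test for one plot
#'
#' Tests the association between the physical and phylogenetic distance
#' matrices by jointly permuting the rows and columns of the phylogenetic
#' matrix under random relabelling of individuals. The permutation p-value
#' uses the add-one rule, `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`
#' for the one-sided "greater" alternative (the default: spatial
#' aggregation of relatives shows up as positive r), so p is never zero
#' and never below `1/(n_perm + 1)`.
#'
#' @param pd A `pair_dist` object.
#' @param n_perm Number of permutations (default 999).
#' @param alternative One of "greater", "less", "two.sided".
#' @param seed Optional integer; fully determines the permutation stream.
#' @param alpha Significance level used for the `significant` flag.
#' @return One-row tibble of class `mantel_result`: `plot_id`, `r`,
#'   `p_value`, `n_perm`, `n_individuals`, `pair_count`, `alternative`,
#'   `significant`.
#' @export
mantel_test <- function(pd, n_perm = 999, alternative = c("greater", "less", "two.sided"),
                        seed = NULL, alpha = 0.05) {
  alternative <- match.arg(alternative)
  assert_scalar_count(n_perm, "n_perm", min = 1L)
  r_obs <- pairwise_pearson(pd)
  n <- pd$n
  ut <- upper.tri(pd$physical)
  x <- pd$physical[ut]
  r_perm <- with_seed_or_stream(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      y <- pd$phylogenetic[p, p][ut]
      keep <- !is.na(y)
      suppressWarnings(stats::cor(x[keep], y[keep]))
    }, numeric(1))
  })
  # permutations can make the masked subset degenerate; drop those draws
  ok <- is.finite(r_perm)
  n_eff <- sum(ok)
  r_perm <- r_perm[ok]
  p_value <- switch(alternative,
    greater   = (1 + sum(r_perm >= r_obs)) / (1 + n_eff),
    less      = (1 + sum(r_perm <= r_obs)) / (1 + n_eff),
    two.sided = (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_eff)
  )
  out <- tibble(
    plot_id = pd$plot_id,
    r = r_obs,
    p_value = p_value,
    n_perm = n_eff,
    n_individuals = n,
    pair_count = pd$pair_count,
    alternative = alternative,
    significant = p_value <= alpha
  )
  class(out) <- c("mantel_result", class(out))
  out
}

#' Mantel tests for every plot of a stem map
#'
#' Builds the matched pair-distance matrices per plot and runs
#' [mantel_test()] on each. Plots that are degenerate (a single species,
#' or fewer than 2 individuals) are flagged rather than dropped: their row
#' carries `NA` statistics and the `note` column says why.
#'
#' @param stem_map A `stem_map` tibble.
#' @param tree Tree from [read_ultrametric_tree()] covering all species
#'   (possibly at genus level, see `genus_fallback`).
#' @param n_perm,alternative,alpha,seed Passed to [mantel_test()]; the
#'   seed, when given, derives an independent sub-seed per plot so results
#'   do not depend on plot order.
#' @param include_conspecific Keep conspecific (zero-distance) pairs.
#' @param genus_fallback Map species to a genus-level tip when the exact
#'   name is absent (uses the first word of the binomial, or a `genus`
#'   column when present).
#' @return Tibble with one row per plot plus a `note` column.
#' @export
mantel_tests <- function(stem_map, tree, n_perm = 999,
                         alternative = "greater", alpha = 0.05, seed = NULL,
                         include_conspecific = TRUE, genus_fallback = FALSE) {
  sdm <- stem_map_patristic(stem_map, tree, genus_fallback)
  plot_ids <- unique(stem_map$plot_id)
  seeds <- derive_seeds(seed, length(plot_ids))
  purrr::map2_dfr(plot_ids, seeds, function(pid, s) {
    plants <- stem_map[stem_map$plot_id == pid, ]
    res <- tryCatch(
      {
        pd <- build_pair_distances(plants, sdm, include_conspecific)
        dplyr::mutate(mantel_test(pd, n_perm = n_perm, alternative = alternative,
                                  seed = s, alpha = alpha),
                      note = NA_character_)
      },
      phylospace_degenerate_matrix = function(e) degenerate_mantel_row(pid, plants, e),
      phylospace_insufficient_individuals = function(e) degenerate_mantel_row(pid, plants, e)
    )
    res
  })
}

degenerate_mantel_row <- function(pid, plants, e) {
  tibble(
    plot_id = pid, r = NA_real_, p_value = NA_real_, n_perm = NA_integer_,
    n_individuals = nrow(plants), pair_count = NA_integer_,
    alternative = NA_character_, significant = NA,
    note = conditionMessage(e)
  )
}

# Species-level patristic matrix for everything in a stem map.
stem_map_patristic <- function(stem_map, tree, genus_fallback = FALSE) {
  species <- unique(stem_map$species)
  genus <- NULL
  if (genus_fallback) {
    genus <- if ("genus" %in% names(stem_map)) {
      stem_map$genus[match(species, stem_map$species)]
    } else {
      vapply(strsplit(species, "[ _]"), `[[`, "", 1)
    }
  }
  patristic_matrix(tree, species, genus)
}

# One independent 31-bit sub-seed per unit of work, or NULLs when unseeded.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  with_seed_or_stream(seed, as.list(sample.int(.Machine$integer.max, n)))
}
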