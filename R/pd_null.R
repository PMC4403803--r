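#' Richness-constrained Faith's PD null test for one assemblage
#'
#' Compares the observed Faith's PD of an assemblage against a null
#' distribution built by repeatedly drawing the same number of species
#' uniformly, without replacement and without abundance weighting, from a
#' species pool. Tail probabilities are rank-based with ties counted
#' inclusively and add-one smoothing:
#' `p_low = (1 + #{PD_null <= PD_obs}) / (1 + n_rep)` and symmetrically for
#' `p_high`. The two-sided decision at overall level `alpha` calls a plot
#' clustered when `p_low <= alpha/2` (PD lower than expected from its
#' richness) and overdispersed when `p_high <= alpha/2`; degenerate nulls
#' (e.g. a star tree, where PD depends only on richness) land on
#' "neither" because both smoothed tails stay near 1.
#'
#' @param tree Tree from [read_ultrametric_tree()].
#' @param pool Character vector: the species pool (all tips eligible for
#'   random assembly; typically every species observed across all plots).
#' @param observed Character vector: the assemblage, a subset of `pool`.
#' @param n_rep Null replicates (default 10000).
#' @param alpha Overall two-sided level (default 0.05).
#' @param seed Optional integer for reproducible draws.
#' @param rooted Passed to [faith_pd()].
#' @return One-row tibble: `observed_pd`, `richness`, `pool_size`,
#'   `null_mean`, `null_sd`, `ses`, `p_low`, `p_high`, `n_rep`,
#'   `classification`.
#' @export
pd_null_test <- function(tree, pool, observed, n_rep = 10000, alpha = 0.05,
                         seed = NULL, rooted = TRUE) {
  assert_scalar_count(n_rep, "n_rep", min = 1L)
  pool <- unique(pool)
  observed <- unique(observed)
  if (length(observed) < 1) {
    abort("`observed` must contain at least one species.",
          class = "phylospace_domain_error")
  }
  if (!all(observed %in% pool)) {
    abort(sprintf("Observed species outside the pool: %s",
                  paste(setdiff(observed, pool), collapse = ", ")),
          class = "phylospace_lookup_error")
  }
  labels <- match_tree_labels(pool, tree)
  k <- length(observed)
  obs_pd <- faith_pd(tree, observed, rooted = rooted)
  if (k == length(pool)) {
    warn("Assemblage equals the pool; the null has a single possible draw.",
         class = "phylospace_degenerate_null")
    return(pd_null_row(obs_pd, k, length(pool), obs_pd, 0, obs_pd, n_rep = 1,
                       alpha = alpha))
  }

  # PD per draw via an edge-incidence product: one matrix multiply per plot
  # instead of n_rep subtree traversals.
  inc <- edge_tip_incidence(tree)
  len <- tree$edge.length
  if (!rooted) {
    # handled per-draw below through faith_pd; the rooted fast path is the default
    nulls <- with_seed_or_stream(seed, {
      vapply(seq_len(n_rep), function(i)
        faith_pd(tree, sample(pool, k), rooted = FALSE), numeric(1))
    })
  } else {
    pool_idx <- match(unname(labels), colnames(inc))
    nulls <- with_seed_or_stream(seed, {
      draws <- replicate(n_rep, sample(pool_idx, k))
      if (k == 1) draws <- matrix(draws, nrow = 1)
      membership <- matrix(0L, ncol(inc), n_rep)
      membership[cbind(as.vector(draws), rep(seq_len(n_rep), each = k))] <- 1L
      covered <- (inc %*% membership) > 0
      as.vector(crossprod(covered, len))
    })
  }
  pd_null_row(obs_pd, k, length(pool), mean(nulls), stats::sd(nulls), nulls,
              n_rep = n_rep, alpha = alpha)
}

pd_null_row <- function(obs_pd, k, pool_size, null_mean, null_sd, nulls, n_rep, alpha) {
  eps <- 1e-9 * max(1, abs(obs_pd)) # inclusive ties despite float round-off
  p_low <- (1 + sum(nulls <= obs_pd + eps)) / (1 + n_rep)
  p_high <- (1 + sum(nulls >= obs_pd - eps)) / (1 + n_rep)
  classification <- if (p_low <= alpha / 2) {
    "clustered"
  } else if (p_high <= alpha / 2) {
    "overdispersed"
  } else {
    "neither"
  }
  tibble(
    observed_pd = obs_pd, richness = k, pool_size = pool_size,
    null_mean = null_mean,
    null_sd = if (is.na(null_sd)) 0 else null_sd,
    ses = if (is.na(null_sd) || null_sd == 0) NA_real_ else (obs_pd - null_mean) / null_sd,
    p_low = p_low, p_high = p_high, n_rep = n_rep,
    classification = classification
  )
}

#' PD null tests for every plot of a stem map
#'
#' Runs [pd_null_test()] per plot. The pool defaults to all species
#' observed across all plots of the study (both vegetation types mixed —
#' a grassland assemblage is judged against the grassland-forest species
#' mix); `pool = "vegetation"` restricts each plot's pool to species of
#' its own vegetation type.
#'
#' @inheritParams pd_null_test
#' @param stem_map A `stem_map` tibble.
#' @param pool `"study"` (default), `"vegetation"`, or an explicit
#'   character vector of species.
#' @return Tibble with one row per plot (`plot_id`, `vegetation`, then the
#'   [pd_null_test()] columns).
#' @export
pd_null_tests <- function(stem_map, tree, pool = "study", n_rep = 10000,
                          alpha = 0.05, seed = NULL, rooted = TRUE) {
  plot_ids <- unique(stem_map$plot_id)
  seeds <- derive_seeds(seed, length(plot_ids))
  study_pool <- unique(stem_map$species)
  purrr::map2_dfr(plot_ids, seeds, function(pid, s) {
    plants <- stem_map[stem_map$plot_id == pid, ]
    this_pool <- if (identical(pool, "study")) {
      study_pool
    } else if (identical(pool, "vegetation")) {
      unique(stem_map$species[stem_map$vegetation == plants$vegetation[[1]]])
    } else {
      pool
    }
    res <- withCallingHandlers(
      pd_null_test(tree, this_pool, unique(plants$species), n_rep = n_rep,
                   alpha = alpha, seed = s, rooted = rooted),
      phylospace_degenerate_null = function(w) invokeRestart("muffleWarning")
    )
    dplyr::bind_cols(tibble(plot_id = pid, vegetation = plants$vegetation[[1]]), res)
  })
}

#' PD null suite: full data and sensitivity reruns
#'
#' Repeats the per-plot PD null classification for three configurations —
#' the full data, aliens removed, and graminoids removed — recomputing the
#' species pool within each configuration. A plot emptied by a filter is
#' kept as an unevaluable row (`classification = NA`) while the remaining
#' plots proceed.
#'
#' @inheritParams pd_null_tests
#' @param graminoid_families Families treated as graminoids for the
#'   grass-removal rerun; default `"Poaceae"` (use
#'   `c("Poaceae", "Cyperaceae")` to drop all graminoids).
#' @return Tibble of per-plot results with a `configuration` column
#'   (`full`, `no_alien`, `no_graminoid`).
#' @export
run_pd_suite <- function(stem_map, tree, pool = "study", n_rep = 10000,
                         alpha = 0.05, seed = NULL,
                         graminoid_families = "Poaceae") {
  configs <- list(
    full = function(sm) sm,
    no_alien = function(sm) filter_plants(sm, exclude_status = "alien"),
    no_graminoid = function(sm) filter_plants(sm, exclude_families = graminoid_families)
  )
  seeds <- derive_seeds(seed, length(configs))
  all_plots <- dplyr::distinct(stem_map, .data$plot_id, .data$vegetation)
  purrr::imap_dfr(configs, function(f, nm) {
    s <- seeds[[match(nm, names(configs))]]
    filtered <- tryCatch(f(stem_map), phylospace_empty_plot_error = function(e) NULL)
    if (is.null(filtered)) {
      return(dplyr::mutate(all_plots, configuration = nm, classification = NA_character_))
    }
    res <- pd_null_tests(filtered, tree, pool = pool, n_rep = n_rep,
                         alpha = alpha, seed = s)
    res <- dplyr::left_join(all_plots, res, by = c("plot_id", "vegetation"))
    dplyr::mutate(res, configuration = nm, .before = 1)
  })
}
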