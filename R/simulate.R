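#' Simulation parameters for a synthetic stem-map study
#'
#' Defaults emulate a two-vegetation stem-map survey: twenty 5 x 5 m
#' plots (ten forest, ten grassland), a regional pool of ~200 species on a
#' 150 Ma ultrametric tree, per-plot richness 10-40, per-plot abundance
#' 100-200 (forest) and 200-400 (grassland, the denser sward), and ~9% of
#' pool species alien. `kappa` sets the degree of spatial-phylogenetic
#' coupling: each individual is placed near its species' (phylogenetically
#' heritable) niche centre with probability `kappa` and uniformly at
#' random otherwise; `sigma` is the placement scatter around the centre.
#'
#' @param n_species_pool Species in the regional pool.
#' @param root_age Tree root age, Ma.
#' @param n_plots_forest,n_plots_grassland Plot counts per vegetation type.
#' @param richness_range Named list of c(min, max) per-plot species counts.
#' @param individuals_range Named list of c(min, max) per-plot individuals.
#' @param kappa Spatial-phylogenetic coupling in \[0, 1\].
#' @param sigma Placement scatter around niche centres, metres.
#' @param p_alien_species Fraction of pool species flagged alien.
#' @param plot_size Plot side length, metres (square plots).
#' @param grassland_clade Draw grassland species from the shallowest clade
#'   of the pool (emulating a graminoid-dominated, low-PD sward) instead
#'   of the whole pool.
#' @param alien_clade Confine alien species to a single clade instead of
#'   scattering them uniformly over the pool.
#' @param geometric_theta Parameter of the geometric rank-abundance series.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_species_pool = 200,
                       root_age = 150,
                       n_plots_forest = 10,
                       n_plots_grassland = 10,
                       richness_range = list(forest = c(10, 40), grassland = c(10, 40)),
                       individuals_range = list(forest = c(100, 200), grassland = c(200, 400)),
                       kappa = 0.5,
                       sigma = 0.6,
                       p_alien_species = 0.09,
                       plot_size = 5,
                       grassland_clade = FALSE,
                       alien_clade = FALSE,
                       geometric_theta = 0.2) {
  p <- as.list(environment())
  if (p$kappa < 0 || p$kappa > 1) {
    abort("`kappa` must lie in [0, 1].", class = "phylospace_parameter_error")
  }
  if (p$sigma <= 0) abort("`sigma` must be positive.", class = "phylospace_parameter_error")
  if (p$plot_size <= 0) abort("`plot_size` must be positive.", class = "phylospace_parameter_error")
  if (p$p_alien_species < 0 || p$p_alien_species > 1) {
    abort("`p_alien_species` must lie in [0, 1].", class = "phylospace_parameter_error")
  }
  assert_scalar_count(p$n_species_pool, "n_species_pool", min = 2L)
  assert_scalar_count(p$n_plots_forest, "n_plots_forest", min = 0L)
  assert_scalar_count(p$n_plots_grassland, "n_plots_grassland", min = 0L)
  for (veg in c("forest", "grassland")) {
    rr <- p$richness_range[[veg]]; ir <- p$individuals_range[[veg]]
    if (is.null(rr) || is.null(ir) || length(rr) != 2 || length(ir) != 2 ||
        rr[1] < 1 || rr[1] > rr[2] || ir[1] < 1 || ir[1] > ir[2]) {
      abort(sprintf("Invalid richness/individuals range for %s.", veg),
            class = "phylospace_parameter_error")
    }
    if (rr[2] > p$n_species_pool) {
      abort("Per-plot richness cannot exceed the species pool.",
            class = "phylospace_parameter_error")
    }
    if (ir[1] < rr[1]) {
      abort("Individuals per plot must be at least the plot richness.",
            class = "phylospace_parameter_error")
    }
  }
  structure(p, class = "sim_params")
}

#' Simulate an ultrametric pure-birth tree
#'
#' Yule (pure-birth) topology with exponential waiting times, rescaled so
#' the root age is exact; ultrametric by construction. Tips are labelled
#' `sp001`, `sp002`, ...
#'
#' @param n Number of species (tips), at least 2.
#' @param root_age Target root age, Ma.
#' @param seed Optional integer.
#' @return A validated tree as from [read_ultrametric_tree()].
#' @export
simulate_tree <- function(n, root_age = 150, seed = NULL) {
  assert_scalar_count(n, "n", min = 2L)
  if (root_age <= 0) abort("`root_age` must be positive.", class = "phylospace_parameter_error")
  tree <- with_seed_or_stream(seed, ape::rphylo(n, birth = 1, death = 0))
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n)])
  tree$edge.length <- tree$edge.length * root_age / depth
  validate_ultrametric_tree(tree)
}

#' Simulate phylogenetically heritable niche centres
#'
#' Evolves two independent Brownian-motion traits along the tree (variance
#' proportional to branch length) and rescales each affinely to span
#' `[0, plot_size]`. Close relatives therefore get close centres in
#' expectation, which is the mechanism that couples patristic and spatial
#' distance in simulated plots.
#'
#' @param tree A tree from [simulate_tree()] or [read_ultrametric_tree()].
#' @param plot_size Plot side length, metres.
#' @param seed Optional integer.
#' @return Tibble with `species`, `x0`, `y0`.
#' @export
simulate_niches <- function(tree, plot_size = 5, seed = NULL) {
  rescale <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(plot_size / 2, length(v)))
    (v - rng[1]) / diff(rng) * plot_size
  }
  traits <- with_seed_or_stream(seed, {
    list(x = ape::rTraitCont(tree, model = "BM", sigma = 1),
         y = ape::rTraitCont(tree, model = "BM", sigma = 1))
  })
  tibble(
    species = tree$tip.label,
    x0 = rescale(traits$x[tree$tip.label]),
    y0 = rescale(traits$y[tree$tip.label])
  )
}

# Tips of the shallowest clade holding at least `min_tips` species:
# the candidate "graminoid sward" for low-PD grassland simulation.
shallowest_clade <- function(tree, min_tips) {
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  root_age <- max(depths[seq_len(ntip)])
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  sizes <- vapply(internal, function(nd) length(tip_descendants(tree, nd)), integer(1))
  crown_age <- root_age - depths[internal] # age of each internal node
  ok <- sizes >= min_tips & internal != ntip + 1L
  if (!any(ok)) ok <- sizes >= min_tips
  best <- internal[ok][which.min(crown_age[ok])]
  tree$tip.label[tip_descendants(tree, best)]
}

tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tip_descendants, tree = tree))
}

# Geometric rank-abundance allocation: each of k species gets one
# individual, the remaining N - k are multinomial with geometric weights.
allocate_abundances <- function(k, n_total, theta) {
  probs <- theta * (1 - theta)^(seq_len(k) - 1)
  counts <- rep(1L, k)
  if (n_total > k) {
    counts <- counts + as.integer(stats::rmultinom(1, n_total - k, probs))
  }
  counts
}

#' Simulate one stem-mapped plot
#'
#' Draws richness and total abundance from the vegetation type's ranges,
#' allocates abundances by a geometric rank-abundance series, and places
#' each individual either near its species' niche centre (with probability
#' `kappa`; isotropic Gaussian scatter `sigma`, resampled until inside the
#' plot) or uniformly at random. Species keep their pool-level
#' alien/indigenous status.
#'
#' @param tree Tree covering the pool.
#' @param niches Output of [simulate_niches()].
#' @param vegetation `"forest"` or `"grassland"`.
#' @param params A [sim_params()] object.
#' @param plot_id Plot identifier.
#' @param species_status Named character vector (species -> status); when
#'   NULL all species are indigenous.
#' @param species_pool Candidate species for this plot (default all tips).
#' @param seed Optional integer.
#' @return A `stem_map` tibble for the single plot.
#' @export
simulate_plot <- function(tree, niches, vegetation, params = sim_params(),
                          plot_id = "p01", species_status = NULL,
                          species_pool = tree$tip.label, seed = NULL) {
  stopifnot(vegetation %in% c("forest", "grassland"))
  rr <- params$richness_range[[vegetation]]
  ir <- params$individuals_range[[vegetation]]
  if (min(rr) > length(species_pool)) {
    abort("Species pool smaller than the requested plot richness.",
          class = "phylospace_parameter_error")
  }
  L <- params$plot_size
  with_seed_or_stream(seed, {
    k <- sample(seq(rr[1], min(rr[2], length(species_pool))), 1)
    n_total <- sample(seq(ir[1], ir[2]), 1)
    sp <- sample(species_pool, k)
    counts <- allocate_abundances(k, n_total, params$geometric_theta)
    species <- rep(sp, counts)
    centre <- niches[match(species, niches$species), ]
    coupled <- stats::runif(n_total) < params$kappa
    x <- stats::runif(n_total, 0, L)
    y <- stats::runif(n_total, 0, L)
    for (i in which(coupled)) {
      repeat { # resample, not clip: keeps density smooth at the plot edge
        xi <- stats::rnorm(1, centre$x0[i], params$sigma)
        yi <- stats::rnorm(1, centre$y0[i], params$sigma)
        if (xi >= 0 && xi <= L && yi >= 0 && yi <= L) break
      }
      x[i] <- xi; y[i] <- yi
    }
    status <- if (is.null(species_status)) {
      rep("indigenous", n_total)
    } else {
      unname(species_status[species])
    }
    out <- tibble(
      plot_id = plot_id,
      individual_id = sprintf("ind%04d", seq_len(n_total)),
      species = species,
      family = NA_character_,
      status = status,
      x = x, y = y,
      vegetation = vegetation,
      width = L, height = L
    )
    class(out) <- c("stem_map", class(out))
    out
  })
}

#' Simulate a complete stem-map study
#'
#' One pure-birth tree, one set of niche centres, and
#' `n_plots_forest + n_plots_grassland` plots, fully determined by the
#' seed. With `grassland_clade = TRUE` grassland plots draw their species
#' from the shallowest sufficiently large clade of the pool, giving them
#' systematically lower PD (the graminoid-sward situation); with
#' `alien_clade = TRUE` alien status is confined to one clade instead of
#' being scattered uniformly.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer; drives every random choice.
#' @return List of class `phylospace_sim`: `tree`, `niches`, `stem_map`
#'   (all plots), `species_status`, `params`.
#' @export
simulate_study <- function(params = sim_params(), seed = NULL) {
  seeds <- derive_seeds(seed, 3 + params$n_plots_forest + params$n_plots_grassland)
  tree <- simulate_tree(params$n_species_pool, params$root_age, seed = seeds[[1]])
  niches <- simulate_niches(tree, params$plot_size, seed = seeds[[2]])
  pool <- tree$tip.label
  species_status <- with_seed_or_stream(seeds[[3]], {
    n_alien <- round(params$p_alien_species * length(pool))
    aliens <- if (params$alien_clade && n_alien > 0) {
      clade <- shallowest_clade(tree, n_alien)
      sample(clade, min(n_alien, length(clade)))
    } else {
      sample(pool, n_alien)
    }
    stats::setNames(ifelse(pool %in% aliens, "alien", "indigenous"), pool)
  })
  grass_pool <- if (params$grassland_clade) {
    shallowest_clade(tree, max(params$richness_range$grassland))
  } else {
    pool
  }
  veg <- c(rep("forest", params$n_plots_forest),
           rep("grassland", params$n_plots_grassland))
  plots <- purrr::map_dfr(seq_along(veg), function(i) {
    simulate_plot(
      tree, niches, veg[i], params,
      plot_id = sprintf("%s%02d", substr(veg[i], 1, 1), i),
      species_status = species_status,
      species_pool = if (veg[i] == "grassland") grass_pool else pool,
      seed = seeds[[3 + i]]
    )
  })
  class(plots) <- c("stem_map", class(plots))
  structure(
    list(tree = tree, niches = niches, stem_map = plots,
         species_status = species_status, params = params),
    class = "phylospace_sim"
  )
}

#' @export
print.phylospace_sim <- function(x, ...) {
  cat(sprintf(
    "<phylospace_sim> %d species pool (root age %.4g Ma), %d plots, %d individuals\n",
    length(x$tree$tip.label), root_age(x$tree),
    dplyr::n_distinct(x$stem_map$plot_id), nrow(x$stem_map)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the tree (newick) and the stem-map and plot-metadata CSVs via
#' the same writers the empirical pipeline reads from, so simulated and
#' real data enter the analysis identically.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree_path <- file.path(dir, "tree.nwk")
  plants_path <- file.path(dir, "stem_map.csv")
  meta_path <- file.path(dir, "plots.csv")
  ape::write.tree(sim$tree, file = tree_path)
  write_stem_maps(sim$stem_map, plants_path, meta_path)
  invisible(c(tree = tree_path, plants = plants_path, meta = meta_path))
}
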