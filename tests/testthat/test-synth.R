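test_that("parameter validation catches impossible settings", {
  expect_error(sim_params(kappa = 1.5), class = "phylospace_parameter_error")
  expect_error(sim_params(sigma = 0), class = "phylospace_parameter_error")
  expect_error(sim_params(n_species_pool = 5,
                          richness_range = list(forest = c(10, 40),
                                                grassland = c(10, 40))),
               class = "phylospace_parameter_error")
  expect_error(sim_params(individuals_range = list(forest = c(5, 10),
                                                   grassland = c(200, 400))),
               class = "phylospace_parameter_error")
  expect_error(simulate_tree(1, 100), class = "phylospace_parameter_error")
})

test_that("simulated trees are ultrametric with exact root age", {
  cherry <- simulate_tree(2, root_age = 50, seed = 1)
  expect_equal(sort(cherry$edge.length), c(50, 50)) # single cherry
  for (seed in 1:5) {
    tr <- simulate_tree(25, root_age = 150, seed = seed)
    expect_silent(validate_ultrametric_tree(tr, strict = TRUE))
    expect_equal(root_age(tr), 150)
    expect_equal(length(tr$tip.label), 25)
    expect_false(anyDuplicated(tr$tip.label) > 0)
  }
})

test_that("lineage growth matches an independent pure-birth counter", {
  set.seed(71)
  n <- 32
  fr <- c(0.25, 0.5, 0.75)
  ltt_at <- function(tr, fracs) {
    T <- root_age(tr)
    depths <- ape::node.depth.edgelength(tr)
    vapply(fracs, function(f)
      sum(depths[tr$edge[, 1]] <= f * T & depths[tr$edge[, 2]] > f * T), numeric(1))
  }
  tree_ltt <- rowMeans(vapply(1:200, function(i)
    ltt_at(simulate_tree(n, 100, seed = 500 + i), fr), numeric(3)))
  # oracle: plain birth counter from the root's 2 lineages to n, rescaled time
  counter <- rowMeans(replicate(4000, {
    times <- cumsum(stats::rexp(n - 2, rate = 2:(n - 1)))
    T <- times[n - 2]
    vapply(fr, function(f) 2 + sum(times <= f * T), numeric(1))
  }))
  expect_true(all(abs(tree_ltt - counter) / counter < 0.15))
})

test_that("niche centres are phylogenetically heritable and inside the plot", {
  # zero-length terminal branches in a cherry: no divergence time, same centre
  tr <- read_ultrametric_tree("((A:0,B:0):1,C:1);")
  centres <- simulate_niches(tr, 5, seed = 3)
  expect_equal(centres[centres$species == "A", c("x0", "y0")],
               centres[centres$species == "B", c("x0", "y0")],
               ignore_attr = TRUE)
  expect_true(all(centres$x0 >= 0 & centres$x0 <= 5))
  expect_true(all(centres$y0 >= 0 & centres$y0 <= 5))

  # across trees, patristic distance and centre distance correlate positively
  set.seed(72)
  cors <- vapply(1:60, function(i) {
    tr <- simulate_tree(20, 100, seed = 900 + i)
    cen <- simulate_niches(tr, 5, seed = 950 + i)
    pm <- patristic_matrix(tr)[cen$species, cen$species]
    cd <- as.matrix(stats::dist(cbind(cen$x0, cen$y0)))
    stats::cor(pm[upper.tri(pm)], cd[upper.tri(cd)])
  }, numeric(1))
  expect_gt(mean(cors), 0.2)
  expect_gt(mean(cors > 0), 0.8)
})

test_that("plot simulation conserves abundances and respects plot bounds", {
  p <- do.call(sim_params, small_sim_args())
  tr <- simulate_tree(p$n_species_pool, p$root_age, seed = 4)
  niches <- simulate_niches(tr, p$plot_size, seed = 5)
  for (i in 1:5) {
    pl <- simulate_plot(tr, niches, "grassland", p, plot_id = "g1", seed = 70 + i)
    rr <- p$richness_range$grassland
    ir <- p$individuals_range$grassland
    expect_gte(nrow(pl), ir[1]); expect_lte(nrow(pl), ir[2])
    k <- dplyr::n_distinct(pl$species)
    expect_gte(k, rr[1]); expect_lte(k, rr[2])
    expect_true(all(pl$x >= 0 & pl$x <= p$plot_size))
    expect_true(all(pl$y >= 0 & pl$y <= p$plot_size))
    expect_equal(sum(table(pl$species)), nrow(pl)) # abundances sum to the total
  }
})

test_that("kappa = 1 with tight scatter stacks conspecifics on their centres", {
  p <- do.call(sim_params, small_sim_args(kappa = 1, sigma = 1e-4))
  tr <- simulate_tree(p$n_species_pool, p$root_age, seed = 6)
  niches <- simulate_niches(tr, p$plot_size, seed = 7)
  pl <- simulate_plot(tr, niches, "forest", p, seed = 8)
  spread <- tapply(seq_len(nrow(pl)), pl$species, function(ix)
    max(stats::dist(cbind(pl$x[ix], pl$y[ix])), 0))
  expect_lt(max(spread), 0.01)
  # centre geometry then drives a positive physical-phylogenetic correlation
  sdm <- patristic_matrix(tr, unique(pl$species))
  r <- pairwise_pearson(build_pair_distances(pl, sdm))
  expect_gt(r, 0)
})

test_that("a full study is reproducible end to end, files included", {
  args <- small_sim_args()
  s1 <- simulate_study(do.call(sim_params, args), seed = 99)
  s2 <- simulate_study(do.call(sim_params, args), seed = 99)
  expect_equal(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_equal(as.data.frame(s1$stem_map), as.data.frame(s2$stem_map))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_study(s1, d1); f2 <- write_study(s2, d2)
  for (k in seq_along(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]])) # byte-identical
  }
  # the written study is readable by the standard readers
  back <- read_stem_maps(f1[["plants"]], f1[["meta"]])
  expect_equal(nrow(back), nrow(s1$stem_map))
  tr_back <- read_ultrametric_tree(f1[["tree"]])
  expect_equal(sort(tr_back$tip.label), sort(s1$tree$tip.label))
})

test_that("default parameters give twenty plots, ten per vegetation type", {
  sim <- simulate_study(seed = 123)
  counts <- table(dplyr::distinct(sim$stem_map, plot_id, vegetation)$vegetation)
  expect_equal(as.integer(counts[c("forest", "grassland")]), c(10, 10))
  expect_equal(length(sim$tree$tip.label), 200)
  # alien flag applies at species level, at the configured rate
  st <- table(sim$species_status)
  expect_equal(as.integer(st["alien"]), round(0.09 * 200))
  sm_status <- dplyr::distinct(sim$stem_map, species, status)
  expect_true(all(sm_status$status == sim$species_status[sm_status$species]))
})

test_that("per-plot Mantel r strengthens with the coupling parameter", {
  # compact version of the headline parameter-recovery property
  mean_r_at <- function(kappa, n_studies = 4) {
    args <- small_sim_args(kappa = kappa)
    mean(vapply(seq_len(n_studies), function(i) {
      sim <- simulate_study(do.call(sim_params, args), seed = 3000 + i)
      sdm <- patristic_matrix(sim$tree, unique(sim$stem_map$species))
      rs <- vapply(unique(sim$stem_map$plot_id), function(pid) {
        pl <- sim$stem_map[sim$stem_map$plot_id == pid, ]
        tryCatch(pairwise_pearson(build_pair_distances(pl, sdm)),
                 phylospace_degenerate_matrix = function(e) NA_real_)
      }, numeric(1))
      mean(rs, na.rm = TRUE)
    }, numeric(1)))
  }
  r <- vapply(c(0, 0.5, 1), mean_r_at, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_lt(abs(r[1]), 0.1)
})
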