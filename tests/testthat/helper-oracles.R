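# Independent brute-force oracles used across the suite. These deliberately
# take different routes than the package internals: per-pair root-path
# intersection for patristic distances, per-leaf root-path edge unions for
# PD, and full permutation enumeration for the Mantel null.

# Edge indices on the path from a tip to the root, by parent-pointer walk.
oracle_root_path <- function(tree, tip_label) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node <- match(tip_label, tree$tip.label)
  path <- integer(0)
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    path <- c(path, e)
    node <- tree$edge[e, 1]
  }
  path
}

# Patristic distance: depth(i) + depth(j) - 2 * depth(MRCA), with the MRCA
# found by intersecting root paths.
oracle_patristic <- function(tree, a, b) {
  if (a == b) return(0)
  pa <- oracle_root_path(tree, a)
  pb <- oracle_root_path(tree, b)
  shared <- intersect(pa, pb)
  sum(tree$edge.length[setdiff(pa, shared)]) +
    sum(tree$edge.length[setdiff(pb, shared)])
}

oracle_patristic_matrix <- function(tree, species) {
  n <- length(species)
  m <- matrix(0, n, n, dimnames = list(species, species))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) m[i, j] <- m[j, i] <- oracle_patristic(tree, species[i], species[j])
    }
  }
  m
}

# Rooted Faith's PD: total length of the union of root-path edge sets.
oracle_faith_pd <- function(tree, species) {
  edges <- unique(unlist(lapply(unique(species), oracle_root_path, tree = tree)))
  sum(tree$edge.length[edges])
}

# Random ultrametric test tree (coalescent shape, arbitrary age).
random_ultrametric_tree <- function(n, age = 100) {
  tr <- ape::rcoal(n, tip.label = sprintf("t%02d", seq_len(n)))
  depth <- max(ape::node.depth.edgelength(tr)[seq_len(n)])
  tr$edge.length <- tr$edge.length * age / depth
  validate_ultrametric_tree(tr)
}

# All permutations of 1..n (n small).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exact one-sided ("greater") Mantel p over all n! relabellings,
# inclusive ties, no add-one (the full enumeration is the reference set).
oracle_mantel_exact_p <- function(phys, phy) {
  n <- nrow(phys)
  ut <- upper.tri(phys)
  x <- phys[ut]
  r_obs <- stats::cor(x, phy[ut])
  perms <- all_permutations(n)
  r_all <- apply(perms, 1, function(p) stats::cor(x, phy[p, p][ut]))
  mean(r_all >= r_obs - 1e-12)
}

# Small deterministic stem map: two plots, one shared species.
toy_stem_map <- function() {
  sm <- tibble::tibble(
    plot_id = c("p1", "p1", "p1", "p2", "p2"),
    individual_id = c("i1", "i2", "i3", "i1", "i2"),
    species = c("A", "A", "B", "B", "C"),
    family = c("Fam1", "Fam1", "Poaceae", "Poaceae", "Fam2"),
    status = c("indigenous", "indigenous", "alien", "alien", "indigenous"),
    x = c(0, 3, 1, 2, 4),
    y = c(0, 4, 1, 2, 4),
    vegetation = c("forest", "forest", "forest", "grassland", "grassland"),
    width = 5, height = 5
  )
  class(sm) <- c("stem_map", class(sm))
  sm
}

# Small simulation settings reused by pipeline-level tests.
small_sim_args <- function(...) {
  utils::modifyList(
    list(
      n_species_pool = 40,
      n_plots_forest = 3, n_plots_grassland = 3,
      richness_range = list(forest = c(5, 10), grassland = c(5, 10)),
      individuals_range = list(forest = c(15, 30), grassland = c(20, 40))
    ),
    list(...)
  )
}
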