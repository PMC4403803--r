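#' Read and validate an ultrametric phylogeny from newick text
#'
#' Parses a single rooted newick tree (branch lengths required on every
#' non-root edge, interpreted as millions of years, Ma) and validates it as
#' an ultrametric tree: unique non-empty tip labels, non-negative branch
#' lengths, and all root-to-tip path lengths equal within a relative
#' tolerance. Dated empirical trees often carry small rounding departures
#' from exact ultrametricity, so violations above tolerance raise a warning
#' by default; `strict = TRUE` escalates them to an error.
#'
#' @param newick Newick string, or path to a file containing one tree.
#' @param tol Relative tolerance on root-to-tip depth spread (default 1e-6).
#' @param strict Escalate ultrametricity violations to errors.
#' @return An [ape::phylo] tree with attribute `root_age` (maximum
#'   root-to-tip depth, Ma).
#' @examples
#' tr <- read_ultrametric_tree("((A:1,B:1):1,C:2);")
#' attr(tr, "root_age")  # 2
#' @export
read_ultrametric_tree <- function(newick, tol = 1e-6, strict = FALSE) {
  stopifnot(is.character(newick), length(newick) == 1)
  is_path <- !grepl("\\(", newick) && file.exists(newick)
  text <- if (is_path) paste(readLines(newick, warn = FALSE), collapse = "") else newick
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(
      sprintf("Malformed newick: %s", conditionMessage(e)),
      class = "phylospace_parse_error"
    )
  )
  if (is.null(tree)) {
    # ape returns NULL (with a warning) on some malformed inputs
    pos <- regexpr("[^();,[:alnum:]_.:' -]", text)
    abort(
      sprintf("Malformed newick near position %d: %s",
              if (pos > 0) pos else nchar(text), substr(text, 1, 60)),
      class = "phylospace_parse_error"
    )
  }
  validate_ultrametric_tree(tree, tol = tol, strict = strict)
}

#' Validate a phylo object as an ultrametric tree
#'
#' @param tree An [ape::phylo] object.
#' @inheritParams read_ultrametric_tree
#' @return The tree, with `root_age` attribute set.
#' @export
validate_ultrametric_tree <- function(tree, tol = 1e-6, strict = FALSE) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be an ape 'phylo' object.", class = "phylospace_validation_error")
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("Every edge must carry a branch length.",
          class = "phylospace_validation_error")
  }
  if (any(tree$edge.length < 0)) {
    abort("Negative branch lengths are not allowed.",
          class = "phylospace_validation_error")
  }
  labs <- tree$tip.label
  if (anyDuplicated(labs)) {
    abort(
      sprintf("Duplicate leaf label(s): %s",
              paste(unique(labs[duplicated(labs)]), collapse = ", ")),
      class = "phylospace_validation_error"
    )
  }
  if (any(!nzchar(labs))) {
    abort("Empty leaf labels are not allowed.", class = "phylospace_validation_error")
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(labs)]
  root_age <- max(depths)
  spread <- (root_age - min(depths)) / max(root_age, .Machine$double.eps)
  if (spread > tol) {
    msg <- sprintf(
      "Tree is not ultrametric: root-to-tip depths span %.6g to %.6g (relative spread %.3g > %g).",
      min(depths), root_age, spread, tol
    )
    if (strict) abort(msg, class = "phylospace_validation_error")
    warn(msg, class = "phylospace_ultrametric_warning")
  }
  attr(tree, "root_age") <- root_age
  tree
}

#' Root age of a validated tree
#'
#' @param tree A tree from [read_ultrametric_tree()] or any `phylo`.
#' @return Maximum root-to-tip depth (Ma).
#' @export
root_age <- function(tree) {
  attr(tree, "root_age") %||%
    max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

# Edge-by-tip incidence: inc[e, i] is TRUE when edge e lies on the path
# from the root to tip i. Patristic distances and PD both reduce to sums
# over this matrix.
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  edge_of <- integer(nnode) # edge index whose child is the node
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  inc <- matrix(FALSE, nrow = nrow(tree$edge), ncol = ntip,
                dimnames = list(NULL, tree$tip.label))
  for (i in seq_len(ntip)) {
    node <- i
    while (node != root) {
      inc[edge_of[node], i] <- TRUE
      node <- parent[node]
    }
  }
  inc
}

# Resolve requested species names against tree tips, optionally falling
# back to a genus-level tip (for genus-exemplar trees). Returns the tip
# label standing for each name; errors listing unresolved names.
match_tree_labels <- function(species, tree, genus = NULL) {
  tips <- tree$tip.label
  out <- ifelse(species %in% tips, species, NA_character_)
  if (!is.null(genus)) {
    stopifnot(length(genus) == length(species))
    miss <- is.na(out) & !is.na(genus) & genus %in% tips
    out[miss] <- genus[miss]
  }
  if (anyNA(out)) {
    abort(
      sprintf("Species not found in tree: %s",
              paste(unique(species[is.na(out)]), collapse = ", ")),
      class = "phylospace_lookup_error"
    )
  }
  stats::setNames(out, species)
}

#' Patristic distance matrix for a set of species
#'
#' Entry (i, j) is the sum of branch lengths along the tree path between
#' the tips standing for species i and j, in the tree's branch-length
#' units (Ma for a dated tree). On a genus-exemplar tree, species can fall
#' back to their genus tip via `genus`; congeneric species then have
#' patristic distance zero.
#'
#' @param tree Tree from [read_ultrametric_tree()].
#' @param species Character vector of species names (defaults to all tips).
#' @param genus Optional character vector, same length as `species`, of
#'   genus names used as fallback tips.
#' @return Symmetric numeric matrix with `species` as dimnames.
#' @examples
#' tr <- read_ultrametric_tree("((A:1,B:1):1,C:2);")
#' patristic_matrix(tr)
#' @export
patristic_matrix <- function(tree, species = tree$tip.label, genus = NULL) {
  stopifnot(is.character(species), length(species) >= 1)
  if (anyDuplicated(species)) {
    abort("`species` must not contain duplicates.", class = "phylospace_validation_error")
  }
  labels <- match_tree_labels(species, tree, genus)
  inc <- edge_tip_incidence(tree)[, labels, drop = FALSE]
  len <- tree$edge.length
  depths <- colSums(inc * len)
  shared <- crossprod(inc * sqrt(len)) # shared root-path length per pair
  d <- outer(depths, depths, `+`) - 2 * shared
  d[d < 0] <- 0 # guard tiny negative round-off
  diag(d) <- 0
  dimnames(d) <- list(species, species)
  d
}

#' Faith's phylogenetic diversity of a species set
#'
#' Total branch length of the minimal subtree spanning the species set, in
#' Ma. By default the subtree includes the path to the root (the Phylocom
#' `pd` convention); `rooted = FALSE` restricts it to the subtree spanning
#' the set's most recent common ancestor, in which case a single species
#' has PD 0.
#'
#' @inheritParams patristic_matrix
#' @param species Character vector (treated as a set) of species names.
#' @param rooted Include the root path (default TRUE).
#' @return Phylogenetic diversity in branch-length units (Ma).
#' @examples
#' tr <- read_ultrametric_tree("((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B"))      # 3
#' faith_pd(tr, c("A", "B", "C")) # 5, the total branch length
#' @export
faith_pd <- function(tree, species, genus = NULL, rooted = TRUE) {
  if (length(species) == 0) {
    abort("`species` must be a non-empty set.", class = "phylospace_domain_error")
  }
  labels <- unique(unname(match_tree_labels(unique(species), tree, genus)))
  inc <- edge_tip_incidence(tree)
  on_path <- rowSums(inc[, labels, drop = FALSE]) > 0
  if (!rooted) {
    # drop edges ancestral to the set's MRCA: edges covering every member
    covers_all <- rowSums(inc[, labels, drop = FALSE]) == length(labels)
    if (length(labels) == 1) return(0)
    on_path <- on_path & !covers_all
  }
  sum(tree$edge.length[on_path])
}
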