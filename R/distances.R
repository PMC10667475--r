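#' Validate a pairwise species-distance matrix
#'
#' Distances must be square, symmetric, non-negative, with a zero diagonal and
#' species labels as dimnames. Used internally by every estimator that takes a
#' distance matrix.
#'
#' @param d Numeric matrix.
#' @return The matrix, invisibly unchanged, after validation.
#' @export
as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    abort("distance matrix needs species labels as dimnames")
  }
  if (!identical(rownames(d), colnames(d))) abort("row and column labels differ")
  if (anyNA(d) || any(d < 0)) abort("distances must be non-negative and non-missing")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix diagonal must be zero")
  if (max(abs(d - t(d))) > 1e-9) abort("distance matrix must be symmetric")
  d
}

#' The 0/1 (identity) species-distance matrix
#'
#' All distinct species are at distance one, each species at distance zero
#' from itself. Rao's quadratic diversity computed with this matrix equals the
#' Gini-Simpson index, which is how the two index families connect.
#'
#' @param species Character vector of species labels, or a single species
#'   count (labels are then generated).
#' @return An S x S matrix with zero diagonal and unit off-diagonal.
#' @export
#' @examples
#' identity_distances(c("a", "b"))
identity_distances <- function(species) {
  if (is.numeric(species) && length(species) == 1L) {
    if (species < 1) abort("need at least one species")
    species <- sprintf("sp%02d", seq_len(species))
  }
  species <- as.character(species)
  s <- length(species)
  d <- matrix(1, s, s, dimnames = list(species, species))
  diag(d) <- 0
  d
}

#' Taxonomic path distances from a rank table
#'
#' Given a table assigning each species to nested taxonomic ranks (columns
#' ordered from the lowest rank above species to the highest, e.g. `genus`,
#' `family`, `order`), the distance between two species is the sum of equal
#' per-linkage weights along *both* species' paths up to their lowest common
#' taxonomic unit. Two congeners are two linkages apart (one step up on each
#' side); two species sharing only a family are four linkages apart, and so
#' on. Species sharing no listed rank are joined through an implicit root one
#' level above the highest column.
#'
#' @param hierarchy Data frame with a `species` column followed by rank
#'   columns ordered lowest to highest.
#' @param weight Positive weight per classification linkage (default 20).
#' @return A symmetric distance matrix over the table's species.
#' @export
#' @examples
#' h <- data.frame(species = c("a", "b", "c"),
#'                 genus = c("G1", "G1", "G2"),
#'                 family = c("F", "F", "F"))
#' taxonomic_distances(h)   # a-b: 40, a-c: 80
taxonomic_distances <- function(hierarchy, weight = 20) {
  h <- as_tibble(hierarchy)
  if (!"species" %in% names(h)) abort("hierarchy needs a `species` column")
  if (!is.numeric(weight) || weight <= 0) abort("weight must be positive")
  ranks <- setdiff(names(h), "species")
  if (length(ranks) == 0L) abort("hierarchy needs at least one rank column")
  if (anyDuplicated(h$species)) abort("duplicate species in hierarchy")
  if (anyNA(h[ranks])) abort("every species needs a complete rank path")
  sp <- as.character(h$species)
  s <- length(sp)
  d <- matrix(0, s, s, dimnames = list(sp, sp))
  rk <- as.matrix(h[ranks])
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      if (i == j) next
      shared <- which(rk[i, ] == rk[j, ])
      k <- if (length(shared) > 0L) min(shared) else length(ranks) + 1L
      # k linkages climbed on each of the two paths to the common unit
      d[i, j] <- 2 * weight * k
    }
  }
  d
}

#' Patristic distances from a phylogenetic tree
#'
#' Tip-to-tip path-length distances (sums of branch lengths) computed from a
#' Newick tree or an [ape::phylo] object.
#'
#' @param tree An `ape::phylo` object, a Newick string, or a path to a Newick
#'   file.
#' @return A symmetric distance matrix over the tree's tips.
#' @export
#' @examples
#' patristic_distances("((A:1,B:1):1,C:2);")
patristic_distances <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) abort("cannot interpret `tree` as a phylogeny")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  d <- ape::cophenetic.phylo(tree)
  as_dist_matrix(d[tree$tip.label, tree$tip.label])
}

#' Read a square distance matrix from CSV
#'
#' Expects species ids as both the header row and the first column.
#'
#' @param path Path to the CSV file.
#' @return A validated distance matrix.
#' @export
load_distances <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  as_dist_matrix(m)
}

# aligns a distance matrix to a species order, erroring on mismatch
align_distances <- function(d, species) {
  d <- as_dist_matrix(d)
  missing <- setdiff(species, rownames(d))
  if (length(missing) > 0L) {
    abort(sprintf("distance matrix lacks species: %s",
                  paste(utils::head(missing, 5L), collapse = ", ")))
  }
  d[species, species, drop = FALSE]
}
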