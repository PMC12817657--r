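#' Parse a Newick tree
#'
#' Reads a Newick string (or a file containing one) into an `ape` `"phylo"`
#' tree and validates it for use in a phylogenetic meta-analysis: single tree,
#' unique tip labels, nonnegative branch lengths.  Trees without branch
#' lengths are rejected unless `unit_length = TRUE`, in which case every edge
#' is assigned length 1 (a common fallback for topologies retrieved without
#' divergence-time estimates).
#'
#' @param text A Newick string ending in `;`, or the path of a file holding
#'   one (detected by existence on disk).
#' @param unit_length If `TRUE`, missing branch lengths are replaced by 1
#'   instead of raising an error.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((A:0.5,B:0.5):0.5,C:1);")
#' @export
parse_newick <- function(text, unit_length = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  tree <- tryCatch(
    {
      if (file.exists(text)) ape::read.tree(text) else ape::read.tree(text = text)
    },
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    tm_abort("Malformed Newick input (unbalanced parentheses or bad syntax).",
             "tm_error_newick")
  }
  if (anyDuplicated(tree$tip.label)) {
    tm_abort("Duplicate tip labels in tree.", "tm_error_newick")
  }
  if (is.null(tree$edge.length)) {
    if (!unit_length) {
      tm_abort(
        "Tree has no branch lengths; pass unit_length = TRUE to assume unit edges.",
        "tm_error_newick"
      )
    }
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0)) {
    tm_abort("Negative or missing branch lengths in tree.", "tm_error_newick")
  }
  tree
}

#' Write a tree as a Newick string
#'
#' @param tree A `"phylo"` tree.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Species-level phylogenetic correlation matrix
#'
#' Builds the species-by-species correlation matrix used to structure the
#' phylogenetic random effect: under a Brownian-motion model the covariance of
#' two tips is the root-to-MRCA shared path length, and the correlation is
#' `C_ij = shared_ij / sqrt(depth_i * depth_j)`.  For ultrametric trees this
#' reduces to shared length over tree depth.  The result is symmetric with
#' unit diagonal and is checked to be positive semi-definite.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @param species Ordered character vector of tip labels to include (default
#'   all tips, in tree order).  Row/column order of the result follows it.
#' @return A correlation matrix with `dimnames` equal to `species`.
#' @examples
#' tr <- parse_newick("((A:0.5,B:0.5):0.5,C:1);")
#' phylo_correlation(tr) # C_AB = 0.5
#' @export
phylo_correlation <- function(tree, species = tree$tip.label) {
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp)) {
    tm_abort(
      paste0("Species not in tree: ", paste(missing_sp, collapse = ", ")),
      "tm_error_species"
    )
  }
  vc <- ape::vcv(tree)
  depths <- diag(vc)
  if (any(depths[species] <= 0)) {
    tm_abort("Zero root-to-tip depth for a requested species.", "tm_error_species")
  }
  corr <- vc / sqrt(outer(depths, depths))
  corr <- symmetrise(corr[species, species, drop = FALSE])
  diag(corr) <- 1
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    tm_abort("Phylogenetic correlation matrix is not positive semi-definite.",
             "tm_error_psd")
  }
  corr
}

#' Expand a species correlation matrix to effect-size rows
#'
#' Maps the species-by-species correlation matrix onto the rows of the
#' analysis table: `R_ij = C[species_i, species_j]`.  Because `R` is a
#' selection (with repetition) of a positive semi-definite matrix it is itself
#' positive semi-definite.
#'
#' @param corr Species correlation matrix with dimnames (from
#'   [phylo_correlation()]).
#' @param species Character vector giving each row's species.
#' @return A length(species) square correlation matrix.
#' @export
expand_phylo <- function(corr, species) {
  unknown <- setdiff(unique(species), rownames(corr))
  if (length(unknown)) {
    tm_abort(
      paste0("Species missing from correlation matrix: ",
             paste(unknown, collapse = ", ")),
      "tm_error_species"
    )
  }
  out <- corr[species, species, drop = FALSE]
  dimnames(out) <- list(species, species)
  out
}
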