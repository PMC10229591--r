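# Simpson (turnover-only) beta diversity, taxonomic and phylogenetic.
#
# The Simpson index 1 - a/(a + min(b, c)) measures compositional turnover
# between two assemblages from their shared (a) and unique (b, c) components.
# In taxonomic mode a, b, c count genera; in phylogenetic mode they sum branch
# lengths of the phylogeny spanned by each assemblage. Because the index
# divides by a + min(b, c) it ignores richness differences and pure
# nestedness: an assemblage whose genera (or branches) are a subset of
# another's has zero turnover against it.

#' Simpson dissimilarity from shared/unique components
#'
#' @param comp a `beta_components` object (or any list with numeric fields
#'   `a`, `b`, `c`), as returned by [taxonomic_components()] or
#'   [phylogenetic_components()].
#' @return dissimilarity in \[0, 1\].
#' @examples
#' simpson(beta_components(a = 2, b = 1, c = 3))  # 1 - 2/3
#' @export
simpson <- function(comp) {
  a <- comp$a; b <- comp$b; cc <- comp$c
  if (any(c(a, b, cc) < 0)) fr_stop("fr_invalid_parameter", "components must be nonnegative")
  denom <- a + min(b, cc)
  if (denom <= 0)
    fr_stop("fr_undefined_beta",
            "Simpson beta undefined: a + min(b, c) = 0 (empty assemblage?)")
  1 - a / denom
}

#' Construct a beta-components triple
#'
#' @param a shared richness or shared branch length.
#' @param b,c components unique to the first and second assemblage.
#' @export
beta_components <- function(a, b, c) {
  structure(list(a = a, b = b, c = c), class = "beta_components")
}

#' Shared and unique genus counts for a pair of GSUs
#'
#' @param occ binary occurrence matrix (genera in rows, GSUs in columns).
#' @param gsu1,gsu2 GSU ids (column names of `occ`).
#' @return a `beta_components` object with genus counts.
#' @export
taxonomic_components <- function(occ, gsu1, gsu2) {
  for (g in c(gsu1, gsu2))
    if (!g %in% colnames(occ)) fr_stop("fr_lookup_error", "unknown GSU id: %s", g)
  s1 <- rownames(occ)[occ[, gsu1] > 0]
  s2 <- rownames(occ)[occ[, gsu2] > 0]
  beta_components(a = length(intersect(s1, s2)),
                  b = length(setdiff(s1, s2)),
                  c = length(setdiff(s2, s1)))
}

# Edge-by-tip descendancy: for each edge of `tree`, which tips descend from
# its child end. Returned as a logical matrix (edges x tips) in edge order.
# The root carries no stem branch, so every edge in tree$edge is a real branch.
edge_tip_map <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  # postorder guarantees children are accumulated before their parent
  for (i in ape::postorder(tree)) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  desc[tree$edge[, 2], , drop = FALSE]
}

#' Shared and unique branch lengths for a pair of GSUs
#'
#' A branch is treated as present in a GSU when at least one of its descendant
#' tips occurs there; the root contributes no stem branch. This is the
#' deliberately plain per-pair path (an explicit loop over branches) used as
#' the independent cross-check for the vectorised [pairwise_beta()].
#'
#' @param tree dated ultrametric phylogeny (`phylo`), tips = genera.
#' @param occ binary occurrence matrix (genera x GSUs).
#' @param gsu1,gsu2 GSU ids.
#' @return a `beta_components` object with branch lengths (same units as the
#'   tree's branch lengths).
#' @export
phylogenetic_components <- function(tree, occ, gsu1, gsu2) {
  for (g in c(gsu1, gsu2))
    if (!g %in% colnames(occ)) fr_stop("fr_lookup_error", "unknown GSU id: %s", g)
  missing <- setdiff(rownames(occ), tree$tip.label)
  if (length(missing))
    fr_stop("fr_consistency_error", "genus not on tree: %s", missing[1])
  tips1 <- rownames(occ)[occ[, gsu1] > 0]
  tips2 <- rownames(occ)[occ[, gsu2] > 0]
  if (!length(tips1) || !length(tips2))
    fr_stop("fr_undefined_beta", "empty assemblage in GSU pair (%s, %s)", gsu1, gsu2)
  dm <- edge_tip_map(tree)
  idx1 <- match(tips1, tree$tip.label)
  idx2 <- match(tips2, tree$tip.label)
  a <- b <- cc <- 0
  for (e in seq_len(nrow(tree$edge))) {
    in1 <- any(dm[e, idx1]); in2 <- any(dm[e, idx2])
    len <- tree$edge.length[e]
    if (in1 && in2) a <- a + len
    else if (in1) b <- b + len
    else if (in2) cc <- cc + len
  }
  beta_components(a = a, b = b, c = cc)
}

#' Pairwise Simpson beta-diversity matrix among GSUs
#'
#' Computes all n(n-1)/2 pairwise Simpson dissimilarities in one vectorised
#' pass: presence of every genus (taxonomic mode) or branch (phylogenetic
#' mode) is tabulated per GSU once, and shared components for all pairs follow
#' from a single cross-product.
#'
#' @param occ binary occurrence matrix (genera x GSUs).
#' @param tree dated phylogeny; required for `mode = "phylogenetic"`.
#' @param mode `"taxonomic"` or `"phylogenetic"`.
#' @return symmetric dissimilarity matrix with GSU dimnames, zero diagonal.
#' @export
pairwise_beta <- function(occ, tree = NULL, mode = c("phylogenetic", "taxonomic")) {
  mode <- match.arg(mode)
  check_occurrence(occ)
  if (mode == "phylogenetic") {
    if (is.null(tree))
      fr_stop("fr_invalid_parameter", "phylogenetic mode requires a tree")
    missing <- setdiff(rownames(occ), tree$tip.label)
    if (length(missing))
      fr_stop("fr_consistency_error", "genus not on tree: %s", missing[1])
    dm <- edge_tip_map(tree)                       # edges x tips
    # branch presence per GSU: edge present iff any descendant tip present;
    # tree tips absent from the matrix simply contribute nothing
    occ_t <- matrix(0, length(tree$tip.label), ncol(occ),
                    dimnames = list(tree$tip.label, colnames(occ)))
    occ_t[rownames(occ), ] <- occ
    pres <- (dm %*% occ_t) > 0                     # edges x GSUs, logical
    w <- tree$edge.length
  } else {
    pres <- occ > 0                                # genera x GSUs
    w <- rep(1, nrow(occ))
  }
  storage.mode(pres) <- "numeric"
  shared <- crossprod(pres, pres * w)              # a_ij
  tot <- diag(shared)                              # total length/richness per GSU
  if (any(tot <= 0))
    fr_stop("fr_undefined_beta", "GSU with zero total branch length/richness: %s",
            colnames(occ)[which(tot <= 0)[1]])
  b <- outer(tot, rep(1, length(tot))) - shared    # unique to row GSU
  cc <- t(b)
  beta <- 1 - shared / (shared + pmin(b, cc))
  undef <- (shared + pmin(b, cc)) <= 0
  if (any(undef & upper.tri(undef))) {
    ij <- which(undef & upper.tri(undef), arr.ind = TRUE)[1, ]
    fr_stop("fr_undefined_beta", "Simpson beta undefined for GSU pair (%s, %s)",
            colnames(occ)[ij[1]], colnames(occ)[ij[2]])
  }
  diag(beta) <- 0
  beta[beta < 0] <- 0  # guard against -1e-17 style round-off
  dimnames(beta) <- list(colnames(occ), colnames(occ))
  beta
}
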