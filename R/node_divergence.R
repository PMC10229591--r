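# Node-based distributional divergence: for each internal node, how strongly
# the geographic ranges of its two descendant clades mismatch (GND, in
# [0, 1]), which sites each clade dominates (SOS, a per-GSU standardized
# score against a clade-label randomization null), and how well a node's SOS
# pattern separates a given realm pair (one-way ANOVA R-squared).

#' Per-GSU occupancy counts of a node's two descendant clades
#'
#' Polytomies are reduced to the two largest children (logged); the
#' remaining children are ignored for this node.
#'
#' @param tree dated phylogeny.
#' @param occ binary occurrence matrix (genera x GSUs).
#' @param node internal node id (ape numbering).
#' @return list with `gsus` (ids where >= 1 node tip occurs), `count_a`,
#'   `count_b` (tip counts per GSU), `tips_a`, `tips_b`.
#' @export
node_occupancy <- function(tree, occ, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip || node > ntip + tree$Nnode)
    fr_stop("fr_invalid_parameter", "node %d is not internal", node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  tipset <- function(ch) {
    if (ch <= ntip) tree$tip.label[ch]
    else tree$tip.label[phangorn_free_descendants(tree, ch)]
  }
  sets <- lapply(kids, tipset)
  if (length(sets) > 2) {
    ord <- order(-lengths(sets))
    fr_log("node %d is a polytomy; using its two largest children", node)
    sets <- sets[ord[1:2]]
  }
  tips_a <- intersect(sets[[1]], rownames(occ))
  tips_b <- intersect(sets[[2]], rownames(occ))
  if (!length(tips_a) && !length(tips_b))
    fr_stop("fr_empty_node", "no tip of node %d occurs in the matrix", node)
  count_a <- colSums(occ[tips_a, , drop = FALSE])
  count_b <- colSums(occ[tips_b, , drop = FALSE])
  keep <- (count_a + count_b) > 0
  list(gsus = colnames(occ)[keep], count_a = count_a[keep],
       count_b = count_b[keep], tips_a = tips_a, tips_b = tips_b)
}

#' Geographic node divergence score
#'
#' Simpson-type mismatch of the two descendant clades' occupied-GSU sets:
#' `1 - |intersection| / (|intersection| + min(|only A|, |only B|))`.
#' 0 for identical ranges, 1 for disjoint ranges. The metric slot is
#' pluggable: pass any function of the occupancy list returning a value in
#' \[0, 1\].
#'
#' @param occupancy a list from [node_occupancy()].
#' @param metric optional replacement metric function.
#' @return GND in \[0, 1\].
#' @export
gnd_score <- function(occupancy, metric = NULL) {
  if (!is.null(metric)) return(metric(occupancy))
  sa <- occupancy$gsus[occupancy$count_a > 0]
  sb <- occupancy$gsus[occupancy$count_b > 0]
  if (!length(sa) || !length(sb))
    fr_stop("fr_undefined_gnd", "a descendant clade occupies no GSU")
  a <- length(intersect(sa, sb))
  b <- length(setdiff(sa, sb)); cc <- length(setdiff(sb, sa))
  1 - a / (a + min(b, cc))
}

#' Specific overrepresentation scores per GSU
#'
#' The observed statistic per GSU is the count of clade-A tips present; the
#' null shuffles the A/B clade labels across the node's tips (preserving
#' clade sizes and every tip's range) `n_rand` times. SOS is the
#' standardized deviation (observed - null mean) / null SD; positive values
#' mark predominance of clade A, negative of clade B; a zero null SD yields
#' SOS 0.
#'
#' @param occupancy a list from [node_occupancy()].
#' @param occ the occurrence matrix the occupancy was computed from.
#' @param n_rand number of label randomizations (>= 20).
#' @param seed integer seed.
#' @return named numeric SOS per occupied GSU.
#' @export
sos_scores <- function(occupancy, occ, n_rand = 200, seed = 1) {
  if (n_rand < 20) fr_stop("fr_invalid_parameter", "n_rand must be >= 20")
  tips <- c(occupancy$tips_a, occupancy$tips_b)
  n_a <- length(occupancy$tips_a)
  M <- occ[tips, occupancy$gsus, drop = FALSE]
  obs <- colSums(M[seq_len(n_a), , drop = FALSE])
  null <- with_seed(substream_seed(seed, "sos"), {
    vapply(seq_len(n_rand), function(i) {
      pick <- sample(length(tips), n_a)
      colSums(M[pick, , drop = FALSE])
    }, numeric(ncol(M)))
  })
  if (ncol(M) == 1) null <- matrix(null, nrow = 1)
  mu <- rowMeans(null)
  sdv <- apply(null, 1, stats::sd)
  sos <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  stats::setNames(sos, occupancy$gsus)
}

#' Screen all internal nodes for high geographic divergence
#'
#' Scores every internal node whose two clades each occupy at least one GSU
#' and returns those with GND strictly above `threshold`, sorted by GND
#' descending, ties by node age descending.
#'
#' @param tree dated phylogeny.
#' @param occ binary occurrence matrix.
#' @param threshold GND cut-off (strict inequality).
#' @return data.frame `(node, age, gnd, n_tips_a, n_tips_b)`.
#' @export
high_divergence_nodes <- function(tree, occ, threshold = 0.65) {
  if (threshold < 0 || threshold > 1)
    fr_stop("fr_invalid_parameter", "threshold must be in [0, 1]")
  ntip <- length(tree$tip.label)
  ages <- tree_node_ages(tree)
  rows <- list()
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    occu <- tryCatch(node_occupancy(tree, occ, node),
                     fr_empty_node = function(e) NULL)
    if (is.null(occu)) next
    if (!any(occu$count_a > 0) || !any(occu$count_b > 0)) next
    g <- gnd_score(occu)
    rows[[length(rows) + 1]] <- data.frame(
      node = node, age = ages[node], gnd = g,
      n_tips_a = length(occu$tips_a), n_tips_b = length(occu$tips_b))
  }
  out <- do.call(rbind, rows)
  out <- out[out$gnd > threshold, , drop = FALSE]
  out[order(-out$gnd, -out$age), , drop = FALSE]
}

#' ANOVA R-squared of a node's SOS pattern across a realm pair
#'
#' One-way analysis of variance with the SOS scores as response and the two
#' realms as groups, over the GSUs of the two realms where SOS is defined:
#' R-squared = between-realm sum of squares / total sum of squares.
#' Constant SOS yields 0; fewer than 2 usable GSUs in either realm flags the
#' result as insufficient.
#'
#' @param sos named SOS vector (from [sos_scores()]).
#' @param partition named realm labels.
#' @param realm_pair length-2 vector of realm labels.
#' @return list `(r2, n, flag)`.
#' @export
clade_contribution <- function(sos, partition, realm_pair) {
  if (length(realm_pair) != 2)
    fr_stop("fr_invalid_parameter", "realm_pair must name exactly two realms")
  ids <- intersect(names(sos), names(partition))
  ids <- ids[partition[ids] %in% realm_pair]
  grp <- factor(partition[ids], levels = realm_pair)
  if (any(table(grp) < 2))
    return(list(r2 = NA_real_, n = length(ids), flag = "insufficient"))
  y <- sos[ids]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(list(r2 = 0, n = length(ids), flag = "constant_sos"))
  gm <- tapply(y, grp, mean)
  ssb <- sum(table(grp) * (gm - mean(y))^2)
  list(r2 = ssb / sst, n = length(ids), flag = "ok")
}

#' Full node-divergence screen with per-node realm-pair contributions
#'
#' Convenience wrapper: screens nodes with [high_divergence_nodes()],
#' computes SOS per retained node and the ANOVA contribution to the given
#' realm pair.
#'
#' @param tree,occ,partition as above.
#' @param realm_pair length-2 realm-label vector.
#' @param threshold GND screen threshold.
#' @param n_rand randomizations per node.
#' @param seed integer seed; each node's null is seeded by `seed + node`.
#' @return data.frame `(node, age, gnd, r2, n, flag)`.
#' @export
node_divergence <- function(tree, occ, partition, realm_pair, threshold = 0.65,
                            n_rand = 200, seed = 1) {
  hits <- high_divergence_nodes(tree, occ, threshold)
  if (is.null(hits) || !nrow(hits)) return(hits)
  res <- lapply(seq_len(nrow(hits)), function(i) {
    node <- hits$node[i]
    occu <- node_occupancy(tree, occ, node)
    sos <- sos_scores(occu, occ, n_rand = n_rand, seed = seed + node)
    cc <- clade_contribution(sos, partition, realm_pair)
    data.frame(node = node, age = hits$age[i], gnd = hits$gnd[i],
               r2 = cc$r2, n = cc$n, flag = cc$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
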