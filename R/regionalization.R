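# Delineation of nested floristic realms from a beta-diversity matrix:
# linkage evaluation (explained turnover + cophenetic correlation), UPGMA
# dendrogram cuts at explained-turnover thresholds, NMDS ordination, fuzzy
# memberships, silhouette hardness, and the genus boundary-confinement
# statistic.

LINKAGE_METHODS <- c(single = "single", complete = "complete",
                     average = "average", upgma = "average",
                     mcquitty = "mcquitty", wpgma = "mcquitty",
                     ward = "ward.D2", centroid = "centroid", median = "median")

resolve_linkage <- function(method) {
  m <- LINKAGE_METHODS[tolower(method)]
  if (is.na(m)) fr_stop("fr_invalid_parameter", "unknown linkage method: %s", method)
  unname(m)
}

#' Proportion of beta diversity explained by a partition
#'
#' The sum of beta diversity over GSU pairs in different clusters divided by
#' the sum over all pairs. Equals 0 for a single cluster and 1 when every
#' GSU is its own cluster.
#'
#' @param partition named integer/character vector of cluster labels.
#' @param beta symmetric beta matrix over the same GSUs.
#' @return fraction in \[0, 1\].
#' @export
p_beta <- function(partition, beta) {
  ids <- rownames(beta)
  if (length(ids) < 2) fr_stop("fr_undefined_beta", "P_beta needs at least 2 GSUs")
  part <- check_partition_covers(partition, ids)
  total <- sum(beta[ids, ids]) / 2
  if (total <= 0)
    fr_stop("fr_undefined_beta", "P_beta undefined: total beta diversity is zero")
  within <- 0
  for (cl in unique(part)) {
    sel <- ids[part == cl]
    if (length(sel) > 1) within <- within + sum(beta[sel, sel]) / 2
  }
  (total - within) / total
}

#' Hierarchical clustering of a beta matrix
#'
#' @param beta symmetric beta matrix.
#' @param method linkage name: one of single, complete, average (UPGMA),
#'   mcquitty (WPGMA), ward, centroid, median.
#' @return an `hclust` object with the GSU ids as labels.
#' @export
build_dendrogram <- function(beta, method = "average") {
  check_beta_matrix(beta)
  stats::hclust(stats::as.dist(beta), method = resolve_linkage(method))
}

#' Partition from the smallest nested cut reaching a P_beta threshold
#'
#' Scans the dendrogram's nested cut sequence k = 1..n and returns the
#' partition with the smallest k whose explained turnover reaches
#' `threshold`. If the matrix carries no turnover at all the single-cluster
#' partition is returned.
#'
#' @param dend an `hclust` from [build_dendrogram()].
#' @param beta the beta matrix the dendrogram was built from.
#' @param threshold P_beta threshold in \[0, 1\].
#' @return named integer partition with attributes `k` and `pbeta`.
#' @export
cut_at_pbeta <- function(dend, beta, threshold) {
  if (threshold < 0 || threshold > 1)
    fr_stop("fr_invalid_parameter", "threshold must be in [0, 1]")
  n <- length(dend$labels)
  if (sum(beta) == 0) {
    part <- as_partition(rep(1L, n), dend$labels)
    attr(part, "k") <- 1L; attr(part, "pbeta") <- 0
    return(part)
  }
  for (k in seq_len(n)) {
    part <- stats::cutree(dend, k = k)
    pb <- if (k == 1) 0 else p_beta(part, beta)
    if (pb >= threshold) {
      out <- as_partition(part, dend$labels)
      attr(out, "k") <- k; attr(out, "pbeta") <- pb
      return(out)
    }
  }
  # unreachable: all-singleton cut has P_beta = 1 >= any threshold <= 1
  fr_stop("fr_consistency_error", "no nested cut reached the threshold")
}

#' Compare linkage methods by performance and accuracy
#'
#' Performance: the minimum number of clusters at which the explained
#' turnover reaches `perf_threshold` (99% by default) along each
#' dendrogram's nested cuts -- fewer is better. Accuracy: the Pearson
#' cophenetic correlation between the input dissimilarities and each
#' dendrogram's cophenetic distances -- higher is better. The selected
#' method has the best performance, ties broken by accuracy.
#'
#' @param beta symmetric beta matrix.
#' @param methods linkage names to compare.
#' @param perf_threshold P_beta level for the performance scan.
#' @return data.frame `(method, min_k, cophenetic_cor, selected)`.
#' @export
evaluate_linkages <- function(beta,
                              methods = c("single", "complete", "average",
                                          "mcquitty", "ward", "centroid", "median"),
                              perf_threshold = 0.99) {
  if (length(methods) < 2)
    fr_stop("fr_invalid_parameter", "need at least 2 methods to compare")
  d <- stats::as.dist(beta)
  res <- lapply(methods, function(m) {
    dend <- build_dendrogram(beta, m)
    part <- cut_at_pbeta(dend, beta, perf_threshold)
    data.frame(method = m, min_k = attr(part, "k"),
               cophenetic_cor = stats::cor(d, stats::cophenetic(dend)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ord <- order(out$min_k, -out$cophenetic_cor)
  out$selected <- seq_len(nrow(out)) == ord[1]
  out
}

#' Nonmetric multidimensional scaling of a beta matrix
#'
#' Best (lowest Kruskal stress-1) of `n_starts` random-start monotone-
#' regression NMDS runs, via [vegan::metaMDS()]. Coordinates are centered at
#' the origin. A matrix with no variation yields a deterministic circular
#' layout with a warning.
#'
#' @param beta symmetric beta matrix (n >= 3).
#' @param dims embedding dimension.
#' @param n_starts random starts.
#' @param seed integer seed; fixed seed gives identical coordinates.
#' @return list with `points` (n x dims, GSU rownames) and `stress`.
#' @export
nmds_embed <- function(beta, dims = 2, n_starts = 100, seed = 1) {
  check_beta_matrix(beta)
  n <- nrow(beta)
  if (n < 3) fr_stop("fr_invalid_parameter", "NMDS needs at least 3 GSUs")
  d <- stats::as.dist(beta)
  if (stats::sd(d) < 1e-12) {
    fr_warn("fr_degenerate_configuration",
            "all dissimilarities equal; returning a deterministic circular layout")
    theta <- 2 * pi * (seq_len(n) - 1) / n
    pts <- cbind(cos(theta), sin(theta))[, seq_len(dims), drop = FALSE]
    pts <- scale(pts, scale = FALSE)
    rownames(pts) <- rownames(beta)
    return(list(points = pts, stress = NA_real_))
  }
  fit <- with_seed(substream_seed(seed, "nmds"), suppressWarnings(
    vegan::metaMDS(d, k = dims, try = n_starts, trymax = n_starts,
                   trace = 0, autotransform = FALSE, wascores = FALSE)
  ))
  pts <- scale(fit$points, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(beta)
  list(points = pts, stress = fit$stress)
}

#' Fuzzy c-means style memberships from a beta matrix
#'
#' Dissimilarity-based fuzzy clustering (the FANNY objective of
#' [cluster::fanny()]) applied directly to the beta matrix: each GSU receives
#' a membership likelihood in each of `k` clusters, rows summing to 1.
#'
#' @param beta symmetric beta matrix.
#' @param k number of clusters (2 <= k <= n).
#' @param fuzziness membership exponent (> 1).
#' @param seed integer seed (recorded; the optimizer is deterministic).
#' @return membership matrix (GSU x cluster) with attribute `fuzziness`.
#' @export
fuzzy_membership <- function(beta, k, fuzziness = 1.5, seed = 1) {
  check_beta_matrix(beta)
  n <- nrow(beta)
  if (k < 2 || k > n)
    fr_stop("fr_invalid_parameter", "k must be in [2, n]")
  if (fuzziness <= 1)
    fr_stop("fr_invalid_parameter", "fuzziness exponent must exceed 1")
  fit <- cluster::fanny(stats::as.dist(beta), k = k, memb.exp = fuzziness,
                        maxit = 2000, tol = 1e-10)
  mem <- fit$membership
  rownames(mem) <- rownames(beta)
  colnames(mem) <- seq_len(k)
  attr(mem, "fuzziness") <- fuzziness
  mem
}

#' Silhouette widths of a partition under a beta matrix
#'
#' Standard silhouette on the beta matrix as the distance; GSUs in singleton
#' clusters receive width 0.
#'
#' @param partition named cluster labels (k >= 2).
#' @param beta symmetric beta matrix.
#' @return named numeric vector of widths in \[-1, 1\].
#' @export
silhouette_widths <- function(partition, beta) {
  ids <- rownames(beta)
  part <- check_partition_covers(partition, ids)
  if (length(unique(part)) < 2)
    fr_stop("fr_undefined_beta", "silhouette undefined for a single cluster")
  if (length(unique(part)) == length(ids))   # all singletons: width 0 by convention
    return(stats::setNames(rep(0, length(ids)), ids))
  sil <- cluster::silhouette(as.integer(factor(part)), stats::as.dist(beta))
  stats::setNames(sil[, "sil_width"], ids)
}

#' Fraction of genera confined within single realm boundaries
#'
#' A genus is confined when every GSU it occupies carries the same realm
#' label.
#'
#' @param occ binary occurrence matrix (genera x GSUs).
#' @param partition named realm labels covering the GSUs of `occ`.
#' @return fraction in \[0, 1\].
#' @export
boundary_confinement <- function(occ, partition) {
  check_occurrence(occ)
  part <- check_partition_covers(partition, colnames(occ))
  confined <- apply(occ > 0, 1, function(pres) length(unique(part[pres])) == 1)
  mean(confined)
}

#' Delineate nested floristic realms from a beta matrix
#'
#' End-to-end regionalization: optional linkage selection (P_beta performance
#' at 99% + cophenetic accuracy), dendrogram construction, realm and
#' sub-realm cuts at the two P_beta thresholds, the two-cluster
#' (super-realm) cut, silhouette hardness of the realm partition, NMDS
#' ordination, and fuzzy memberships at the realm count.
#'
#' @param beta symmetric beta matrix among GSUs.
#' @param pbeta_realm,pbeta_subrealm explained-turnover thresholds for the
#'   realm and sub-realm cuts (`pbeta_realm < pbeta_subrealm`).
#' @param linkage `"auto"` to select by [evaluate_linkages()], or a linkage
#'   name.
#' @param nmds logical; run the ordination.
#' @param fuzzy logical; compute fuzzy memberships at the realm count.
#' @param fuzziness fuzzy membership exponent.
#' @param n_starts NMDS random starts.
#' @param seed integer seed.
#' @return a `regionalization` list: `method`, `dendrogram`, `realms`,
#'   `subrealms`, `super_realms`, `silhouette`, `nmds`, `membership`,
#'   `evaluation`.
#' @export
regionalize <- function(beta, pbeta_realm = 0.80, pbeta_subrealm = 0.95,
                        linkage = "auto", nmds = TRUE, fuzzy = TRUE,
                        fuzziness = 1.5, n_starts = 100, seed = 1) {
  check_beta_matrix(beta)
  if (pbeta_realm >= pbeta_subrealm)
    fr_stop("fr_invalid_parameter", "realm threshold must be below sub-realm threshold")
  evaluation <- NULL
  if (identical(linkage, "auto")) {
    evaluation <- evaluate_linkages(beta)
    linkage <- evaluation$method[evaluation$selected]
  }
  dend <- build_dendrogram(beta, linkage)
  realms <- cut_at_pbeta(dend, beta, pbeta_realm)
  subrealms <- cut_at_pbeta(dend, beta, pbeta_subrealm)
  super <- as_partition(stats::cutree(dend, k = min(2L, length(dend$labels))),
                        dend$labels)
  sil <- if (attr(realms, "k") >= 2) silhouette_widths(realms, beta) else NULL
  ord <- if (nmds && nrow(beta) >= 3)
    nmds_embed(beta, n_starts = n_starts, seed = seed) else NULL
  mem <- NULL
  if (fuzzy && attr(realms, "k") >= 2) {
    mem <- tryCatch(
      fuzzy_membership(beta, k = attr(realms, "k"), fuzziness = fuzziness,
                       seed = seed),
      error = function(e) {
        fr_log("fuzzy memberships unavailable for k = %d on %d GSUs: %s",
               attr(realms, "k"), nrow(beta), conditionMessage(e))
        NULL
      })
  }
  structure(list(method = linkage, dendrogram = dend, realms = realms,
                 subrealms = subrealms, super_realms = super,
                 silhouette = sil, nmds = ord, membership = mem,
                 evaluation = evaluation,
                 pbeta = c(realm = attr(realms, "pbeta"),
                           subrealm = attr(subrealms, "pbeta"))),
            class = "regionalization")
}

#' @export
print.regionalization <- function(x, ...) {
  cat("Floristic regionalization (", x$method, " linkage)\n", sep = "")
  cat("  realms:    ", attr(x$realms, "k"),
      sprintf(" (P_beta = %.3f)\n", x$pbeta[["realm"]]), sep = "")
  cat("  sub-realms:", attr(x$subrealms, "k"),
      sprintf(" (P_beta = %.3f)\n", x$pbeta[["subrealm"]]), sep = "")
  if (!is.null(x$silhouette))
    cat(sprintf("  mean silhouette width: %.3f\n", mean(x$silhouette)))
  invisible(x)
}
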