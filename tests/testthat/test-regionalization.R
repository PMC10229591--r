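# Explained turnover, dendrogram cutting, linkage evaluation, ordination,
# fuzzy memberships, silhouettes and the confinement statistic.

test_that("p_beta is the between-cluster share of total beta", {
  b <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  part <- stats::setNames(c(1, 1, 2), c("x", "y", "z"))
  expect_equal(p_beta(part, b), (0.6 + 0.8) / 1.6)
  expect_equal(p_beta(stats::setNames(c(1, 1, 1), c("x", "y", "z")), b), 0)
  expect_equal(p_beta(stats::setNames(1:3, c("x", "y", "z")), b), 1)

  bb <- block_beta(2, 2)
  part22 <- stats::setNames(c(1, 1, 2, 2), rownames(bb))
  expect_equal(p_beta(part22, bb), 1)
  expect_error(p_beta(part[1], b[1, 1, drop = FALSE]), class = "fr_undefined_beta")
})

test_that("dendrogram merge heights follow the linkage rules", {
  b <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  for (m in c("single", "complete", "average", "ward")) {
    dend <- build_dendrogram(b, m)
    expect_equal(dend$height[1], 0.1)  # unique minimum merges first
  }
  expect_equal(build_dendrogram(b, "average")$height[2], (0.9 + 0.9) / 2)
  expect_equal(build_dendrogram(b, "single")$height[2], 0.9)
  expect_error(build_dendrogram(b, "totally-made-up"),
               class = "fr_invalid_parameter")
})

test_that("cut_at_pbeta returns the smallest nested cut over the threshold", {
  bb <- block_beta(3, 3)
  dend <- build_dendrogram(bb, "average")
  expect_equal(attr(cut_at_pbeta(dend, bb, 0), "k"), 1L)
  cut <- cut_at_pbeta(dend, bb, 0.8)
  expect_equal(attr(cut, "k"), 2L)
  expect_equal(ari(cut, stats::setNames(rep(1:2, each = 3), rownames(bb))), 1)
})

test_that("P_beta is nondecreasing along the nested cuts of any dendrogram", {
  set.seed(31)
  for (rep in 1:20) {
    b <- rand_beta(15)
    dend <- build_dendrogram(b, "average")
    pb <- vapply(1:15, function(k) {
      part <- stats::setNames(stats::cutree(dend, k), dend$labels)
      if (k == 1) 0 else p_beta(part, b)
    }, 0)
    expect_true(all(diff(pb) >= -1e-12))
    expect_equal(pb[1], 0)
    expect_equal(pb[15], 1)
  }
})

test_that("linkage evaluation scans performance and cophenetic accuracy", {
  bb <- block_beta(3, 3)
  ev <- evaluate_linkages(bb, methods = c("single", "complete", "average"))
  expect_equal(ev$min_k, rep(2L, 3))  # an exact 2-block matrix is ultrametric
  expect_equal(ev$cophenetic_cor, rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(ev$selected), 1L)

  # reported min_k brackets the threshold along the chosen dendrogram
  set.seed(8)
  b <- rand_beta(12)
  ev2 <- evaluate_linkages(b, methods = c("average", "complete"))
  for (i in seq_len(nrow(ev2))) {
    dend <- build_dendrogram(b, ev2$method[i])
    k <- ev2$min_k[i]
    pb_k <- p_beta(stats::setNames(stats::cutree(dend, k), dend$labels), b)
    expect_gte(pb_k, 0.99)
    if (k > 1) {
      pb_k1 <- if (k - 1 == 1) 0 else
        p_beta(stats::setNames(stats::cutree(dend, k - 1), dend$labels), b)
      expect_lt(pb_k1, 0.99)
    }
  }
  expect_error(evaluate_linkages(bb, methods = "average"),
               class = "fr_invalid_parameter")
})

test_that("NMDS recovers embeddable configurations and is seed-stable", {
  set.seed(5)
  pts <- matrix(runif(12), 6, 2)
  d <- as.matrix(dist(pts))
  d <- d / max(d) * 0.9
  dimnames(d) <- list(letters[1:6], letters[1:6])
  ord <- nmds_embed(d, n_starts = 20, seed = 1)
  expect_lte(ord$stress, 0.01)
  expect_equal(colMeans(ord$points), c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(ord$points, nmds_embed(d, n_starts = 20, seed = 1)$points)

  # stress is invariant under reflection of the configuration
  refl <- ord$points %*% diag(c(-1, 1))
  st <- function(p) {
    dd <- dist(p)
    vegan::monoMDS(stats::as.dist(d), y = as.matrix(p), maxit = 0)$stress
  }
  expect_equal(st(ord$points), st(refl), tolerance = 1e-8)

  dg <- matrix(0.5, 4, 4); diag(dg) <- 0
  dimnames(dg) <- list(letters[1:4], letters[1:4])
  expect_warning(nmds_embed(dg, seed = 1), class = "fr_degenerate_configuration")
})

test_that("fuzzy memberships are sharp on separated blocks and normalized", {
  bb <- block_beta(3, 3)
  mem <- fuzzy_membership(bb, k = 2, fuzziness = 1.5, seed = 1)
  expect_equal(unname(rowSums(mem)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(apply(mem, 1, max) >= 0.99))
  hard <- apply(mem, 1, which.max)
  expect_equal(ari(stats::setNames(hard, rownames(bb)),
                   stats::setNames(rep(1:2, each = 3), rownames(bb))), 1)

  set.seed(2)
  b <- rand_beta(8)
  mem2 <- fuzzy_membership(b, k = 3, fuzziness = 1.4)
  expect_equal(unname(rowSums(mem2)), rep(1, 8), tolerance = 1e-9)
  expect_error(fuzzy_membership(bb, k = 10), class = "fr_invalid_parameter")
  expect_error(fuzzy_membership(bb, k = 1), class = "fr_invalid_parameter")
})

test_that("silhouette widths match the definitional brute force", {
  bb <- block_beta(3, 3)
  part <- stats::setNames(rep(1:2, each = 3), rownames(bb))
  expect_equal(unname(silhouette_widths(part, bb)), rep(1, 6))

  set.seed(13)
  b <- rand_beta(9)
  part <- stats::setNames(rep(1:3, each = 3), rownames(b))
  got <- silhouette_widths(part, b)
  for (i in rownames(b)) {
    own <- setdiff(names(part)[part == part[i]], i)
    a <- mean(b[i, own])
    bo <- min(vapply(setdiff(unique(part), part[i]), function(cl)
      mean(b[i, names(part)[part == cl]]), 0))
    expect_equal(unname(got[i]), (bo - a) / max(a, bo), tolerance = 1e-12)
  }
  expect_error(silhouette_widths(stats::setNames(rep(1, 9), rownames(b)), b),
               class = "fr_undefined_beta")
})

test_that("boundary confinement counts single-realm genera", {
  occ <- occ_from_list(list(u = c("A", "B", "C"), v = c("A", "C"), w = "B"))
  part <- stats::setNames(c(1, 1, 2), c("u", "v", "w"))
  # B spans realms 1 and 2; A and C stay in realm 1
  expect_equal(boundary_confinement(occ, part), 2 / 3)
  expect_equal(boundary_confinement(occ, stats::setNames(c(1, 1, 1), c("u", "v", "w"))), 1)
})

test_that("regionalize produces nested ranks and the two-cluster overview", {
  fl <- gen_flora(seed = 6)
  beta <- pairwise_beta(fl$occ, fl$tree, "phylogenetic")
  reg <- regionalize(beta, linkage = "average", nmds = FALSE, fuzzy = FALSE)
  expect_gte(reg$pbeta[["realm"]], 0.80)
  expect_gte(reg$pbeta[["subrealm"]], 0.95)
  # sub-realms nest within realms
  tab <- table(reg$subrealms, reg$realms[names(reg$subrealms)])
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(length(unique(reg$super_realms)), 2L)
  expect_error(regionalize(beta, pbeta_realm = 0.95, pbeta_subrealm = 0.8),
               class = "fr_invalid_parameter")
})
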