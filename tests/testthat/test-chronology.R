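# Tree slicing, assemblage collapsing, realm matching and the chronology.

test_that("slice_tree collapses branches crossing the depth", {
  tr <- toy_tree()
  sl0 <- slice_tree(tr, 0)
  expect_equal(sort(names(sl0$lineages)), c("A", "B", "C"))
  expect_equal(unname(sl0$tip_map[c("A", "B", "C")]), c("A", "B", "C"))

  sl <- slice_tree(tr, 1.5)  # AB stem spans [1,2]; C's branch spans [0,2]
  expect_equal(length(sl$lineages), 2L)
  sets <- lapply(sl$lineages, sort)
  expect_true(any(vapply(sets, identical, TRUE, c("A", "B"))))
  expect_true(any(vapply(sets, identical, TRUE, "C")))
  # the sliced tree is the truncated original: two tips, both 0.5 Ma long
  expect_equal(sort(sl$sliced_tree$edge.length), c(0.5, 0.5))

  expect_warning(slice_tree(tr, 3), class = "fr_slice_warning")
  expect_error(slice_tree(tr, -1), class = "fr_invalid_parameter")
})

test_that("lineage counts and collapsed support shrink with depth", {
  fl <- gen_flora(n_tips = 80, grid_dims = c(4, 4), seed = 9)
  prev_n <- Inf
  prev_cols <- NULL
  for (t in c(0, 10, 25, 50, 80)) {
    sl <- suppressWarnings(slice_tree(fl$tree, t))
    expect_lte(length(sl$lineages), prev_n)
    prev_n <- length(sl$lineages)
    occ_s <- slice_assemblages(fl$occ, sl$tip_map)
    expect_true(all(colSums(occ_s) <= length(sl$lineages)))
    if (!is.null(prev_cols))
      expect_true(all(colSums(occ_s) <= prev_cols))
    prev_cols <- colSums(occ_s)
  }
})

test_that("slice_assemblages applies the union rule", {
  occ <- occ_from_list(list(u = "B", v = c("A", "C")))
  tip_map <- stats::setNames(c("L1", "L1", "C"), c("A", "B", "C"))
  coll <- slice_assemblages(occ, tip_map)
  expect_equal(coll["L1", "u"], 1L)  # only B present, lineage {A,B} counts
  expect_equal(coll["C", "u"], 0L)
  expect_error(slice_assemblages(occ, tip_map[-1]), class = "fr_consistency_error")
  # identity at t = 0
  sl0 <- slice_tree(toy_tree(), 0)
  expect_equal(slice_assemblages(occ, sl0$tip_map), occ[, sort(colnames(occ))])
})

test_that("match_realms solves the assignment and flags ancestral clusters", {
  p <- stats::setNames(c(1, 1, 2, 2, 3, 3), paste0("g", 1:6))
  ident <- match_realms(p, p)
  expect_equal(unname(ident$map), c("1", "2", "3"))
  expect_equal(unname(ident$jaccard), rep(1, 3))

  perm <- stats::setNames(c(2, 2, 3, 3, 1, 1), paste0("g", 1:6))
  m <- match_realms(p, perm)
  expect_equal(unname(m$map[c("1", "2", "3")]), c("2", "3", "1"))

  # a slice merging two present realms: the union matches neither at >= 0.5
  merged <- stats::setNames(c(1, 1, 1, 1, 2, 2), paste0("g", 1:6))
  m2 <- match_realms(merged, p)
  expect_equal(unname(m2$map[["2"]]), "3")
  expect_equal(unname(m2$jaccard[["1"]]), 0.5)
  m3 <- match_realms(merged, p, min_jaccard = 0.6)
  expect_match(m3$map[["1"]], "^ancestral_")
})

test_that("chronology t=0 equals the present regionalization and realms merge back in time", {
  fl <- gen_flora(n_realms = 3, n_tips = 150, realm_splits = c(60, 30),
                  leakage = 0.001, seed = 4)
  ch <- suppressWarnings(suppressMessages(
    chronology_run(fl$tree, fl$occ, times = seq(0, 80, 20), run_nmds = FALSE)))
  expect_identical(ch$slices[["t0"]]$partition, ch$present)

  beta <- pairwise_beta(fl$occ, fl$tree, "phylogenetic")
  reg <- regionalize(beta, linkage = "average", nmds = FALSE, fuzzy = FALSE)
  expect_equal(ari(ch$present, reg$realms), 1)

  k_by_t <- vapply(ch$slices, function(sl) length(unique(sl$partition)), 1L)
  expect_lt(k_by_t[["t80"]], k_by_t[["t0"]])
  expect_equal(k_by_t[["t80"]], 1L)  # deeper than the crown: one realm
})

test_that("procrustes alignment is exact on self and rotated copies", {
  fl <- gen_flora(n_tips = 80, grid_dims = c(4, 4), seed = 3)
  ch <- suppressWarnings(suppressMessages(
    chronology_run(fl$tree, fl$occ, times = c(0, 20), run_nmds = TRUE,
                   n_starts = 10, seed = 3)))
  expect_lt(ch$slices[["t0"]]$procrustes_rmse, 1e-6)

  # rotating a configuration leaves nothing behind after alignment
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pts <- ch$slices[["t0"]]$nmds
  pr <- vegan::procrustes(pts, pts %*% R, symmetric = FALSE)
  expect_lt(pr$ss, 1e-18)
})

test_that("planted split times are recovered by the separation onset", {
  fl <- gen_flora(n_realms = 3, n_tips = 150, realm_splits = c(60, 30),
                  leakage = 0.001, seed = 11)
  ch <- suppressWarnings(suppressMessages(
    chronology_run(fl$tree, fl$occ, times = seq(0, 80, 10), run_nmds = FALSE)))
  r <- fl$world$realm_of_gsu
  g <- function(i) names(r)[r == i]
  expect_lte(abs(separation_time(ch, g(1), g(2)) - 60), 10)
  expect_lte(abs(separation_time(ch, g(2), g(3)) - 30), 10)
})
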