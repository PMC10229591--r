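# Synthetic-world generator: tree simulation, lattice worlds, planted
# occupancy, climate and paleo-landscape structure, determinism.

test_that("gen_tree rescales to the requested crown age and is deterministic", {
  tr <- gen_tree(2, 100, seed = 1)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(max(d), 100, tolerance = 1e-9)
  expect_equal(length(tr$tip.label), 2)

  tr50 <- gen_tree(50, 140, seed = 7)
  expect_equal(max(ape::node.depth.edgelength(tr50)), 140, tolerance = 1e-9)
  expect_true(ape::is.ultrametric(tr50, tol = 1e-9))

  expect_identical(ape::write.tree(gen_tree(20, 80, seed = 3)),
                   ape::write.tree(gen_tree(20, 80, seed = 3)))
  expect_false(identical(ape::write.tree(gen_tree(20, 80, seed = 3)),
                         ape::write.tree(gen_tree(20, 80, seed = 4))))
  expect_error(gen_tree(1, 10), class = "fr_invalid_parameter")
})

test_that("gen_world partitions the lattice into contiguous balanced blocks", {
  w <- gen_world(c(4, 4), 4)
  expect_equal(as.integer(table(w$realm_of_gsu)), rep(4L, 4))
  w2 <- gen_world(c(6, 1), 2)
  expect_equal(unname(w2$realm_of_gsu[order(w2$gsu_table$row)]),
               rep(1:2, each = 3))
  w3 <- gen_world(c(3, 3), 1)
  expect_equal(unname(unique(w3$realm_of_gsu)), 1L)
  expect_error(gen_world(c(2, 2), 5), class = "fr_invalid_parameter")
  # every realm block is an axis-aligned rectangle fully owned by its realm
  gt <- gen_world(c(6, 6), 4)$gsu_table
  for (r in 1:4) {
    sel <- gt[gt$true_realm == r, ]
    expect_equal(nrow(sel),
                 (diff(range(sel$row)) + 1L) * (diff(range(sel$col)) + 1L))
  }
})

test_that("gen_ranges plants confinement and block-structured beta", {
  w <- gen_world(c(4, 4), 2)
  tr <- gen_realm_tree(w, 40, realm_splits = 60, seed = 2)
  occ0 <- gen_ranges(tr, w, affinity = 0.9, leakage = 0, seed = 1)
  expect_equal(boundary_confinement(occ0, w$realm_of_gsu), 1)

  # between-realm beta exceeds within-realm beta (direct computation)
  w4 <- gen_world(c(6, 6), 4)
  tr4 <- gen_realm_tree(w4, 200, seed = 3)
  occ <- gen_ranges(tr4, w4, affinity = 0.8, leakage = 0.02, seed = 3)
  beta <- pairwise_beta(occ, tr4, "phylogenetic")
  r <- w4$realm_of_gsu[rownames(beta)]
  same <- outer(r, r, "==") & upper.tri(beta)
  diff_ <- outer(r, r, "!=") & upper.tri(beta)
  expect_gt(mean(beta[diff_]), mean(beta[same]))

  # determinism and occupancy invariants
  occ_b <- gen_ranges(tr4, w4, affinity = 0.8, leakage = 0.02, seed = 3)
  expect_identical(occ, occ_b)
  expect_true(all(rowSums(occ) > 0) && all(colSums(occ) > 0))
  expect_error(gen_ranges(tr4, w4, affinity = 0.5, leakage = 0.6),
               class = "fr_invalid_parameter")
})

test_that("gen_climate mixes latitude and realm structure as requested", {
  w <- gen_world(c(4, 4), 4)
  lat_only <- gen_climate(w, gradient_align = 0, noise_sd = 0, seed = 1)
  gt <- w$gsu_table
  same_lat <- which(abs(gt$lat - gt$lat[1]) < 1e-9)
  expect_equal(stats::sd(lat_only$mat_c[same_lat]), 0)

  realm_only <- gen_climate(w, gradient_align = 1, noise_sd = 0, seed = 1)
  for (r in 1:4)
    expect_equal(stats::sd(realm_only$mat_c[gt$true_realm == r]), 0)

  expect_identical(gen_climate(w, 0.5, 1, seed = 9), gen_climate(w, 0.5, 1, seed = 9))
})

test_that("gen_paleo opens ocean strips after splits and raises route costs", {
  w <- gen_world(c(4, 4), 2)
  tr <- gen_realm_tree(w, 40, realm_splits = 60, seed = 2)
  occ <- gen_ranges(tr, w, seed = 2)
  w$split_times <- attr(occ, "split_times")
  pa <- gen_paleo(w, times = seq(0, 80, 20), seed = 1, scenario = "isolation")
  expect_gt(sum(pa$surfaces[["t0"]]$mask == 0), 0)      # strip present today
  expect_equal(sum(pa$surfaces[["t80"]]$mask == 0), 0)  # one landmass at 80 Ma

  iso0 <- least_cost_isolation(pa$surfaces[["t0"]], w$gsu_table)
  iso80 <- least_cost_isolation(pa$surfaces[["t80"]], w$gsu_table)
  r <- w$realm_of_gsu
  p <- names(r)[r == 1][1]; q <- names(r)[r == 2][8]
  expect_gt(iso0[p, q], iso80[p, q])

  expect_error(gen_paleo(w, times = 0:10, seed = 1),
               class = "fr_invalid_parameter")  # split outside the window
})

test_that("one master seed reproduces the whole world", {
  f1 <- gen_flora(n_tips = 60, grid_dims = c(4, 4), seed = 17)
  f2 <- gen_flora(n_tips = 60, grid_dims = c(4, 4), seed = 17)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  expect_identical(f1$occ, f2$occ)
  expect_identical(f1$climate, f2$climate)
  f3 <- gen_flora(n_tips = 60, grid_dims = c(4, 4), seed = 18)
  expect_false(identical(f1$occ, f3$occ))
})
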