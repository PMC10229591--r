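# Readers and writers: strict validation, typed errors, and round trips.

test_that("newick reading validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_tree(f)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)

  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tr, f2)
  tr2 <- read_tree(f2)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE))

  writeLines("((A:1,A:1):1);", f)
  expect_error(read_tree(f), class = "fr_format_error")
  writeLines("((A:1,B:-1):1);", f)
  expect_error(read_tree(f), class = "fr_format_error")
  writeLines("not a newick at all", f)
  expect_error(read_tree(f), class = "fr_format_error")
})

test_that("occurrence reading collapses duplicates and intersects with the tree", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genus_id,gsu_id", "A,u", "A,u", "B,v"), f)
  expect_message(occ <- read_occurrences(f), "1 duplicate")
  expect_equal(sum(occ), 2)

  tr <- toy_tree()
  writeLines(c("genus_id,gsu_id", "A,u", "B,u", "Zzz,v"), f)
  expect_message(occ <- read_occurrences(f, tr), "dropped")
  expect_false("Zzz" %in% rownames(occ))
  expect_false("v" %in% colnames(occ))  # GSU emptied by the drop goes too

  writeLines("genus_id,gsu_id", f)
  expect_error(read_occurrences(f), class = "fr_format_error")
  writeLines(c("foo,bar", "A,u"), f)
  expect_error(read_occurrences(f), class = "fr_format_error")

  # round trip preserves the presence set exactly
  occ0 <- occ_from_list(list(u = c("A", "B"), v = c("B", "C")))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ0, f3)
  expect_identical(read_occurrences(f3), occ0)
})

test_that("cost surface directory reading pairs, validates and orders", {
  w <- gen_world(c(3, 3), 2)
  tr <- gen_realm_tree(w, 20, realm_splits = 50, seed = 1)
  occ <- gen_ranges(tr, w, seed = 1)
  w$split_times <- attr(occ, "split_times")
  pa <- gen_paleo(w, times = c(0, 30, 60), seed = 1)
  d <- withr::local_tempdir()
  write_cost_surfaces(pa$surfaces, d)
  ss <- read_cost_surfaces(d)
  expect_equal(vapply(ss, `[[`, 0, "time"), c(0, 30, 60))
  expect_equal(ss[[1]]$mask, pa$surfaces[[1]]$mask)

  # unpaired elevation grid
  file.remove(file.path(d, "paleo_30ma_elev.asc"))
  expect_error(read_cost_surfaces(d), class = "fr_format_error")

  # shape mismatch
  d2 <- withr::local_tempdir()
  s <- pa$surfaces[[1]]
  write_cost_surfaces(list(s), d2)
  bad <- s; bad$elev <- bad$elev[, -1]
  florealm:::write_asc(bad$elev, s$xll, s$yll, s$cellsize,
                       file.path(d2, "paleo_0ma_elev.asc"))
  expect_error(read_cost_surfaces(d2), class = "fr_format_error")

  # NODATA mask cells become ocean, with a log message
  d3 <- withr::local_tempdir()
  m <- s$mask; m[1, 1] <- NA
  florealm:::write_asc(m, s$xll, s$yll, s$cellsize,
                       file.path(d3, "paleo_0ma_mask.asc"))
  florealm:::write_asc(s$elev, s$xll, s$yll, s$cellsize,
                       file.path(d3, "paleo_0ma_elev.asc"))
  expect_message(ss3 <- read_cost_surfaces(d3), "NODATA")
  expect_equal(ss3[[1]]$mask[1, 1], 0)
})

test_that("regionalization writing validates nestedness and round-trips", {
  fl <- gen_flora(n_tips = 60, grid_dims = c(4, 4), seed = 4)
  beta <- pairwise_beta(fl$occ, fl$tree, "phylogenetic")
  reg <- regionalize(beta, nmds = FALSE, fuzzy = FALSE, linkage = "average")
  f <- file.path(withr::local_tempdir(), "reg.csv")
  write_regionalization(reg, fl$world$gsu_table, f)
  back <- read_regionalization(f)
  expect_equal(unname(back$realms), unname(reg$realms[fl$world$gsu_table$gsu_id]))
  expect_true(file.exists(sub("\\.csv$", ".geojson", f)))
  gj <- jsonlite::read_json(sub("\\.csv$", ".geojson", f))
  expect_equal(length(gj$features), nrow(fl$world$gsu_table))

  # nestedness violation is rejected before writing
  broken <- reg
  ids <- names(broken$subrealms)
  broken$subrealms[ids] <- rep_len(1:2, length(ids))  # sub-realms now span realms
  expect_error(write_regionalization(broken, fl$world$gsu_table, f),
               class = "fr_consistency_error")

  # unassigned GSU is rejected
  short <- reg
  short$realms <- reg$realms[-1]
  expect_error(write_regionalization(short, fl$world$gsu_table, f),
               class = "fr_consistency_error")
})

test_that("climate table validation catches structural errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_climate(data.frame(gsu_id = c("a", "b"), mat_c = c(10, 20),
                           map_mm = c(500, 900)), f)
  cl <- read_climate(f)
  expect_equal(cl$map_mm, c(500, 900))
  write.csv(data.frame(gsu_id = "a", mat_c = 1, map_mm = -5), f, row.names = FALSE)
  expect_error(read_climate(f), class = "fr_format_error")
})
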