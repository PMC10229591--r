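# Climate distances, OLS fits, least-cost isolation, hierarchical
# partitioning and the per-Ma driver series.

test_that("climate distance is the z-scored Euclidean norm", {
  cl <- data.frame(gsu_id = c("a", "b", "c"),
                   mat_c = c(10, 20, 10), map_mm = c(500, 900, 500))
  d <- climate_distance(cl)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  # a pair one (realized) SD apart in each standardized variable sits
  # sqrt(2) apart; on the raw scale the same holds for unit differences
  v <- c(0, 1, 2, 3)
  cl2 <- data.frame(gsu_id = c("a", "b", "c", "d"), mat_c = v, map_mm = 10 * v)
  got <- unname(climate_distance(cl2)["a", "b"])
  expect_equal(got, sqrt(2 * (1 / sd(v))^2))
  cl3 <- data.frame(gsu_id = c("a", "b"), mat_c = c(0, 1), map_mm = c(0, 1))
  expect_equal(unname(climate_distance(cl3, standardize = FALSE)["a", "b"]),
               sqrt(2))
  cl3 <- data.frame(gsu_id = c("a", "b"), mat_c = c(1, 1), map_mm = c(0, 10))
  expect_error(climate_distance(cl3), class = "fr_invalid_parameter")
  expect_equal(unname(climate_distance(cl3, standardize = FALSE)["a", "b"]), 10)
})

test_that("ols_r2 matches 1 - SSE/SST and handles the degenerate cases", {
  x <- 1:10
  expect_equal(ols_r2(2 * x + 1, x), 1)
  set.seed(20)
  y_orth <- unname(resid(lm(rnorm(6) ~ I(1:6))))  # constructed orthogonal
  expect_equal(ols_r2(y_orth, 1:6), 0, tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:5) {
    xx <- rnorm(30); yy <- rnorm(30)
    fit <- lm(yy ~ xx)
    expect_equal(ols_r2(yy, xx), summary(fit)$r.squared, tolerance = 1e-12)
  }
  expect_error(ols_r2(rnorm(5), rep(1, 5)), class = "fr_undefined_r2")
})

test_that("least-cost isolation follows great-circle x friction arithmetic", {
  flat <- structure(list(time = 0, mask = matrix(1, 1, 3),
                         elev = matrix(0, 1, 3), cellsize = 1, xll = 0,
                         yll = -0.5), class = "cost_surface")
  cent <- data.frame(gsu_id = c("a", "b", "c"), lon = c(0.5, 1.5, 2.5),
                     lat = c(0, 0, 0))
  iso <- least_cost_isolation(flat, cent, k_ocean = 10, k_elev = 0)
  expect_equal(iso["a", "c"], 2 * 111.195, tolerance = 1e-3)

  # hand Dijkstra with an ocean middle cell: both edges cost (1+10)/2 x length
  wet <- flat; wet$mask[1, 2] <- 0
  iso2 <- suppressMessages(least_cost_isolation(wet, cent, k_ocean = 10, k_elev = 0))
  expect_equal(iso2["a", "c"], 11 * 111.195, tolerance = 1e-2)

  # elevation friction raises land costs
  hil <- flat; hil$elev[] <- 2000
  iso3 <- least_cost_isolation(hil, cent, k_ocean = 10, k_elev = 1)
  expect_equal(iso3["a", "c"] / iso["a", "c"], 3, tolerance = 1e-6)
})

test_that("isolation matrices satisfy shortest-path metric properties", {
  fl <- gen_flora(n_tips = 60, grid_dims = c(4, 4), seed = 2)
  pa <- gen_paleo(fl$world, times = c(0, 50, 100), seed = 2)
  for (s in pa$surfaces) {
    iso <- least_cost_isolation(s, fl$world$gsu_table)
    expect_equal(iso, t(iso))
    expect_equal(unname(diag(iso)), rep(0, nrow(iso)))
    n <- nrow(iso)
    set.seed(3)
    for (rep in 1:30) {
      ijk <- sample(n, 3)
      expect_lte(iso[ijk[1], ijk[3]],
                 iso[ijk[1], ijk[2]] + iso[ijk[2], ijk[3]] + 1e-9)
    }
  }
})

test_that("hierarchical partitioning obeys its algebra", {
  set.seed(4)
  x1 <- rnorm(40); x2 <- rnorm(40)
  y <- x1 + rnorm(40, 0, 0.1)  # x2 is pure noise
  hp <- hpart_two(y, x1, x2)
  expect_gt(hp[["I1"]], 10 * max(hp[["I2"]], 1e-6))
  expect_equal(hp[["I1"]] + hp[["I2"]], hp[["r2_full"]], tolerance = 1e-12)

  expect_warning(hp2 <- hpart_two(y, x1, x1), class = "fr_collinear")
  expect_equal(hp2[["I1"]], hp2[["I2"]])
  expect_error(hpart_two(y, x1, rep(1, 40)), class = "fr_undefined_r2")
})

test_that("within/between climate fits flag degenerate realms", {
  fl <- gen_flora(n_tips = 80, grid_dims = c(4, 4), gradient_align = 1,
                  climate_noise_sd = 0, seed = 5)
  beta <- pairwise_beta(fl$occ, fl$tree, "phylogenetic")
  cd <- climate_distance(fl$climate)
  res <- within_between_r2(beta, fl$world$realm_of_gsu, cd)
  # realm climates collapse to points: every distance vector is constant,
  # within realms and across any realm pair alike
  expect_true(all(res$flag == "constant_predictor"))
  expect_true(all(is.na(res$r2)))

  # with a mixed gradient, within-realm climate does explain turnover
  fl2 <- gen_flora(n_tips = 80, grid_dims = c(4, 4), gradient_align = 0.5,
                   climate_noise_sd = 0.5, seed = 5)
  beta2 <- pairwise_beta(fl2$occ, fl2$tree, "phylogenetic")
  res2 <- within_between_r2(beta2, fl2$world$realm_of_gsu,
                            climate_distance(fl2$climate))
  expect_true(all(res2$flag[res2$scope == "within"] == "ok"))
  expect_true(all(res2$r2[res2$flag == "ok"] >= 0 & res2$r2[res2$flag == "ok"] <= 1))
})

test_that("driver series bins, SEs and degenerate paths behave", {
  dw <- gen_driver_world("isolation", n_tips = 80, grid_dims = c(4, 4),
                         times = seq(0, 100, 10), seed = 6)
  beta <- pairwise_beta(dw$occ, dw$tree, "phylogenetic")
  ds <- driver_series(beta, dw$world$realm_of_gsu, 1:2, 3:4, dw$iso,
                      dw$paleo$paleoclimate, dw$paleo$times, bin_width = 5)
  expect_equal(nrow(ds$per_step), 11)
  expect_true(all(ds$per_step$i_geo >= 0 & ds$per_step$i_clim >= 0))
  expect_equal(ds$per_step$i_geo + ds$per_step$i_clim, ds$per_step$r2_full,
               tolerance = 1e-9)
  # one step per 5-Ma bin on a 10-Ma grid: SE of a single value is 0
  expect_true(all(ds$per_bin$i_geo_se == 0))
  expect_true(all(abs(ds$per_step$r_predictors) <= 1))

  # identical predictors exercise the collinearity path, r = 1
  ds2 <- suppressWarnings(
    driver_series(beta, dw$world$realm_of_gsu, 1:2, 3:4, dw$iso,
                  dw$paleo$paleoclimate, dw$paleo$times))
  expect_error(
    driver_series(beta, dw$world$realm_of_gsu, 1:2, 3:4, dw$iso[-1],
                  dw$paleo$paleoclimate, dw$paleo$times),
    class = "fr_consistency_error")
})
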