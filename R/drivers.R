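# Drivers of realm divergence: contemporary climate versus phylogenetic
# turnover (within/between-realm OLS fits), least-cost geographic isolation
# over time-stamped paleo-landscapes, and the per-Ma hierarchical
# partitioning of ln(beta) ~ ln(climate isolation) + ln(geographic
# isolation) into independent effects.

#' Pairwise climate distances among GSUs
#'
#' Euclidean distance in the two-dimensional (annual mean temperature,
#' annual precipitation) climate space, with variables z-scored first by
#' default (degrees C and mm are incommensurable).
#'
#' @param climate data.frame `(gsu_id, mat_c, map_mm)`.
#' @param standardize z-score the two variables before the norm.
#' @return symmetric distance matrix with GSU dimnames.
#' @export
climate_distance <- function(climate, standardize = TRUE) {
  need <- c("gsu_id", "mat_c", "map_mm")
  if (!all(need %in% names(climate)))
    fr_stop("fr_format_error", "climate table needs columns gsu_id, mat_c, map_mm")
  x <- as.matrix(climate[, c("mat_c", "map_mm")])
  rownames(x) <- climate$gsu_id
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      fr_stop("fr_invalid_parameter",
              "zero-variance climate variable; cannot standardize")
    x <- scale(x)
  }
  as.matrix(stats::dist(x))
}

#' Coefficient of determination of a simple least-squares fit
#'
#' @param response,predictor aligned numeric vectors (>= 3 values).
#' @return R-squared in \[0, 1\].
#' @export
ols_r2 <- function(response, predictor) {
  if (length(response) != length(predictor) || length(response) < 3)
    fr_stop("fr_invalid_parameter", "need >= 3 aligned observations")
  if (stats::sd(predictor) == 0)
    fr_stop("fr_undefined_r2", "constant predictor: R2 undefined")
  fit <- stats::lm.fit(cbind(1, predictor), response)
  sst <- sum((response - mean(response))^2)
  if (sst == 0) return(0)
  max(0, min(1, 1 - sum(fit$residuals^2) / sst))
}

# multiple-regression R2 (two predictors), shared by hpart_two
ols_r2_multi <- function(response, X) {
  fit <- stats::lm.fit(cbind(1, X), response)
  sst <- sum((response - mean(response))^2)
  if (sst == 0) return(0)
  max(0, min(1, 1 - sum(fit$residuals^2) / sst))
}

#' Climate explanatory power within and between realms
#'
#' OLS fits of beta diversity against climate distance, separately over
#' pairs inside each realm and over the cross pairs of each realm pair (or
#' of supplied realm groupings). Realms with fewer than `min_pairs`
#' internal pairs, or constant climate distances, are flagged rather than
#' fitted.
#'
#' @param beta symmetric beta matrix.
#' @param partition named realm labels over the GSUs.
#' @param climdist symmetric climate distance matrix (same GSUs).
#' @param groups optional named list of realm-label vectors; each pair of
#'   groups is fitted over its pooled cross pairs in place of raw realm
#'   pairs.
#' @param min_pairs minimum number of pairs for a fit.
#' @return data.frame `(scope, unit, r2, n_pairs, flag)`.
#' @export
within_between_r2 <- function(beta, partition, climdist, groups = NULL,
                              min_pairs = 3) {
  ids <- rownames(beta)
  part <- check_partition_covers(partition, ids)
  climdist <- climdist[ids, ids]

  pair_vectors <- function(set1, set2 = NULL) {
    if (is.null(set2)) {
      sel <- ids[part %in% set1]
      if (length(sel) < 2) return(NULL)
      ut <- upper.tri(matrix(0, length(sel), length(sel)))
      list(beta = beta[sel, sel][ut], clim = climdist[sel, sel][ut])
    } else {
      s1 <- ids[part %in% set1]; s2 <- ids[part %in% set2]
      if (!length(s1) || !length(s2)) return(NULL)
      list(beta = as.vector(beta[s1, s2]), clim = as.vector(climdist[s1, s2]))
    }
  }

  fit_row <- function(scope, unit, v) {
    if (is.null(v) || length(v$beta) < min_pairs)
      return(data.frame(scope = scope, unit = unit, r2 = NA_real_,
                        n_pairs = if (is.null(v)) 0L else length(v$beta),
                        flag = "insufficient", stringsAsFactors = FALSE))
    if (stats::sd(v$clim) == 0)
      return(data.frame(scope = scope, unit = unit, r2 = NA_real_,
                        n_pairs = length(v$beta), flag = "constant_predictor",
                        stringsAsFactors = FALSE))
    data.frame(scope = scope, unit = unit, r2 = ols_r2(v$beta, v$clim),
               n_pairs = length(v$beta), flag = "ok", stringsAsFactors = FALSE)
  }

  realms <- sort(unique(part))
  rows <- lapply(realms, function(r) fit_row("within", as.character(r),
                                             pair_vectors(r)))
  if (is.null(groups)) groups <- stats::setNames(as.list(realms), realms)
  gn <- names(groups)
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i < j) {
      rows[[length(rows) + 1]] <- fit_row(
        "between", paste0(gn[i], "|", gn[j]),
        pair_vectors(groups[[i]], groups[[j]]))
    }
  }
  do.call(rbind, rows)
}

#' Least-cost geographic isolation among GSUs over a cost surface
#'
#' All-pairs shortest-path route costs (Dijkstra over the 8-neighbor cell
#' graph) among GSU centroids. Each move costs the great-circle length
#' between the two cell centers times the mean of the two cells' frictions:
#' land friction `1 + k_elev * elevation/1000 m`, ocean friction `k_ocean`
#' (`Inf` makes ocean impassable; unreachable pairs get `Inf` and are
#' flagged). Centroids falling on ocean cells are snapped to the nearest
#' land cell with a logged warning.
#'
#' @param surface a `cost_surface` (time stamp, land/ocean mask, elevation,
#'   cell size, origin).
#' @param centroids data.frame `(gsu_id, lon, lat)`.
#' @param k_ocean ocean friction multiplier.
#' @param k_elev elevation friction per km of altitude.
#' @return symmetric cost matrix (km-equivalents) with GSU dimnames and a
#'   `time` attribute; `Inf` entries mark disconnected pairs.
#' @export
least_cost_isolation <- function(surface, centroids, k_ocean = 10, k_elev = 1) {
  mask <- surface$mask; elev <- surface$elev
  R <- nrow(mask); C <- ncol(mask)
  cs <- surface$cellsize
  lon_c <- surface$xll + (seq_len(C) - 0.5) * cs
  lat_c <- surface$yll + (R - seq_len(R) + 0.5) * cs   # row 1 = north

  friction <- ifelse(mask > 0, 1 + k_elev * elev / 1000, k_ocean)
  passable <- is.finite(friction)

  cell_id <- function(r, c) (c - 1L) * R + r
  # 8-neighbor edges (4 unique directions, both orientations implied)
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  from <- to <- integer(0); w <- numeric(0)
  rc <- expand.grid(r = seq_len(R), c = seq_len(C))
  for (i in seq_len(nrow(offs))) {
    r2 <- rc$r + offs[i, 1]; c2 <- rc$c + offs[i, 2]
    ok <- r2 >= 1 & r2 <= R & c2 >= 1 & c2 <= C
    a <- cell_id(rc$r[ok], rc$c[ok]); b <- cell_id(r2[ok], c2[ok])
    keep <- passable[a] & passable[b]
    a <- a[keep]; b <- b[keep]
    if (!length(a)) next
    p1 <- cbind(lon_c[(a - 1L) %/% R + 1L], lat_c[(a - 1L) %% R + 1L])
    p2 <- cbind(lon_c[(b - 1L) %/% R + 1L], lat_c[(b - 1L) %% R + 1L])
    len <- gc_dist_km(p1, p2)
    from <- c(from, a); to <- c(to, b)
    w <- c(w, len * (friction[a] + friction[b]) / 2)
  }
  g <- igraph::make_empty_graph(n = R * C, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w

  # snap centroids to cells (nearest land cell if the cell is ocean)
  snap <- vapply(seq_len(nrow(centroids)), function(i) {
    col <- pmin(pmax(ceiling((centroids$lon[i] - surface$xll) / cs), 1L), C)
    row <- pmin(pmax(ceiling((surface$yll + R * cs - centroids$lat[i]) / cs), 1L), R)
    if (!passable[cell_id(row, col)] || mask[row, col] == 0) {
      land <- which(mask > 0 & is.finite(friction), arr.ind = TRUE)
      if (!nrow(land)) fr_stop("fr_invalid_parameter", "surface has no land cells")
      d2 <- (land[, 1] - row)^2 + (land[, 2] - col)^2
      j <- which.min(d2)
      fr_log("GSU %s centroid on ocean at %g Ma; snapped to nearest land cell",
             centroids$gsu_id[i], surface$time)
      row <- land[j, 1]; col <- land[j, 2]
    }
    as.integer(cell_id(row, col))
  }, 1L)

  usnap <- unique(snap)
  d0 <- igraph::distances(g, v = usnap, to = usnap, algorithm = "dijkstra")
  d <- d0[match(snap, usnap), match(snap, usnap), drop = FALSE]
  dimnames(d) <- list(centroids$gsu_id, centroids$gsu_id)
  if (any(is.infinite(d)))
    fr_warn("fr_disconnected", "disconnected GSU pairs at %g Ma: infinite cost",
            surface$time)
  attr(d, "time") <- surface$time
  d
}

#' Hierarchical partitioning of a two-predictor regression
#'
#' Decomposes the full-model R-squared into independent contributions of the
#' two predictors, averaged over both entry orders:
#' `I1 = (R2(x1) + R2(full) - R2(x2)) / 2`, symmetrically for `I2`; the two
#' always sum to the full-model R-squared. Collinear predictors split the
#' R-squared evenly with a warning.
#'
#' @param response,x1,x2 aligned numeric vectors (>= 4 observations).
#' @return named numeric `(I1, I2, r2_full)`.
#' @export
hpart_two <- function(response, x1, x2) {
  n <- length(response)
  if (length(x1) != n || length(x2) != n || n < 4)
    fr_stop("fr_invalid_parameter", "need >= 4 aligned observations")
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0)
    fr_stop("fr_undefined_r2", "constant predictor in hierarchical partitioning")
  if (abs(stats::cor(x1, x2)) > 1 - 1e-12) {
    rf <- ols_r2(response, x1)
    fr_warn("fr_collinear", "collinear predictors; splitting R2 evenly")
    return(c(I1 = rf / 2, I2 = rf / 2, r2_full = rf))
  }
  r1 <- ols_r2(response, x1)
  r2 <- ols_r2(response, x2)
  rf <- ols_r2_multi(response, cbind(x1, x2))
  I1 <- (r1 + rf - r2) / 2
  I2 <- (r2 + rf - r1) / 2
  stopifnot(abs(I1 + I2 - rf) < 1e-9)   # algebraic identity, asserted in-code
  c(I1 = I1, I2 = I2, r2_full = rf)
}

#' Time-resolved driver partitioning for a realm pair
#'
#' For every time step: restrict to the cross pairs between the two realm
#' groups, ln-transform present-day phylogenetic beta, climate isolation and
#' geographic isolation (each vector offset by 1e-6 of its positive maximum
#' before the log), record the Pearson correlation between the two
#' predictors, and partition the ln-ln regression R-squared into the
#' independent effects of climate and geography with [hpart_two()]. Steps
#' are then aggregated into `bin_width`-Ma bins as mean and SE (SD/sqrt(n)).
#'
#' @param beta present-day phylogenetic beta matrix.
#' @param partition named realm labels.
#' @param group1,group2 realm-label vectors defining the division under
#'   study.
#' @param iso_series list of isolation matrices (one per time step, from
#'   [least_cost_isolation()]), with `time` attributes.
#' @param clim_series list of paleoclimate data.frames
#'   `(gsu_id, mat_c, map_mm)` on the same time grid.
#' @param times numeric time stamps (Ma) of both series.
#' @param bin_width bin width in Ma.
#' @param standardize_climate z-score paleoclimate variables per step.
#' @return a `driver_series` list: `per_step` data.frame
#'   `(time, r_predictors, i_clim, i_geo, r2_full)` and `per_bin` data.frame
#'   of bin means and SEs.
#' @export
driver_series <- function(beta, partition, group1, group2, iso_series,
                          clim_series, times, bin_width = 5,
                          standardize_climate = TRUE) {
  if (length(iso_series) != length(times) || length(clim_series) != length(times))
    fr_stop("fr_consistency_error", "isolation/climate series misaligned with times")
  iso_t <- unname(vapply(iso_series, function(m) attr(m, "time") %||% NA_real_, 1))
  if (!all(is.na(iso_t)) && !isTRUE(all.equal(sort(iso_t), sort(unname(times)))))
    fr_stop("fr_consistency_error", "isolation series time stamps do not match times")
  ids <- rownames(beta)
  part <- check_partition_covers(partition, ids)
  s1 <- ids[part %in% group1]; s2 <- ids[part %in% group2]
  if (length(s1) < 2 || length(s2) < 2)
    fr_stop("fr_invalid_parameter", "each realm group needs >= 2 GSUs")

  ln_off <- function(v) {
    mx <- max(v[v > 0], 0)
    delta <- if (mx > 0) 1e-6 * mx else 1e-6
    log(v + delta)
  }
  beta_v <- ln_off(as.vector(beta[s1, s2]))

  per_step <- lapply(seq_along(times), function(i) {
    iso <- iso_series[[i]][s1, s2]
    cd <- climate_distance(clim_series[[i]], standardize = standardize_climate)
    clim <- cd[s1, s2]
    iso_v <- ln_off(as.vector(iso))
    clim_v <- ln_off(as.vector(clim))
    r <- suppressWarnings(stats::cor(iso_v, clim_v))
    hp <- withCallingHandlers(
      hpart_two(beta_v, clim_v, iso_v),
      fr_collinear = function(w) invokeRestart("muffleWarning"))
    data.frame(time = times[i], r_predictors = r,
               i_clim = hp[["I1"]], i_geo = hp[["I2"]],
               r2_full = hp[["r2_full"]])
  })
  per_step <- do.call(rbind, per_step)

  bin <- floor(per_step$time / bin_width) * bin_width
  agg <- function(v) {
    m <- tapply(v, bin, mean)
    se <- tapply(v, bin, function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0)
    list(mean = m, se = se)
  }
  gi <- agg(per_step$i_geo); ci <- agg(per_step$i_clim); rp <- agg(per_step$r_predictors)
  per_bin <- data.frame(
    bin_start = as.numeric(names(gi$mean)),
    i_geo_mean = as.numeric(gi$mean), i_geo_se = as.numeric(gi$se),
    i_clim_mean = as.numeric(ci$mean), i_clim_se = as.numeric(ci$se),
    r_mean = as.numeric(rp$mean), r_se = as.numeric(rp$se)
  )
  per_bin <- per_bin[order(per_bin$bin_start), ]
  structure(list(per_step = per_step, per_bin = per_bin,
                 group1 = group1, group2 = group2),
            class = "driver_series")
}
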