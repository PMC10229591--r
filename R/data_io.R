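# Readers and writers for every external format the pipeline touches:
# newick trees, long-format occurrence CSV, climate CSV, ESRI ASCII-grid
# paleo surfaces, regionalization CSV/GeoJSON, and the synthetic-world
# bundle. All readers validate strictly and raise typed format errors; all
# writers round-trip.

#' Read a dated phylogeny from a newick file
#'
#' @param path newick file with branch lengths.
#' @return a `phylo`; duplicate tips, missing or negative branch lengths are
#'   rejected with a format error naming the offender.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) fr_stop("fr_format_error", "no such file: %s", path)
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) fr_stop("fr_format_error",
                                             "unparsable newick in %s: %s",
                                             path, conditionMessage(e)))
  if (is.null(tr)) fr_stop("fr_format_error", "unparsable newick in %s", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) fr_stop("fr_format_error", "duplicate tip label: %s", dup[1])
  if (is.null(tr$edge.length))
    fr_stop("fr_format_error", "tree has no branch lengths: %s", path)
  if (any(tr$edge.length < 0))
    fr_stop("fr_format_error", "negative branch length on edge to node %d",
            tr$edge[which(tr$edge.length < 0)[1], 2])
  tr
}

#' Write a phylogeny to newick
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read occurrence records into a binary genus x GSU matrix
#'
#' Expects a CSV with columns `genus_id,gsu_id`. Duplicate records are
#' collapsed (logged); when a tree is supplied, genera absent from its tips
#' are dropped (logged), mirroring the intersection of phylogeny and
#' distribution data; GSUs left empty by the drop are removed (logged).
#'
#' @param path CSV path.
#' @param tree optional `phylo` to intersect against.
#' @return binary occurrence matrix, genera and GSUs in lexicographic order.
#' @export
read_occurrences <- function(path, tree = NULL) {
  if (!file.exists(path)) fr_stop("fr_format_error", "no such file: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) fr_stop("fr_format_error",
                                             "cannot parse %s: %s", path,
                                             conditionMessage(e)))
  if (!nrow(df)) fr_stop("fr_format_error", "empty occurrence file: %s", path)
  if (!all(c("genus_id", "gsu_id") %in% names(df)))
    fr_stop("fr_format_error", "occurrence file needs columns genus_id,gsu_id")
  df <- df[, c("genus_id", "gsu_id")]
  ndup <- sum(duplicated(df))
  if (ndup) {
    fr_log("collapsed %d duplicate occurrence record(s)", ndup)
    df <- unique(df)
  }
  if (!is.null(tree)) {
    drop <- !df$genus_id %in% tree$tip.label
    if (any(drop)) {
      fr_log("dropped %d record(s) of %d genus/genera absent from the tree",
             sum(drop), length(unique(df$genus_id[drop])))
      df <- df[!drop, , drop = FALSE]
    }
    if (!nrow(df))
      fr_stop("fr_format_error", "no occurrence records remain after tree intersection")
  }
  genera <- sort(unique(df$genus_id))
  gsus <- sort(unique(df$gsu_id))
  occ <- matrix(0L, length(genera), length(gsus),
                dimnames = list(genera, gsus))
  occ[cbind(match(df$genus_id, genera), match(df$gsu_id, gsus))] <- 1L
  check_occurrence(occ)
}

#' Write an occurrence matrix as long-format CSV
#' @param occ binary occurrence matrix.
#' @param path output CSV.
#' @export
write_occurrences <- function(occ, path) {
  idx <- which(occ > 0, arr.ind = TRUE)
  df <- data.frame(genus_id = rownames(occ)[idx[, 1]],
                   gsu_id = colnames(occ)[idx[, 2]], stringsAsFactors = FALSE)
  df <- df[order(df$genus_id, df$gsu_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-GSU climate table
#' @param path CSV with columns `gsu_id,mat_c,map_mm`.
#' @return validated data.frame (one row per GSU, precipitation >= 0).
#' @export
read_climate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gsu_id", "mat_c", "map_mm") %in% names(df)))
    fr_stop("fr_format_error", "climate file needs columns gsu_id,mat_c,map_mm")
  if (anyDuplicated(df$gsu_id))
    fr_stop("fr_format_error", "duplicate GSU in climate table: %s",
            df$gsu_id[duplicated(df$gsu_id)][1])
  if (any(df$map_mm < 0))
    fr_stop("fr_format_error", "negative precipitation for GSU %s",
            df$gsu_id[df$map_mm < 0][1])
  df
}

#' Write a climate table
#' @param climate data.frame `(gsu_id, mat_c, map_mm)`.
#' @param path output CSV.
#' @export
write_climate <- function(climate, path) {
  utils::write.csv(climate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- ESRI ASCII grid ---------------------------------------------------------
# The paleo surfaces are tiny (1-degree cells), so the plain-text ESRI ASCII
# dialect is used; cell (1,1) is the NW corner and headers follow the usual
# ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value layout.

read_asc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) fr_stop("fr_format_error", "truncated ASCII grid: %s", path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2) fr_stop("fr_format_error", "bad header line '%s' in %s",
                                 lines[i], path)
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    fr_stop("fr_format_error", "incomplete ASCII grid header in %s", path)
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    fr_stop("fr_format_error", "grid body of %s has %d values, expected %d",
            path, length(vals), hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  list(grid = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

write_asc <- function(grid, xll, yll, cellsize, path, nodata = -9999) {
  g <- grid
  g[is.na(g)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(g)), sprintf("nrows %d", nrow(g)),
           sprintf("xllcorner %.10g", xll), sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", cellsize),
           sprintf("NODATA_value %d", nodata))
  body <- apply(g, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a directory of paired paleo cost surfaces
#'
#' Expects files named `paleo_<t>ma_mask.asc` / `paleo_<t>ma_elev.asc`.
#' NODATA mask cells are treated as ocean (logged); mask/elevation grids
#' must be congruent; elevation must be finite on land cells.
#'
#' @param dir directory path.
#' @return list of `cost_surface` objects sorted by time ascending.
#' @export
read_cost_surfaces <- function(dir) {
  masks <- list.files(dir, pattern = "^paleo_\\d+ma_mask\\.asc$")
  if (!length(masks)) fr_stop("fr_format_error", "no paleo mask grids in %s", dir)
  times <- as.numeric(sub("^paleo_(\\d+)ma_mask\\.asc$", "\\1", masks))
  ord <- order(times)
  surfaces <- lapply(ord, function(i) {
    t <- times[i]
    mp <- file.path(dir, sprintf("paleo_%dma_mask.asc", t))
    ep <- file.path(dir, sprintf("paleo_%dma_elev.asc", t))
    if (!file.exists(ep))
      fr_stop("fr_format_error", "unpaired surface: %s has no elevation grid", mp)
    m <- read_asc(mp); e <- read_asc(ep)
    if (!identical(dim(m$grid), dim(e$grid)) ||
        m$cellsize != e$cellsize || m$xll != e$xll || m$yll != e$yll)
      fr_stop("fr_format_error", "mask/elevation grids incongruent at %d Ma", t)
    mask <- m$grid
    nna <- sum(is.na(mask))
    if (nna) {
      fr_log("%d NODATA mask cell(s) at %d Ma treated as ocean", nna, t)
      mask[is.na(mask)] <- 0
    }
    if (any(mask > 0 & is.na(e$grid)))
      fr_stop("fr_format_error", "non-finite elevation on land cells at %d Ma", t)
    elev <- e$grid
    elev[is.na(elev)] <- 0
    structure(list(time = t, mask = mask, elev = elev,
                   cellsize = m$cellsize, xll = m$xll, yll = m$yll),
              class = "cost_surface")
  })
  extra <- setdiff(
    sub("_elev", "_mask", list.files(dir, pattern = "^paleo_\\d+ma_elev\\.asc$")),
    masks)
  if (length(extra))
    fr_stop("fr_format_error", "unpaired elevation grid(s): %s", extra[1])
  surfaces
}

#' Write cost surfaces as paired ASCII grids
#' @param surfaces list of `cost_surface` objects.
#' @param dir output directory (created if absent).
#' @export
write_cost_surfaces <- function(surfaces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in surfaces) {
    write_asc(s$mask, s$xll, s$yll, s$cellsize,
              file.path(dir, sprintf("paleo_%dma_mask.asc", s$time)))
    write_asc(s$elev, s$xll, s$yll, s$cellsize,
              file.path(dir, sprintf("paleo_%dma_elev.asc", s$time)))
  }
  invisible(dir)
}

#' Write a regionalization to CSV and GeoJSON
#'
#' Validates completeness (every GSU assigned at every rank) and nestedness
#' (every sub-realm inside exactly one realm) before writing.
#'
#' @param reg a `regionalization` object.
#' @param gsu_table data.frame with `gsu_id`, `lon`, `lat`.
#' @param path output CSV path; a `.geojson` sibling is written next to it.
#' @return invisibly, the CSV path.
#' @export
write_regionalization <- function(reg, gsu_table, path) {
  ids <- gsu_table$gsu_id
  for (lvl in c("super_realms", "realms", "subrealms")) {
    miss <- setdiff(ids, names(reg[[lvl]]))
    if (length(miss))
      fr_stop("fr_consistency_error", "GSU %s unassigned at level %s", miss[1], lvl)
  }
  cross <- table(reg$subrealms[ids], reg$realms[ids]) > 0
  if (any(rowSums(cross) > 1))
    fr_stop("fr_consistency_error",
            "sub-realm %s spans more than one realm; refusing to write",
            rownames(cross)[rowSums(cross) > 1][1])
  sil <- if (is.null(reg$silhouette)) rep(NA_real_, length(ids))
         else reg$silhouette[ids]
  df <- data.frame(gsu_id = ids,
                   super_realm = reg$super_realms[ids],
                   realm = reg$realms[ids],
                   sub_realm = reg$subrealms[ids],
                   silhouette = sil, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)

  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(gsu_table$lon[i], gsu_table$lat[i])),
         properties = list(gsu_id = df$gsu_id[i],
                           super_realm = df$super_realm[i],
                           realm = df$realm[i], sub_realm = df$sub_realm[i]))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, sub("\\.csv$", ".geojson", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a regionalization CSV back into partitions
#' @param path CSV written by [write_regionalization()].
#' @return list of named partitions `super_realms`, `realms`, `subrealms`
#'   and the `silhouette` vector.
#' @export
read_regionalization <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gsu_id", "super_realm", "realm", "sub_realm", "silhouette")
  if (!all(need %in% names(df)))
    fr_stop("fr_format_error", "regionalization file lacks required columns")
  list(super_realms = stats::setNames(df$super_realm, df$gsu_id),
       realms = stats::setNames(df$realm, df$gsu_id),
       subrealms = stats::setNames(df$sub_realm, df$gsu_id),
       silhouette = stats::setNames(df$silhouette, df$gsu_id))
}

#' Write a complete synthetic world to disk
#'
#' Emits the newick tree, long-format occurrences, GSU table, climate table,
#' optional paired paleo rasters, and a truth JSON (planted realms, split
#' times, parameters, seed).
#'
#' @param flora a `synthetic_flora` from [gen_flora()].
#' @param dir output directory.
#' @param paleo optional `paleo_series` from [gen_paleo()].
#' @return invisibly, `dir`.
#' @export
write_world <- function(flora, dir, paleo = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tree(flora$tree, file.path(dir, "tree.nwk"))
  write_occurrences(flora$occ, file.path(dir, "occurrences.csv"))
  utils::write.csv(flora$world$gsu_table, file.path(dir, "gsu_table.csv"),
                   row.names = FALSE, quote = FALSE)
  write_climate(flora$climate, file.path(dir, "climate.csv"))
  if (!is.null(paleo)) write_cost_surfaces(paleo$surfaces, file.path(dir, "paleo"))
  truth <- list(seed = flora$seed, params = flora$params,
                realm_of_gsu = as.list(flora$world$realm_of_gsu),
                split_times = flora$world$split_times)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(dir)
}
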