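# End-to-end orchestration: run every stage from one validated configuration
# with a single master seed, write all artifacts plus a hash manifest, and
# re-run the regionalization over alternative trees for sensitivity analysis.

#' Default pipeline configuration
#'
#' @param ... overrides of the defaults.
#' @return a validated config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    tree = NULL, occurrences = NULL, climate = NULL, paleo_dir = NULL,
    simulate = NULL,              # a list of gen_flora() arguments, or NULL
    mode = "phylogenetic",
    pbeta_realm = 0.80, pbeta_subrealm = 0.95, pbeta_selection = 0.99,
    linkage = "auto", fuzziness = 1.5, nmds_starts = 50,
    chronology_times = NULL,      # e.g. seq(0, 160, 10); NULL disables
    drivers = FALSE, driver_groups = NULL, driver_times = NULL,
    k_ocean = 10, k_elev = 1,
    nodes = FALSE, gnd_threshold = 0.65, n_rand = 200,
    seed = 1, out = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) fr_stop("fr_config_error", "unknown config field: %s", bad[1])
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$pbeta_realm <= 0 || cfg$pbeta_subrealm > 1 ||
      cfg$pbeta_realm >= cfg$pbeta_subrealm)
    fr_stop("fr_config_error", "need 0 < pbeta_realm < pbeta_subrealm <= 1")
  if (!cfg$mode %in% c("taxonomic", "phylogenetic"))
    fr_stop("fr_config_error", "mode must be taxonomic or phylogenetic")
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$occurrences))
      fr_stop("fr_config_error", "either simulate or an occurrence file is required")
    if (cfg$mode == "phylogenetic" && is.null(cfg$tree))
      fr_stop("fr_config_error", "phylogenetic mode requires a tree")
    if (!is.null(cfg$chronology_times) && is.null(cfg$tree))
      fr_stop("fr_config_error", "chronology requires a tree")
    if (cfg$nodes && is.null(cfg$tree))
      fr_stop("fr_config_error", "node divergence requires a tree")
  }
  if (cfg$drivers && is.null(cfg$simulate) &&
      (is.null(cfg$climate) || is.null(cfg$paleo_dir)))
    fr_stop("fr_config_error", "drivers require climate and paleo inputs")
  if (is.null(cfg$seed)) fr_stop("fr_config_error", "a master seed is required")
  cfg
}

#' Run the full regionalization pipeline from one configuration
#'
#' Stages run in dependency order: simulate (or read inputs), pairwise beta,
#' regionalization, optional chronology, optional drivers, optional node
#' divergence. Every artifact is written under `config$out` together with a
#' manifest of MD5 hashes, the config echo and the seed; identical
#' config + seed reproduce identical manifests.
#'
#' @param config a list from [pipeline_config()].
#' @return a `pipeline_run` list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out <- cfg$out
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, florealm_error = function(e) {
      fr_stop("fr_pipeline_error", "stage '%s' failed: %s", name,
              conditionMessage(e))
    })
  }

  flora <- NULL
  if (!is.null(cfg$simulate)) {
    flora <- stage("simulate", do.call(gen_flora, c(cfg$simulate,
                                                    list(seed = cfg$seed))))
    tree <- flora$tree; occ <- flora$occ; climate <- flora$climate
  } else {
    tree <- if (!is.null(cfg$tree)) stage("read", read_tree(cfg$tree)) else NULL
    occ <- stage("read", read_occurrences(cfg$occurrences, tree))
    climate <- if (!is.null(cfg$climate)) stage("read", read_climate(cfg$climate)) else NULL
  }

  beta <- stage("beta", pairwise_beta(occ, tree, mode = cfg$mode))
  reg <- stage("regionalize",
               regionalize(beta, cfg$pbeta_realm, cfg$pbeta_subrealm,
                           linkage = cfg$linkage, fuzziness = cfg$fuzziness,
                           n_starts = cfg$nmds_starts, seed = cfg$seed))

  chron <- NULL
  if (!is.null(cfg$chronology_times)) {
    chron <- stage("chronology",
                   chronology_run(tree, occ, times = cfg$chronology_times,
                                  pbeta = cfg$pbeta_realm, linkage = reg$method,
                                  n_starts = cfg$nmds_starts, seed = cfg$seed))
  }

  drivers <- NULL
  if (isTRUE(cfg$drivers)) {
    drivers <- stage("drivers", {
      if (!is.null(flora)) {
        paleo <- gen_paleo(flora$world, times = cfg$driver_times,
                           seed = cfg$seed)
        centroids <- flora$world$gsu_table
      } else {
        paleo <- list(surfaces = read_cost_surfaces(cfg$paleo_dir))
        paleo$times <- vapply(paleo$surfaces, `[[`, 0, "time")
        paleo$paleoclimate <- NULL
        centroids <- NULL
        fr_stop("fr_config_error",
                "file-based driver runs need per-step paleoclimate tables; use driver_series() directly")
      }
      iso <- lapply(paleo$surfaces, least_cost_isolation, centroids = centroids,
                    k_ocean = cfg$k_ocean, k_elev = cfg$k_elev)
      groups <- cfg$driver_groups %||% {
        k <- attr(reg$realms, "k")
        list(g1 = seq_len(ceiling(k / 2)), g2 = (ceiling(k / 2) + 1):k)
      }
      driver_series(beta, reg$realms, groups[[1]], groups[[2]], iso,
                    paleo$paleoclimate, paleo$times)
    })
  }

  nodes <- NULL
  if (isTRUE(cfg$nodes)) {
    k <- attr(reg$realms, "k")
    pair <- if (k >= 2) c(1, 2) else NULL
    nodes <- stage("nodes",
                   node_divergence(tree, occ, reg$realms, pair,
                                   threshold = cfg$gnd_threshold,
                                   n_rand = cfg$n_rand, seed = cfg$seed))
  }

  manifest <- NULL
  if (!is.null(out)) {
    gsu_table <- if (!is.null(flora)) flora$world$gsu_table else
      data.frame(gsu_id = colnames(occ), lon = NA_real_, lat = NA_real_)
    if (!is.null(tree)) write_tree(tree, file.path(out, "tree.nwk"))
    write_occurrences(occ, file.path(out, "occurrences.csv"))
    utils::write.csv(
      data.frame(gsu_id = rownames(beta),
                 round(beta, 12), check.names = FALSE),
      file.path(out, "beta.csv"), row.names = FALSE, quote = FALSE)
    write_regionalization(reg, gsu_table, file.path(out, "regionalization.csv"))
    files <- list.files(out, full.names = TRUE, recursive = TRUE)
    manifest <- list(
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "out")],
      hashes = as.list(tools::md5sum(sort(files)))
    )
    names(manifest$hashes) <- basename(sort(files))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  structure(list(tree = tree, occ = occ, climate = climate, beta = beta,
                 regionalization = reg, chronology = chron, drivers = drivers,
                 nodes = nodes, flora = flora, manifest = manifest,
                 config = cfg),
            class = "pipeline_run")
}

#' Sensitivity of the regionalization to alternative trees
#'
#' Re-runs beta + regionalization once per tree on the shared genus set and
#' reports the pairwise adjusted Rand index between the realm partitions.
#'
#' @param occ binary occurrence matrix.
#' @param trees list of `phylo` objects (>= 2) over overlapping tip sets.
#' @param pbeta_realm realm-cut threshold.
#' @param linkage linkage name (default UPGMA).
#' @return list with `regionalizations` (one per tree) and `ari` (matrix).
#' @export
sensitivity_runs <- function(occ, trees, pbeta_realm = 0.80,
                             linkage = "average") {
  if (length(trees) < 2)
    fr_stop("fr_invalid_parameter", "need at least 2 trees")
  shared <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  shared <- intersect(shared, rownames(occ))
  if (!length(shared)) fr_stop("fr_invalid_parameter", "shared genus set is empty")
  occ_s <- occ[shared, , drop = FALSE]
  keep <- colSums(occ_s) > 0
  if (any(!keep)) fr_log("sensitivity: dropping %d empty GSU(s)", sum(!keep))
  occ_s <- occ_s[, keep, drop = FALSE]

  regs <- lapply(trees, function(tr) {
    beta <- pairwise_beta(occ_s, tr, mode = "phylogenetic")
    regionalize(beta, pbeta_realm = pbeta_realm,
                pbeta_subrealm = min(0.99, pbeta_realm + 0.15),
                linkage = linkage, nmds = FALSE, fuzzy = FALSE)
  })
  n <- length(regs)
  am <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    am[i, j] <- am[j, i] <- ari(regs[[i]]$realms, regs[[j]]$realms)
  }
  list(regionalizations = regs, ari = am)
}
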