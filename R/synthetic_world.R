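# Synthetic-world generator: dated phylogenies, lattice worlds with planted
# realms, occurrence matrices, climates and paleo-landscapes with known
# parameters, so every downstream stage can be verified against ground truth.
#
# The generator targets the statistical structure the analyses assume -- a
# block-structured beta-diversity matrix, clade-to-realm association with
# known divergence times, climate gradients partially aligned with realms,
# and landmasses whose pairwise route costs increase after planted splits --
# not a mechanistic model of drift, speciation or niche evolution.

#' Simulate a dated ultrametric tree with a fixed crown age
#'
#' Birth-death simulation conditioned on the number of extant tips, rescaled
#' so the root (crown) sits exactly at `crown_age`.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param crown_age root age in Ma; all branch lengths are rescaled to it.
#' @param birth_rate,death_rate per-Ma rates; `birth_rate > death_rate`.
#' @param seed integer seed; identical seeds give byte-identical trees.
#' @param labels optional character vector of tip labels (length `n_tips`);
#'   defaults to zero-padded `g001 ...`.
#' @return an ultrametric `phylo` with branch lengths in Ma.
#' @export
gen_tree <- function(n_tips, crown_age, birth_rate = 0.15, death_rate = 0,
                     seed = 1, labels = NULL) {
  if (n_tips < 2) fr_stop("fr_invalid_parameter", "n_tips must be >= 2")
  if (crown_age <= 0) fr_stop("fr_invalid_parameter", "crown_age must be > 0")
  if (birth_rate < 0 || death_rate < 0 || birth_rate <= death_rate)
    fr_stop("fr_invalid_parameter", "need birth_rate > death_rate >= 0")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth_rate, death_rate))
  depths <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * (crown_age / max(depths))
  if (is.null(labels)) {
    labels <- sprintf(paste0("g%0", max(3L, nchar(n_tips)), "d"), seq_len(n_tips))
  } else if (length(labels) != n_tips) {
    fr_stop("fr_invalid_parameter", "labels must have length n_tips")
  }
  tr$tip.label <- labels
  tr
}

# halve a GSU block along the longer side of its bounding box (rows on
# ties); the same rule defines the planted sub-realms in gen_world() and the
# spatial bisection of realm clades in gen_realm_tree()
split_gsu_block <- function(gsu_table, ids) {
  sel <- gsu_table[match(ids, gsu_table$gsu_id), ]
  rr <- range(sel$row); cr <- range(sel$col)
  if (diff(rr) >= diff(cr)) {
    cutp <- floor(mean(rr))
    list(A = ids[sel$row <= cutp], B = ids[sel$row > cutp])
  } else {
    cutp <- floor(mean(cr))
    list(A = ids[sel$col <= cutp], B = ids[sel$col > cutp])
  }
}

#' Simulate a tree with realm clades planted at chosen divergence times
#'
#' Builds a caterpillar backbone whose successive splits sit at
#' `realm_splits` (Ma, strictly decreasing) and hangs one realm clade off
#' each backbone position. Every realm clade crowns just below the youngest
#' backbone split and consists of `guilds` parallel subtrees, each of which
#' recursively bisects the realm's GSU block in space, attaching
#' block-resident tips at every bisection level. Lineages therefore stay
#' spatially confined to nested blocks at every phylogenetic depth -- the
#' multi-scale turnover structure (widespread clades, regional clades, local
#' radiations) that real floras show and that time-slicing relies on. Each
#' tip carries its home-block GSUs in the returned `range_map` attribute.
#'
#' @param world a `world_truth` from [gen_world()]; realm clade `i` is tied
#'   to planted realm `i`.
#' @param n_tips total tips, divided as evenly as possible among realms.
#' @param realm_splits backbone split ages (Ma), strictly decreasing; the
#'   crown age is `realm_splits[1]` and the number of realms must equal
#'   `world$n_realms`.
#' @param crown_frac realm clade crown age as a fraction of the youngest
#'   backbone split.
#' @param guilds parallel subtrees per realm clade (reduced automatically
#'   for small tip counts).
#' @param resident_frac fraction of each block's tips that range over the
#'   whole block rather than a sub-block.
#' @param birth_rate,death_rate rates for the terminal clade simulations.
#' @param seed integer seed.
#' @return an ultrametric `phylo` with attributes `range_map` (data.frame
#'   `tip`, `gsu`: every tip's home-block GSUs) and `realm_of_tip`.
#' @export
gen_realm_tree <- function(world, n_tips, realm_splits = c(90, 60, 30),
                           crown_frac = 0.93, guilds = 4, resident_frac = 0.3,
                           birth_rate = 0.3, death_rate = 0, seed = 1) {
  k <- length(realm_splits) + 1L
  if (k != world$n_realms)
    fr_stop("fr_invalid_parameter", "realm_splits implies %d realms, world has %d",
            k, world$n_realms)
  if (any(diff(realm_splits) >= 0))
    fr_stop("fr_invalid_parameter", "realm_splits must be strictly decreasing")
  if (n_tips < 3 * k)
    fr_stop("fr_invalid_parameter", "need at least 3 tips per realm")

  sizes <- rep(n_tips %/% k, k)
  if (n_tips %% k) sizes[seq_len(n_tips %% k)] <- sizes[seq_len(n_tips %% k)] + 1L
  width <- max(3L, nchar(n_tips))
  env <- new.env()
  env$lab <- 0L; env$sd <- 0L
  new_labels <- function(n) {
    out <- sprintf(paste0("g%0", width, "d"), env$lab + seq_len(n))
    env$lab <- env$lab + n
    out
  }
  next_seed <- function() {
    env$sd <- env$sd + 1L
    substream_seed(seed, "tree") + env$sd
  }
  strip_nwk <- function(tr) sub(";$", "", ape::write.tree(tr))

  # a terminal clade of n tips ranging over the block `ids`
  bd_clade <- function(n, crown, ids) {
    labs <- new_labels(n)
    if (n == 1) {
      list(nwk = labs, age = 0,
           ranges = data.frame(tip = rep(labs, length(ids)), gsu = ids,
                               stringsAsFactors = FALSE))
    } else {
      tr <- gen_tree(n, max(crown, 0.5), birth_rate, death_rate,
                     seed = next_seed(), labels = labs)
      list(nwk = strip_nwk(tr), age = max(crown, 0.5),
           ranges = expand.grid(tip = labs, gsu = ids,
                                KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE))
    }
  }

  # recursive spatial bisection: a node at `age` carries block residents and
  # the two half-block subtrees
  build_block <- function(ids, age, n) {
    if (length(ids) == 1 || n < 4 || age < 4) return(bd_clade(n, 0.55 * age, ids))
    n_res <- max(1L, round(resident_frac * n))
    rest <- n - n_res
    if (rest < 2) return(bd_clade(n, 0.55 * age, ids))
    halves <- split_gsu_block(world$gsu_table, ids)
    nA <- min(max(1L, round(rest * length(halves$A) / length(ids))), rest - 1L)
    res <- bd_clade(n_res, 0.55 * age, ids)
    A <- build_block(halves$A, 0.5 * age, nA)
    B <- build_block(halves$B, 0.5 * age, rest - nA)
    nwk <- sprintf("(%s:%.8f,%s:%.8f,%s:%.8f)",
                   res$nwk, age - res$age, A$nwk, age - A$age, B$nwk, age - B$age)
    list(nwk = nwk, age = age, ranges = rbind(res$ranges, A$ranges, B$ranges))
  }

  crown_r <- crown_frac * min(realm_splits)
  clades <- vector("list", k)
  for (i in seq_len(k)) {
    ids <- world$gsu_table$gsu_id[world$gsu_table$true_realm == i]
    n_i <- sizes[i]
    g <- max(1L, min(guilds, n_i %/% 3L))
    gs <- rep(n_i %/% g, g)
    if (n_i %% g) gs[seq_len(n_i %% g)] <- gs[seq_len(n_i %% g)] + 1L
    parts <- lapply(gs, function(ng) build_block(ids, 0.85 * crown_r, ng))
    if (g == 1) {
      clades[[i]] <- parts[[1]]
    } else {
      nwk <- paste0("(", paste(vapply(parts, function(p)
        sprintf("%s:%.8f", p$nwk, crown_r - p$age), ""), collapse = ","), ")")
      clades[[i]] <- list(nwk = nwk, age = crown_r,
                          ranges = do.call(rbind, lapply(parts, `[[`, "ranges")))
    }
  }

  # caterpillar assembly from the youngest backbone split outwards
  s <- realm_splits
  cur <- sprintf("(%s:%.8f,%s:%.8f)",
                 clades[[k - 1]]$nwk, s[k - 1] - clades[[k - 1]]$age,
                 clades[[k]]$nwk, s[k - 1] - clades[[k]]$age)
  cur_age <- s[k - 1]
  for (i in rev(seq_len(max(k - 2, 0)))) {
    cur <- sprintf("(%s:%.8f,%s:%.8f)",
                   clades[[i]]$nwk, s[i] - clades[[i]]$age, cur, s[i] - cur_age)
    cur_age <- s[i]
  }
  tr <- ape::read.tree(text = paste0(cur, ";"))
  range_map <- do.call(rbind, lapply(clades, `[[`, "ranges"))
  realm_of_tip <- stats::setNames(
    rep(seq_len(k), vapply(clades, function(cl) length(unique(cl$ranges$tip)), 1L)),
    unlist(lapply(clades, function(cl) unique(cl$ranges$tip))))
  attr(tr, "range_map") <- range_map
  attr(tr, "realm_of_tip") <- realm_of_tip
  tr
}

#' Generate a lattice world with planted contiguous realms
#'
#' Partitions a `rows x cols` lattice of geographic standard units (GSUs,
#' nominally 4 degrees a side) into `n_realms` contiguous axis-aligned
#' rectangular blocks, as balanced in size as the lattice allows, each split
#' into two sub-blocks along its longer side (the planted sub-realms).
#'
#' @param grid_dims integer `(rows, cols)` of the GSU lattice.
#' @param n_realms number of planted realms (`1 <= n_realms <= rows*cols`).
#' @param seed integer seed (recorded; the layout itself is deterministic).
#' @param cellsize_deg GSU edge length in degrees.
#' @return a `world_truth` list: `grid_dims`, `n_realms`, `gsu_table`
#'   (gsu_id, lon, lat, area_km2, row, col, true_realm, true_subrealm),
#'   `realm_of_gsu`, `subrealm_of_gsu`, `cellsize_deg`, `lon_w`, `lat_s`,
#'   `split_times` (filled by [gen_ranges()]), `seed`.
#' @export
gen_world <- function(grid_dims, n_realms, seed = 1, cellsize_deg = 4) {
  rows <- grid_dims[1]; cols <- grid_dims[2]
  if (rows < 1 || cols < 1) fr_stop("fr_invalid_parameter", "grid_dims must be positive")
  if (n_realms < 1 || n_realms > rows * cols)
    fr_stop("fr_invalid_parameter", "n_realms must be in [1, rows*cols]")

  # realm grid: the divisor pair of n_realms whose aspect best matches the
  # lattice; ties prefer splitting rows
  divs <- which(n_realms %% seq_len(n_realms) == 0)
  cand <- data.frame(nr = divs, nc = n_realms / divs)
  cand <- cand[cand$nr <= rows & cand$nc <= cols, , drop = FALSE]
  if (!nrow(cand))
    fr_stop("fr_invalid_parameter", "n_realms does not fit the lattice as contiguous blocks")
  score <- abs(log(cand$nr / cand$nc) - log(rows / cols))
  cand <- cand[order(score, -cand$nr), , drop = FALSE]
  nr <- cand$nr[1]; nc <- cand$nc[1]

  band <- function(n, k) rep(seq_len(k), times = diff(round(seq(0, n, length.out = k + 1))))
  row_band <- band(rows, nr)
  col_band <- band(cols, nc)

  idx <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  idx <- idx[order(idx$row, idx$col), ]
  realm <- (row_band[idx$row] - 1L) * nc + col_band[idx$col]

  cs <- cellsize_deg
  lon_w <- -cols * cs / 2
  lat_s <- -rows * cs / 2
  lon <- lon_w + (idx$col - 0.5) * cs
  lat <- lat_s + (rows - idx$row + 0.5) * cs   # row 1 = northernmost band
  gsu_id <- sprintf("gsu_%03d", seq_len(nrow(idx)))
  area <- (cs * 111.195)^2 * cos(lat * pi / 180)

  gsu_table <- data.frame(
    gsu_id = gsu_id, lon = lon, lat = lat, area_km2 = area,
    row = idx$row, col = idx$col,
    true_realm = realm, true_subrealm = NA_character_,
    stringsAsFactors = FALSE
  )
  # planted sub-realms: halve each block along its longer side (the same
  # rule drives the spatial bisection in gen_realm_tree)
  for (r in seq_len(n_realms)) {
    ids <- gsu_id[realm == r]
    if (length(ids) == 1) {
      gsu_table$true_subrealm[match(ids, gsu_id)] <- paste0(r, ".1")
    } else {
      halves <- split_gsu_block(gsu_table, ids)
      gsu_table$true_subrealm[match(halves$A, gsu_id)] <- paste0(r, ".1")
      gsu_table$true_subrealm[match(halves$B, gsu_id)] <- paste0(r, ".2")
    }
  }
  structure(list(
    grid_dims = c(rows = rows, cols = cols), n_realms = n_realms,
    realm_grid = c(nr = nr, nc = nc),
    gsu_table = gsu_table,
    realm_of_gsu = stats::setNames(realm, gsu_id),
    subrealm_of_gsu = stats::setNames(gsu_table$true_subrealm, gsu_id),
    cellsize_deg = cs, lon_w = lon_w, lat_s = lat_s,
    split_times = NULL, seed = seed
  ), class = "world_truth")
}

#' Sample an occurrence matrix with planted clade-to-realm association
#'
#' With a tree from [gen_realm_tree()] (carrying a `range_map` attribute)
#' each tip occurs in each GSU of its home block with probability `affinity`
#' and in every other GSU with probability `leakage`. For an arbitrary tree,
#' the `n_realms` oldest disjoint clades are mapped to realms in
#' tip-count-balanced order (ties broken by smallest tip label) and each tip
#' occurs in its home realm's GSUs with probability `affinity` (the sister
#' sub-block of its sub-clade with `sister_affinity`) and in foreign GSUs
#' with probability `leakage`. Empty genera are resampled until occupied; an
#' empty GSU is resampled up to 100 times and then raises a generation error
#' (Simpson beta is undefined for empty assemblages).
#'
#' @param tree dated phylogeny; either planted ([gen_realm_tree()]) or
#'   arbitrary (oldest-disjoint-clades mapping).
#' @param world a `world_truth` from [gen_world()].
#' @param affinity per-tip presence probability in the home block.
#' @param sister_affinity presence probability in the same realm's other
#'   sub-block (generic trees only).
#' @param leakage per-tip presence probability in the foreign GSUs adjacent
#'   to the home block; decays with distance beyond them.
#' @param leakage_scale e-folding distance (degrees) of the dispersal-style
#'   leakage decay; `Inf` gives spatially uniform leakage.
#' @param kernel optional GSU x GSU proximity matrix over which the leakage
#'   decays instead of planar centroid distance (it is rescaled to the mean
#'   centroid distance so `leakage_scale` keeps its meaning); this is how a
#'   planted driver -- route cost or climate similarity -- shapes floristic
#'   exchange.
#' @param seed integer seed.
#' @return binary occurrence matrix (genera x GSUs) with attributes
#'   `realm_of_genus` and `split_times` (the realm pairwise MRCA ages read
#'   off the tree).
#' @export
gen_ranges <- function(tree, world, affinity = 0.8, sister_affinity = 0.35,
                       leakage = 0.02, leakage_scale = 6, kernel = NULL,
                       seed = 1) {
  if (!(leakage >= 0 && leakage < affinity && affinity <= 1))
    fr_stop("fr_invalid_parameter", "need 0 <= leakage < affinity <= 1")
  if (sister_affinity < leakage || sister_affinity > affinity)
    fr_stop("fr_invalid_parameter", "need leakage <= sister_affinity <= affinity")
  k <- world$n_realms
  tips <- sort(tree$tip.label)
  gsu <- world$gsu_table
  n_g <- length(tips); n_s <- nrow(gsu)

  # proximity structure for the dispersal-style leakage decay: planar
  # centroid distance (degrees) unless a driver kernel is supplied
  D <- as.matrix(stats::dist(cbind(gsu$lon, gsu$lat)))
  dimnames(D) <- list(gsu$gsu_id, gsu$gsu_id)
  if (!is.null(kernel)) {
    kernel <- kernel[gsu$gsu_id, gsu$gsu_id]
    off <- upper.tri(kernel)
    D <- kernel * (mean(D[off]) / mean(kernel[off]))
  }
  leak_prob <- function(home_ids) {
    gap <- apply(D[home_ids, , drop = FALSE], 2, min) - world$cellsize_deg
    leakage * exp(-pmax(gap, 0) / leakage_scale)
  }

  prob <- matrix(0, n_g, n_s, dimnames = list(tips, gsu$gsu_id))
  range_map <- attr(tree, "range_map")
  if (!is.null(range_map)) {
    realm_of_genus <- attr(tree, "realm_of_tip")[tips]
    home_sets <- split(range_map$gsu, range_map$tip)
    for (tp in names(home_sets)) prob[tp, ] <- leak_prob(home_sets[[tp]])
    prob[cbind(match(range_map$tip, tips), match(range_map$gsu, gsu$gsu_id))] <-
      affinity
  } else {
    clades <- oldest_disjoint_clades(tree, k)
    # tip-count-balanced order, ties by smallest tip label
    ord <- order(-vapply(clades, function(cl) length(cl$tips), 1L),
                 vapply(clades, function(cl) min(cl$tips), ""))
    clades <- clades[ord]
    realm_of_genus <- stats::setNames(integer(n_g), tips)
    sub_of_genus <- stats::setNames(character(n_g), tips)
    for (r in seq_len(k)) {
      cl <- clades[[r]]
      realm_of_genus[cl$tips] <- r
      subs <- clade_children_tipsets(tree, cl$node)
      if (length(subs) >= 2) {
        sord <- order(-lengths(subs), vapply(subs, min, ""))
        sub_of_genus[subs[[sord[1]]]] <- "1"
        for (j in sord[-1]) sub_of_genus[subs[[j]]] <- "2"
      } else {
        sub_of_genus[cl$tips] <- "1"
      }
    }
    leak_by_realm <- lapply(seq_len(k), function(r)
      leak_prob(gsu$gsu_id[gsu$true_realm == r]))
    for (i in seq_len(n_g)) {
      r <- realm_of_genus[i]
      home <- gsu$true_realm == r
      own_sub <- home & gsu$true_subrealm == paste0(r, ".", sub_of_genus[i])
      prob[i, ] <- leak_by_realm[[r]]
      prob[i, home] <- sister_affinity
      prob[i, own_sub] <- affinity
    }
  }

  occ <- with_seed(substream_seed(seed, "ranges") + seed %% 1000L, {
    m <- matrix(as.integer(stats::runif(n_g * n_s) < prob), n_g, n_s,
                dimnames = dimnames(prob))
    # no all-zero genus: resample the row until occupied
    for (i in which(rowSums(m) == 0)) {
      tries <- 0L
      while (sum(m[i, ]) == 0) {
        m[i, ] <- as.integer(stats::runif(n_s) < prob[i, ])
        tries <- tries + 1L
        if (tries > 10000L)
          fr_stop("fr_generation_error", "cannot occupy genus %s", tips[i])
      }
    }
    # no all-zero GSU: resample the column's incident genera up to 100 times
    for (j in which(colSums(m) == 0)) {
      tries <- 0L
      while (sum(m[, j]) == 0) {
        m[, j] <- as.integer(stats::runif(n_g) < prob[, j])
        tries <- tries + 1L
        if (tries > 100L)
          fr_stop("fr_generation_error",
                  "GSU %s stayed empty after 100 resamples; raise affinity or leakage",
                  gsu$gsu_id[j])
      }
    }
    m
  })

  ages <- tree_node_ages(tree)
  rep_tip <- vapply(seq_len(k), function(r) names(realm_of_genus)[realm_of_genus == r][1], "")
  split_times <- matrix(0, k, k)
  if (k > 1) {
    for (p in seq_len(k - 1)) for (q in (p + 1):k) {
      m <- ape::getMRCA(tree, c(rep_tip[p], rep_tip[q]))
      split_times[p, q] <- split_times[q, p] <- ages[m]
    }
  }
  attr(occ, "realm_of_genus") <- realm_of_genus
  attr(occ, "split_times") <- split_times
  occ
}

# the k oldest disjoint clades: lineages crossing a depth just below the
# (k-1)-th oldest internal node
oldest_disjoint_clades <- function(tree, k) {
  if (k == 1) {
    return(list(list(node = length(tree$tip.label) + 1L, tips = sort(tree$tip.label))))
  }
  ages <- tree_node_ages(tree)
  internal <- sort(unique(ages[-seq_len(length(tree$tip.label))]), decreasing = TRUE)
  if (length(internal) < k - 1)
    fr_stop("fr_invalid_parameter", "tree has too few splits for %d realms", k)
  lo <- if (length(internal) >= k) internal[k] else 0
  t_cut <- (internal[k - 1] + lo) / 2
  lin <- lineages_at_depth(tree, t_cut)
  if (length(lin) != k)
    fr_stop("fr_invalid_parameter",
            "no depth with exactly %d lineages (tied node ages?)", k)
  lapply(lin, function(l) list(node = l$node, tips = sort(l$tips)))
}

# tip sets of a node's children (singleton children are their own sets)
clade_children_tipsets <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(list(tree$tip.label[node]))
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  lapply(kids, function(ch) {
    if (ch <= ntip) tree$tip.label[ch]
    else sort(tree$tip.label[intersect(unlist(phangorn_free_descendants(tree, ch)), seq_len(ntip))])
  })
}

# tips descending from an internal node, base-R traversal
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    n <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (n <= ntip) out <- c(out, n)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == n, 2])
  }
  out
}

#' Generate a contemporary climate table over a synthetic world
#'
#' Annual mean temperature (deg C) and annual precipitation (mm) per GSU are a
#' latitudinal gradient mixed with per-realm offsets in proportion
#' `gradient_align`, plus Gaussian noise.
#'
#' @param world a `world_truth`.
#' @param gradient_align fraction in \[0, 1\]: 0 = climate depends on latitude
#'   only, 1 = climate constant within each realm (plus noise).
#' @param noise_sd noise standard deviation in deg C (precipitation noise is
#'   scaled by 80 mm per deg C).
#' @param seed integer seed.
#' @return data.frame `(gsu_id, mat_c, map_mm)`.
#' @export
gen_climate <- function(world, gradient_align = 0.5, noise_sd = 1, seed = 1) {
  if (gradient_align < 0 || gradient_align > 1)
    fr_stop("fr_invalid_parameter", "gradient_align must be in [0, 1]")
  gsu <- world$gsu_table
  k <- world$n_realms
  with_seed(substream_seed(seed, "climate"), {
    off_mat <- stats::rnorm(k, 0, 6)
    off_map <- stats::rnorm(k, 0, 500)
    lat_mat <- 28 - 0.55 * abs(gsu$lat)
    lat_map <- 2600 - 25 * abs(gsu$lat)
    ga <- gradient_align
    mat <- (1 - ga) * lat_mat + ga * (14 + off_mat[gsu$true_realm]) +
      stats::rnorm(nrow(gsu), 0, noise_sd)
    map <- (1 - ga) * lat_map + ga * (1400 + off_map[gsu$true_realm]) +
      stats::rnorm(nrow(gsu), 0, noise_sd * 80)
    data.frame(gsu_id = gsu$gsu_id, mat_c = mat, map_mm = pmax(map, 0),
               stringsAsFactors = FALSE)
  })
}

#' Generate paleo-landscape surfaces and paleoclimate series
#'
#' Produces one land/ocean + elevation cost surface and one per-GSU
#' paleoclimate table per time step. Under the `"isolation"` scenario an
#' ocean strip opens along the boundary between two adjacent realm blocks at
#' every time younger than their planted split, so least-cost route costs
#' between their GSUs increase after the split, while paleoclimate is spatial
#' noise. Under the `"climate"` scenario the landmass stays whole at all
#' times and realm climates drift apart after their splits (divergence
#' accrues with the square root of elapsed time since each split, in evenly
#' spread directions of the temperature/precipitation plane).
#'
#' @param world a `world_truth`.
#' @param times time steps in Ma, ascending from 0.
#' @param split_times realm-pair split matrix (Ma); defaults to
#'   `world$split_times`.
#' @param seed integer seed.
#' @param scenario `"isolation"` or `"climate"` (which driver is planted).
#' @param cells_per_gsu raster cells per GSU edge (4 gives 1-degree cells for
#'   4-degree GSUs).
#' @param strip_halfwidth ocean strip half-width in cells.
#' @param elev_base,elev_sd land elevation mean and SD (m), fixed over time.
#' @param clim_amp climate drift amplitude (deg C per sqrt(Ma)).
#' @param clim_spatial spatial climate gradient (deg C per degree of
#'   longitude/latitude) under the `"climate"` scenario; climate there is a
#'   smooth spatial field plus the realm drift, as real macroclimate is.
#' @param clim_noise per-GSU climate noise SD (deg C).
#' @return a `paleo_series` list: `surfaces` (list of `cost_surface`),
#'   `paleoclimate` (list of data.frames), `times`, `scenario`.
#' @export
gen_paleo <- function(world, times = NULL, split_times = NULL, seed = 1,
                      scenario = c("isolation", "climate"), cells_per_gsu = 4,
                      strip_halfwidth = 1, elev_base = 300, elev_sd = 200,
                      clim_amp = 6, clim_spatial = 1.5, clim_noise = 0.5) {
  scenario <- match.arg(scenario)
  split_times <- split_times %||% world$split_times
  if (is.null(split_times))
    fr_stop("fr_invalid_parameter", "no split_times on world and none supplied")
  k <- world$n_realms
  splits <- split_times[upper.tri(split_times)]
  if (is.null(times)) times <- 0:ceiling(max(splits) + 10)
  if (is.unsorted(times)) fr_stop("fr_invalid_parameter", "times must ascend from 0")
  if (any(splits < min(times) | splits > max(times)))
    fr_stop("fr_invalid_parameter", "split time outside [%g, %g]", min(times), max(times))

  rows <- world$grid_dims[["rows"]]; cols <- world$grid_dims[["cols"]]
  cpg <- cells_per_gsu
  R <- rows * cpg; C <- cols * cpg
  cell_deg <- world$cellsize_deg / cpg

  elev <- with_seed(substream_seed(seed, "paleo"), {
    matrix(pmax(stats::rnorm(R * C, elev_base, elev_sd), 1), R, C)
  })

  # geographically adjacent realm-block pairs and their shared boundaries
  gsu <- world$gsu_table
  blocks <- lapply(seq_len(k), function(r) {
    sel <- gsu$true_realm == r
    list(rows = range(gsu$row[sel]), cols = range(gsu$col[sel]))
  })
  boundaries <- list()
  for (p in seq_len(k - 1)) for (q in (p + 1):k) {
    bp <- blocks[[p]]; bq <- blocks[[q]]
    if (bp$cols[2] + 1 == bq$cols[1] &&
        max(bp$rows[1], bq$rows[1]) <= min(bp$rows[2], bq$rows[2])) {
      boundaries[[length(boundaries) + 1]] <- list(
        split = split_times[p, q], dir = "v", at = bp$cols[2] * cpg,
        span = c(max(bp$rows[1], bq$rows[1]), min(bp$rows[2], bq$rows[2])))
    }
    if (bp$rows[2] + 1 == bq$rows[1] &&
        max(bp$cols[1], bq$cols[1]) <= min(bp$cols[2], bq$cols[2])) {
      boundaries[[length(boundaries) + 1]] <- list(
        split = split_times[p, q], dir = "h", at = bp$rows[2] * cpg,
        span = c(max(bp$cols[1], bq$cols[1]), min(bp$cols[2], bq$cols[2])))
    }
  }

  hw <- strip_halfwidth
  surfaces <- lapply(times, function(t) {
    mask <- matrix(1L, R, C)
    if (scenario == "isolation") {
      for (b in boundaries) {
        if (t < b$split) {
          cells <- (b$at - hw + 1):(b$at + hw)
          span <- ((b$span[1] - 1) * cpg + 1):(b$span[2] * cpg)
          if (b$dir == "v") mask[span, cells] <- 0L else mask[cells, span] <- 0L
        }
      }
    }
    structure(list(time = t, mask = mask, elev = elev, cellsize = cell_deg,
                   xll = world$lon_w, yll = world$lat_s),
              class = "cost_surface")
  })
  names(surfaces) <- paste0("t", times)

  # per-realm climate drift: each backbone split event pushes its two
  # daughter realm sets apart along a fixed, evenly spread direction
  # (golden-angle spacing; fixed like the block layout, so no seed can place
  # two split events on cancelling axes)
  events <- split_events(split_times)
  angles <- seq_along(events) * 2.399963
  noise <- with_seed(substream_seed(seed, "paleo") + 2L, {
    array(stats::rnorm(nrow(gsu) * length(times) * 2, 0, clim_noise),
          dim = c(nrow(gsu), length(times), 2))
  })
  paleoclimate <- lapply(seq_along(times), function(ti) {
    t <- times[ti]
    pos <- matrix(0, k, 2)
    if (scenario == "climate") {
      for (ei in seq_along(events)) {
        ev <- events[[ei]]
        amp <- clim_amp * sqrt(max(0, ev$age - t))
        u <- c(cos(angles[ei]), sin(angles[ei]))
        pos[ev$left, ] <- pos[ev$left, , drop = FALSE] +
          matrix(amp * u, length(ev$left), 2, byrow = TRUE)
        pos[ev$right, ] <- pos[ev$right, , drop = FALSE] -
          matrix(amp * u, length(ev$right), 2, byrow = TRUE)
      }
    }
    r <- gsu$true_realm
    sx <- sy <- 0
    if (scenario == "climate") {
      sx <- clim_spatial * gsu$lon
      sy <- clim_spatial * gsu$lat
    }
    data.frame(gsu_id = gsu$gsu_id,
               mat_c = 18 + pos[r, 1] + sx + noise[, ti, 1],
               map_mm = pmax(1500 + 60 * (pos[r, 2] + sy) + 60 * noise[, ti, 2], 0),
               stringsAsFactors = FALSE)
  })
  names(paleoclimate) <- paste0("t", times)

  structure(list(surfaces = surfaces, paleoclimate = paleoclimate,
                 times = times, scenario = scenario, seed = seed),
            class = "paleo_series")
}

# decompose an ultrametric split-time matrix into its merge events, each with
# an age and the two realm index sets it separates (oldest first)
split_events <- function(split_times) {
  hc <- stats::hclust(stats::as.dist(split_times), method = "single")
  members <- lapply(seq_len(nrow(split_times)), function(i) i)
  events <- list()
  merged <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) -x else NULL
    left <- if (hc$merge[m, 1] < 0) -hc$merge[m, 1] else merged[[hc$merge[m, 1]]]
    right <- if (hc$merge[m, 2] < 0) -hc$merge[m, 2] else merged[[hc$merge[m, 2]]]
    merged[[m]] <- c(left, right)
    events[[m]] <- list(age = hc$height[m], left = left, right = right)
  }
  events[order(vapply(events, function(e) -e$age, 1))]
}

#' Generate a complete synthetic flora (tree, world, ranges, climate)
#'
#' One master seed drives every stage through named substreams, so each
#' component can be regenerated in isolation. The defaults describe the
#' package's reference study system: four realms on a 6x6 lattice of
#' 4-degree GSUs, 200 genera, realm divergences planted at 90/60/30 Ma,
#' realm clades with four parallel spatially bisecting guild subtrees,
#' home-block affinity 0.8, and foreign leakage 0.02.
#'
#' @param n_realms,n_tips,grid_dims world size.
#' @param realm_splits backbone split ages, strictly decreasing (length
#'   `n_realms - 1`).
#' @param crown_frac,guilds,resident_frac realm clade structure (see
#'   [gen_realm_tree()]).
#' @param affinity,leakage occupancy probabilities.
#' @param gradient_align,climate_noise_sd contemporary climate parameters.
#' @param seed master integer seed.
#' @return a `synthetic_flora` list: `tree`, `world`, `occ`, `climate`,
#'   `params`, `seed`.
#' @export
gen_flora <- function(n_realms = 4, n_tips = 200, grid_dims = c(6, 6),
                      realm_splits = NULL, crown_frac = 0.93, guilds = 4,
                      resident_frac = 0.3, affinity = 0.8, leakage = 0.02,
                      gradient_align = 0.5, climate_noise_sd = 1, seed = 1) {
  if (is.null(realm_splits))
    realm_splits <- if (n_realms == 2) 90 else seq(90, 30, length.out = n_realms - 1)
  world <- gen_world(grid_dims, n_realms, seed = seed)
  tree <- gen_realm_tree(world, n_tips, realm_splits, crown_frac, guilds,
                         resident_frac,
                         seed = substream_seed(seed, "tree") + seed %% 997L)
  occ <- gen_ranges(tree, world, affinity = affinity, leakage = leakage,
                    seed = seed)
  world$split_times <- attr(occ, "split_times")
  climate <- gen_climate(world, gradient_align, climate_noise_sd, seed = seed)
  structure(list(
    tree = tree, world = world, occ = occ, climate = climate,
    params = list(n_realms = n_realms, n_tips = n_tips, grid_dims = grid_dims,
                  realm_splits = realm_splits, crown_frac = crown_frac,
                  guilds = guilds, resident_frac = resident_frac,
                  affinity = affinity, leakage = leakage,
                  gradient_align = gradient_align,
                  climate_noise_sd = climate_noise_sd),
    seed = seed
  ), class = "synthetic_flora")
}

# pairwise realm split times (MRCA ages) for a planted tree
realm_split_times <- function(tree) {
  rt <- attr(tree, "realm_of_tip")
  if (is.null(rt)) fr_stop("fr_invalid_parameter", "tree carries no planted realms")
  k <- max(rt)
  ages <- tree_node_ages(tree)
  st <- matrix(0, k, k)
  for (p in seq_len(k - 1)) for (q in (p + 1):k) {
    m <- ape::getMRCA(tree, c(names(rt)[rt == p][1], names(rt)[rt == q][1]))
    st[p, q] <- st[q, p] <- ages[m]
  }
  st
}

#' Generate a synthetic world with a planted divergence driver
#'
#' Assembles a complete driver-attribution test world. Under the
#' `"isolation"` scenario floristic exchange (the leakage kernel) follows
#' geographic distance and ocean strips open at the planted splits; under
#' the `"climate"` scenario the landmass stays whole and exchange follows
#' the planted climate field (realm drift plus spatial gradient), so the
#' respective driver is the one that structured the flora.
#'
#' @param scenario `"isolation"` or `"climate"`.
#' @param n_realms,n_tips,grid_dims,realm_splits,affinity,leakage world
#'   parameters as in [gen_flora()].
#' @param times paleo time grid (Ma, ascending from 0).
#' @param k_ocean,k_elev route cost parameters for the isolation matrices.
#' @param seed master integer seed.
#' @return list with `world`, `tree`, `occ`, `paleo` (a `paleo_series`),
#'   `iso` (isolation matrices per time step), `scenario`.
#' @export
gen_driver_world <- function(scenario = c("isolation", "climate"),
                             n_realms = 4, n_tips = 200, grid_dims = c(6, 6),
                             realm_splits = NULL, times = seq(0, 100, by = 5),
                             affinity = 0.8, leakage = 0.02,
                             k_ocean = 10, k_elev = 1, seed = 1) {
  scenario <- match.arg(scenario)
  if (is.null(realm_splits))
    realm_splits <- if (n_realms == 2) 90 else seq(90, 30, length.out = n_realms - 1)
  world <- gen_world(grid_dims, n_realms, seed = seed)
  tree <- gen_realm_tree(world, n_tips, realm_splits,
                         seed = substream_seed(seed, "tree") + seed %% 997L)
  split_times <- realm_split_times(tree)
  paleo <- gen_paleo(world, times = times, split_times = split_times,
                     seed = seed, scenario = scenario)
  kernel <- if (scenario == "climate")
    climate_distance(paleo$paleoclimate[[paste0("t", min(times))]]) else NULL
  occ <- gen_ranges(tree, world, affinity = affinity, leakage = leakage,
                    kernel = kernel, seed = seed)
  world$split_times <- attr(occ, "split_times")
  iso <- lapply(paleo$surfaces, least_cost_isolation,
                centroids = world$gsu_table, k_ocean = k_ocean, k_elev = k_elev)
  list(world = world, tree = tree, occ = occ, paleo = paleo, iso = iso,
       scenario = scenario, seed = seed)
}
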