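# Realm chronology by phylogeny time-slicing: cut the dated tree at a depth
# t (Ma before present), collapse every branch crossing t into one lineage,
# re-run the regionalization on the collapsed lineage x GSU matrix with the
# branch lengths of the truncated tree, and match the resulting clusters to
# the present-day realms. The sequence of sliced maps dates when the
# present-day floras of different realms became distinguishable.

# node ages (Ma before present) for an ultrametric tree, rounded to 1e-6 Ma
# (one year) so accumulated newick round-off cannot break slice coverage
tree_node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  round(max(depths) - depths, 6)
}

# lineages crossing depth t: edges with parent age > t >= child age.
# Returns a list of (node = child end, tips = tip labels collapsed onto it).
lineages_at_depth <- function(tree, t) {
  ntip <- length(tree$tip.label)
  ages <- tree_node_ages(tree)
  cross <- which(ages[tree$edge[, 1]] > t & ages[tree$edge[, 2]] <= t)
  lapply(cross, function(e) {
    ch <- tree$edge[e, 2]
    tips <- if (ch <= ntip) tree$tip.label[ch]
            else tree$tip.label[phangorn_free_descendants(tree, ch)]
    list(node = ch, tips = sort(tips))
  })
}

#' Slice a dated tree at a phylogenetic depth
#'
#' Every branch whose age interval spans `t` (parent older than `t`, child at
#' or younger) becomes one collapsed lineage carrying all its descendant
#' tips; the sliced tree is the original truncated below `t`, with the
#' lineages as tips and terminal branch lengths `parent age - t`. `t = 0` is
#' the identity slice. At or beyond the crown age no branch spans `t`: the
#' tree collapses onto the root's children with a warning.
#'
#' @param tree dated ultrametric `phylo`.
#' @param t slice depth in Ma before present (`t >= 0`).
#' @return list with `t`, `lineages` (named list of tip-label vectors),
#'   `tip_map` (named character: tip -> lineage id) and `sliced_tree` (a
#'   `phylo` with lineages as tips, or `NULL` when `t` is at or beyond the
#'   crown).
#' @export
slice_tree <- function(tree, t) {
  if (t < 0) fr_stop("fr_invalid_parameter", "slice depth t must be >= 0")
  ntip <- length(tree$tip.label)
  ages <- tree_node_ages(tree)
  root <- ntip + 1L
  crown <- ages[root]

  if (t >= crown) {
    fr_warn("fr_slice_warning",
            "slice depth %g is at or beyond the crown age %g; tips collapse onto the root's children",
            t, crown)
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    lineages <- lapply(kids, function(ch) {
      if (ch <= ntip) tree$tip.label[ch]
      else sort(tree$tip.label[phangorn_free_descendants(tree, ch)])
    })
    names(lineages) <- ifelse(kids <= ntip, tree$tip.label[pmin(kids, ntip)],
                              paste0("L", kids))
    tip_map <- stats::setNames(rep(names(lineages), lengths(lineages)),
                               unlist(lineages))
    return(list(t = t, lineages = lineages, tip_map = tip_map,
                sliced_tree = NULL))
  }

  lin <- lineages_at_depth(tree, t)
  ids <- vapply(lin, function(l) {
    if (length(l$tips) == 1) l$tips else paste0("L", l$node)
  }, "")
  lineages <- stats::setNames(lapply(lin, `[[`, "tips"), ids)
  tip_map <- stats::setNames(rep(ids, lengths(lineages)), unlist(lineages))
  if (length(tip_map) != ntip)
    fr_stop("fr_consistency_error", "slice did not cover every tip")

  # newick of the truncated tree: recurse over internal nodes older than t
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    parts <- vapply(kids_of[[as.character(node)]], function(ch) {
      if (ages[ch] <= t) {
        id <- if (ch <= ntip && t == 0) tree$tip.label[ch]
              else if (ch <= ntip) tree$tip.label[ch]
              else paste0("L", ch)
        sprintf("%s:%.10f", id, ages[node] - t)
      } else {
        sprintf("%s:%.10f", build(ch), ages[node] - ages[ch])
      }
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  sliced <- if (length(lineages) == 1) NULL
            else ape::read.tree(text = paste0(build(root), ";"))
  list(t = t, lineages = lineages, tip_map = tip_map, sliced_tree = sliced)
}

#' Collapse an occurrence matrix onto sliced lineages
#'
#' A lineage is present in a GSU iff any of its member tips occurs there.
#'
#' @param occ binary occurrence matrix (genera x GSUs).
#' @param tip_map named character vector mapping every genus to a lineage id
#'   (from [slice_tree()]).
#' @return binary lineage x GSU matrix, lineage rows sorted.
#' @export
slice_assemblages <- function(occ, tip_map) {
  miss <- setdiff(rownames(occ), names(tip_map))
  if (length(miss))
    fr_stop("fr_consistency_error", "genus not covered by the slice map: %s", miss[1])
  lin <- tip_map[rownames(occ)]
  agg <- rowsum(occ, group = lin)
  out <- (agg > 0) + 0L
  out[sort(rownames(out)), , drop = FALSE]
}

#' Match sliced clusters to present-day realms
#'
#' Solves the assignment problem maximizing total shared-GSU overlap between
#' slice clusters and present realms (exact dynamic program over realm
#' subsets). Matched clusters whose best-overlap Jaccard falls below
#' `min_jaccard` receive fresh `"ancestral_<cluster>"` labels, as do
#' unmatched clusters.
#'
#' @param slice_partition named integer partition of (a subset of) the GSUs.
#' @param present named integer partition of the present-day realms.
#' @param min_jaccard threshold below which a match is declared ancestral.
#' @return list with `map` (named character: slice cluster -> present realm
#'   label or ancestral label) and `jaccard` (named numeric per slice cluster).
#' @export
match_realms <- function(slice_partition, present, min_jaccard = 0.5) {
  shared <- intersect(names(slice_partition), names(present))
  sp <- slice_partition[shared]; pp <- present[shared]
  scl <- sort(unique(slice_partition)); pcl <- sort(unique(present))
  if (length(pcl) > 20)
    fr_stop("fr_invalid_parameter", "assignment over > 20 present realms not supported")
  ov <- matrix(0L, length(scl), length(pcl), dimnames = list(scl, pcl))
  tb <- table(factor(sp, levels = scl), factor(pp, levels = pcl))
  ov[] <- tb

  # DP over subsets of present realms: best total overlap assigning slice
  # clusters 1..i to distinct realms (or leaving them unassigned)
  np <- length(pcl)
  best <- stats::setNames(rep(0, 2^np), NULL)
  choice <- vector("list", length(scl))
  for (i in seq_along(scl)) {
    nxt <- best
    pick <- matrix(NA_integer_, 2^np, 1)
    for (mask in 0:(2^np - 1)) {
      v <- best[mask + 1]
      b <- v; pb <- NA_integer_
      for (j in seq_len(np)) {
        if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) > 0) {
          prev <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
          cand <- best[prev + 1] + ov[i, j]
          if (cand > b) { b <- cand; pb <- j }
        }
      }
      nxt[mask + 1] <- b
      pick[mask + 1, 1] <- pb
    }
    best <- nxt
    choice[[i]] <- pick
  }
  # backtrack
  assign <- rep(NA_integer_, length(scl))
  mask <- 2^np - 1
  for (i in rev(seq_along(scl))) {
    pb <- choice[[i]][mask + 1, 1]
    if (!is.na(pb)) {
      assign[i] <- pb
      mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, pb - 1L)))
    }
  }

  map <- character(length(scl)); jac <- numeric(length(scl))
  names(map) <- names(jac) <- as.character(scl)
  for (i in seq_along(scl)) {
    if (is.na(assign[i])) { map[i] <- paste0("ancestral_", scl[i]); jac[i] <- 0; next }
    j <- assign[i]
    inter <- ov[i, j]
    uni <- sum(sp == scl[i]) + sum(pp == pcl[j]) - inter
    jac[i] <- if (uni > 0) inter / uni else 0
    map[i] <- if (jac[i] < min_jaccard) paste0("ancestral_", scl[i])
              else as.character(pcl[j])
  }
  list(map = map, jaccard = jac)
}

#' Reconstruct the chronology of floristic realms by tree slicing
#'
#' For each depth in `times` the tree is sliced, assemblages are collapsed
#' onto lineages, pairwise phylogenetic Simpson beta is computed on the
#' truncated tree, the dendrogram is cut at `pbeta`, and the resulting
#' clusters are matched to the present-day (t = 0) realms. NMDS
#' configurations per slice are Procrustes-aligned to the present by
#' [nmds_trajectory()].
#'
#' @param tree dated ultrametric `phylo`.
#' @param occ binary occurrence matrix (genera x GSUs).
#' @param times slice depths in Ma; must include 0.
#' @param pbeta explained-turnover threshold for the realm cut.
#' @param linkage clustering linkage (default UPGMA).
#' @param run_nmds logical; compute and align per-slice NMDS configurations.
#' @param n_starts random starts per NMDS.
#' @param seed integer seed (NMDS initialization).
#' @return a `chronology` list: `slices` (one per time: `t`, `occ`,
#'   `partition`, `pbeta`, `matched` (per-GSU present-realm label), `map`,
#'   `nmds`), `present` (the t = 0 partition), `times`.
#' @export
chronology_run <- function(tree, occ, times = seq(0, 160, by = 10), pbeta = 0.8,
                           linkage = "average", run_nmds = TRUE, n_starts = 20,
                           seed = 1) {
  if (!0 %in% times) fr_stop("fr_invalid_parameter", "times must include 0")
  check_occurrence(occ)
  times <- sort(unique(times))
  crown <- tree_node_ages(tree)[length(tree$tip.label) + 1L]

  slice_one <- function(t) {
    sl <- withCallingHandlers(
      slice_tree(tree, t),
      fr_slice_warning = function(w) invokeRestart("muffleWarning")
    )
    occ_s <- slice_assemblages(occ, sl$tip_map)
    keep <- colSums(occ_s) > 0
    if (any(!keep)) fr_log("slice %g Ma: dropping %d empty GSU(s)", t, sum(!keep))
    occ_s <- occ_s[, keep, drop = FALSE]
    if (ncol(occ_s) < 3) {
      fr_warn("fr_slice_warning", "slice %g Ma has < 3 GSUs; skipped", t)
      return(NULL)
    }
    if (is.null(sl$sliced_tree) || nrow(occ_s) < 2) {
      part <- as_partition(rep(1L, ncol(occ_s)), colnames(occ_s))
      return(list(t = t, occ = occ_s, partition = part, pbeta = 0, beta = NULL))
    }
    beta <- pairwise_beta(occ_s, sl$sliced_tree, mode = "phylogenetic")
    if (sum(beta) == 0) {
      part <- as_partition(rep(1L, ncol(occ_s)), colnames(occ_s))
      return(list(t = t, occ = occ_s, partition = part, pbeta = 0, beta = beta))
    }
    dend <- build_dendrogram(beta, linkage)
    part <- cut_at_pbeta(dend, beta, pbeta)
    list(t = t, occ = occ_s, partition = part,
         pbeta = attr(part, "pbeta"), beta = beta)
  }

  slices <- lapply(times, slice_one)
  names(slices) <- paste0("t", times)
  slices <- Filter(Negate(is.null), slices)
  present <- slices[["t0"]]$partition

  for (i in seq_along(slices)) {
    m <- match_realms(slices[[i]]$partition, present)
    slices[[i]]$map <- m$map
    slices[[i]]$jaccard <- m$jaccard
    slices[[i]]$matched <- stats::setNames(
      m$map[as.character(slices[[i]]$partition)], names(slices[[i]]$partition))
  }

  chron <- structure(list(slices = slices, present = present,
                          times = vapply(slices, `[[`, 0, "t"),
                          crown_age = crown),
                     class = "chronology")
  if (run_nmds) chron <- nmds_trajectory(chron, n_starts = n_starts, seed = seed)
  chron
}

#' Procrustes-align per-slice NMDS configurations to the present
#'
#' Runs NMDS on each slice's beta matrix and aligns every configuration to
#' the t = 0 configuration by Procrustes rotation/reflection/scaling over the
#' shared GSUs, so that inter-realm distances are comparable through time.
#'
#' @param chron a `chronology` from [chronology_run()].
#' @param n_starts random starts per NMDS.
#' @param seed integer seed.
#' @return the chronology with `nmds` (aligned coordinates) per slice.
#' @export
nmds_trajectory <- function(chron, n_starts = 20, seed = 1) {
  ref <- NULL
  for (i in seq_along(chron$slices)) {
    sl <- chron$slices[[i]]
    if (is.null(sl$beta) || sum(sl$beta) == 0) { chron$slices[[i]]$nmds <- NULL; next }
    ord <- nmds_embed(sl$beta, n_starts = n_starts,
                      seed = substream_seed(seed, "nmds") + i)
    chron$slices[[i]]$nmds <- ord$points
    chron$slices[[i]]$stress <- ord$stress
  }
  t0 <- chron$slices[["t0"]]
  if (is.null(t0$nmds)) return(chron)
  ref <- t0$nmds
  for (i in seq_along(chron$slices)) {
    pts <- chron$slices[[i]]$nmds
    if (is.null(pts)) next
    shared <- intersect(rownames(ref), rownames(pts))
    if (length(shared) < 3)
      fr_stop("fr_consistency_error", "fewer than 3 shared GSUs for alignment at slice %g",
              chron$slices[[i]]$t)
    pr <- vegan::procrustes(ref[shared, , drop = FALSE],
                            pts[shared, , drop = FALSE], symmetric = FALSE)
    aligned <- pr$scale * pts %*% pr$rotation
    aligned <- sweep(aligned, 2, pr$translation[1, ], `+`)
    rownames(aligned) <- rownames(pts)
    chron$slices[[i]]$nmds <- aligned
    chron$slices[[i]]$procrustes_rmse <- sqrt(pr$ss / length(shared))
  }
  chron
}

#' Onset of persistent separation between two GSU sets in a chronology
#'
#' Two realms count as separated at a slice when the majority cluster of one
#' realm's GSUs differs from the majority cluster of the other's. The
#' separation time is the oldest slice depth from which the two sets remain
#' separated at every younger slice.
#'
#' @param chron a `chronology`.
#' @param gsus_p,gsus_q GSU id vectors (e.g. the planted realms).
#' @return separation onset in Ma (`NA` if never separated).
#' @export
separation_time <- function(chron, gsus_p, gsus_q) {
  ts <- sort(chron$times)
  sep <- vapply(ts, function(t) {
    sl <- chron$slices[[paste0("t", t)]]
    part <- sl$partition
    p <- intersect(gsus_p, names(part)); q <- intersect(gsus_q, names(part))
    if (!length(p) || !length(q)) return(FALSE)
    label_mode(part[p]) != label_mode(part[q])
  }, TRUE)
  if (!sep[1]) return(NA_real_)
  run_end <- which(!sep)[1]
  if (is.na(run_end)) max(ts) else ts[run_end - 1]
}
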