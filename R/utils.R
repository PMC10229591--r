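# Internal utilities: typed conditions, seeded substreams, small helpers.

#' Signal a typed florealm error
#'
#' All user-facing failures in the package carry a condition class so callers
#' (and tests) can distinguish e.g. malformed input files from invalid
#' parameters without parsing message strings.
#'
#' @param class condition class, e.g. `"fr_format_error"`.
#' @param msg message (sprintf-style with `...`).
#' @param ... values interpolated into `msg`.
#' @keywords internal
#' @noRd
fr_stop <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "florealm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fr_warn <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  warning(structure(
    class = c(class, "florealm_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fr_log <- function(msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  message("[florealm] ", msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never disturb
#' the caller's random stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# One master seed feeds every stochastic stage through named substreams, so a
# stage can be re-run in isolation and still reproduce its in-pipeline draws.
SUBSTREAMS <- c(tree = 101L, world = 211L, ranges = 307L, climate = 401L,
                paleo = 503L, nmds = 601L, sos = 701L, fuzzy = 769L,
                pipeline = 811L)

substream_seed <- function(seed, stream) {
  off <- SUBSTREAMS[[stream]]
  # keep below 2^31 - 1; multiplier is the classic MINSTD constant
  as.integer((as.numeric(seed) %% 44488L) * 48271 + off)
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper over [mclust::adjustedRandIndex()] that aligns the two label
#' vectors by name before comparing.
#'
#' @param a,b named label vectors over the same set of units.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
ari <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (!length(common)) fr_stop("fr_invalid_parameter", "no shared units between labelings")
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b))
    fr_stop("fr_invalid_parameter", "labelings differ in length and carry no names")
  mclust::adjustedRandIndex(a, b)
}

# mode of a label vector with deterministic tie-break (first in sorted order)
label_mode <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

# validate a binary occurrence matrix (genera x GSUs)
check_occurrence <- function(occ) {
  if (!is.matrix(occ) || is.null(rownames(occ)) || is.null(colnames(occ)))
    fr_stop("fr_format_error", "occurrence matrix must have genus rownames and GSU colnames")
  if (any(is.na(occ)) || !all(occ %in% c(0, 1)))
    fr_stop("fr_format_error", "occurrence matrix must be binary 0/1")
  if (anyDuplicated(rownames(occ)) || anyDuplicated(colnames(occ)))
    fr_stop("fr_format_error", "duplicate genus or GSU ids in occurrence matrix")
  rs <- rowSums(occ); cs <- colSums(occ)
  if (any(rs == 0))
    fr_stop("fr_format_error", "genus with no occurrences: %s", rownames(occ)[which(rs == 0)[1]])
  if (any(cs == 0))
    fr_stop("fr_format_error", "GSU with no genera: %s", colnames(occ)[which(cs == 0)[1]])
  invisible(occ)
}

check_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || nrow(beta) != ncol(beta) || is.null(rownames(beta)))
    fr_stop("fr_format_error", "beta matrix must be square with GSU dimnames")
  if (!isTRUE(all.equal(beta, t(beta), tolerance = 1e-9)))
    fr_stop("fr_format_error", "beta matrix must be symmetric")
  if (any(beta < -1e-12) || any(beta > 1 + 1e-12))
    fr_stop("fr_format_error", "beta values must lie in [0, 1]")
  if (any(abs(diag(beta)) > 1e-12))
    fr_stop("fr_format_error", "beta matrix diagonal must be zero")
  invisible(beta)
}

# partition helpers: a partition is a named integer vector (names = GSU ids)
as_partition <- function(labels, ids = names(labels)) {
  if (is.null(ids)) fr_stop("fr_invalid_parameter", "partition needs GSU names")
  out <- as.integer(factor(labels))
  names(out) <- ids
  out
}

check_partition_covers <- function(partition, ids) {
  miss <- setdiff(ids, names(partition))
  if (length(miss))
    fr_stop("fr_consistency_error", "partition misses %d GSU(s), e.g. %s",
            length(miss), miss[1])
  invisible(partition[ids])
}

# great-circle distance in km on the mean-radius sphere (1 degree at the
# equator = 111.195 km)
EARTH_RADIUS_M <- 6371008.8

gc_dist_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M) / 1000
}
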