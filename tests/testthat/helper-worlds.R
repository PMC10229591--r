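# Shared fixtures: tiny trees and matrices built in code.

# the 3-tip hand-checkable tree used throughout: ((A:1,B:1):1,C:2);
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# occurrence matrix from a named list of GSU -> genus vectors
occ_from_list <- function(assemblages, genera = NULL) {
  genera <- genera %||% sort(unique(unlist(assemblages)))
  gsus <- names(assemblages)
  occ <- matrix(0L, length(genera), length(gsus),
                dimnames = list(sort(genera), sort(gsus)))
  for (g in gsus) occ[assemblages[[g]], g] <- 1L
  occ
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random binary occurrence matrix with no empty rows or columns
rand_occ <- function(tips, n_gsu, p = 0.5) {
  repeat {
    occ <- matrix(rbinom(length(tips) * n_gsu, 1, p), length(tips), n_gsu,
                  dimnames = list(tips, sprintf("s%02d", seq_len(n_gsu))))
    if (all(rowSums(occ) > 0) && all(colSums(occ) > 0)) return(occ)
  }
}

# random symmetric dissimilarity matrix in [0, 1] with zero diagonal
rand_beta <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  m
}

# a 2-block exact dissimilarity matrix: 0 within, 1 between
block_beta <- function(n1 = 3, n2 = 3) {
  n <- n1 + n2
  m <- matrix(1, n, n)
  m[1:n1, 1:n1] <- 0
  m[(n1 + 1):n, (n1 + 1):n] <- 0
  diag(m) <- 0
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  m
}
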