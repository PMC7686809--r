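# Internal helpers shared across modules.

# Remove the spatial mean of each column (sample/map) of a channels x samples matrix.
remove_map_means <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# Normalize each column to unit Euclidean norm; zero columns are left at zero.
unit_norm_cols <- function(x) {
  nrm <- sqrt(colSums(x^2))
  nz <- nrm > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2L, nrm[nz], "/")
  x
}

# Deterministic sign convention: the channel with the largest |value| is positive.
fix_map_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

# Run a block of code with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so simulation functions are reproducible without
# clobbering the session stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Stationary distribution of a finite Markov chain with transition matrix P
# (rows sum to 1): solves pi' P = pi', sum(pi) = 1 by least squares.
stationary_distribution <- function(P) {
  K <- nrow(P)
  A <- rbind(t(P) - diag(K), rep(1, K))
  b <- c(rep(0, K), 1)
  as.vector(qr.solve(A, b))
}

# Exact maximum-weight assignment for a small square score matrix, by dynamic
# programming over column subsets (Held-Karp style). Returns the permutation
# sigma with sigma[i] the column assigned to row i.
solve_assignment <- function(S) {
  k <- nrow(S)
  stopifnot(ncol(S) == k)
  nmask <- bitwShiftL(1L, k)
  best <- rep(-Inf, nmask)
  choice <- matrix(0L, nrow = nmask, ncol = 1L)
  best[1L] <- 0
  # best[mask] = best score assigning rows 1..popcount(mask) to columns in mask
  popcount <- vapply(0:(nmask - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) != 0L), integer(1))
  for (mask in 1:(nmask - 1L)) {
    row <- popcount[mask + 1L]
    for (col in seq_len(k)) {
      bit <- bitwShiftL(1L, col - 1L)
      if (bitwAnd(mask, bit) == 0L) next
      prev <- bitwXor(mask, bit)
      sc <- best[prev + 1L] + S[row, col]
      if (sc > best[mask + 1L]) {
        best[mask + 1L] <- sc
        choice[mask + 1L, 1L] <- col
      }
    }
  }
  sigma <- integer(k)
  mask <- nmask - 1L
  for (row in rev(seq_len(k))) {
    col <- choice[mask + 1L, 1L]
    sigma[row] <- col
    mask <- bitwXor(mask, bitwShiftL(1L, col - 1L))
  }
  sigma
}
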