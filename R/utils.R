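# Internal numerical helpers shared across the package.

#' Evaluate an expression under a fixed RNG state
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  }
  force(expr)
}

# Derive a stream of independent sub-seeds (< 2^31) from one integer seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Symmetric inverse square root of a symmetric positive-definite matrix
#' @noRd
sym_inv_sqrt <- function(m, eig_floor = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  floor_val <- eig_floor * max(e$values, 0)
  vals <- pmax(e$values, floor_val)
  if (any(vals <= 0)) {
    stop("matrix is singular and cannot be inverted; increase shrinkage")
  }
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

# Magnitude of the analytic signal (envelope) of a real vector, via FFT.
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Centered moving average with window length k (odd preferred); edges use
# partial windows so the output length equals the input length.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Lower-triangle (off-diagonal) vector of a square matrix, column-major.
lower_tri <- function(m) m[lower.tri(m)]

# Number of condition pairs for n conditions.
n_pairs <- function(n) n * (n - 1L) / 2L

# Rebuild a symmetric zero-diagonal matrix from its lower-triangle vector.
from_lower_tri <- function(v, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m + t(m)
}

# Index map: for an n x n symmetric matrix stored as a lower-triangle vector,
# full_index_matrix()[i, j] gives the position of entry (i, j) in that vector
# (diagonal entries map to NA). Used to permute RDMs by condition label
# without rebuilding matrices.
full_index_matrix <- function(n) {
  idx <- matrix(NA_integer_, n, n)
  idx[lower.tri(idx)] <- seq_len(n_pairs(n))
  idx[upper.tri(idx)] <- t(idx)[upper.tri(idx)]
  idx
}

# Column-wise ranks (average ties) of a matrix.
col_ranks <- function(m) apply(m, 2L, rank)

# Standardize columns to zero mean / unit variance (for fast rank correlations
# via cross products). Constant columns become all-zero.
col_standardize <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  m <- sweep(m, 2L, mu)
  s <- sqrt(colSums(m^2))
  s[s == 0] <- 1
  sweep(m, 2L, s, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
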