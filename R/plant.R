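#' Specification of a planted representational geometry
#'
#' A `plant_spec` describes the condition geometry a synthetic-data generator
#' must realize: the target RDM, where it lives (a vertex/feature set for
#' spatial plants, or a time window plus frequency band for temporal plants),
#' the amplitude of the condition structure, and the noise level.
#'
#' @param target_rdm an [rdm] of pairwise squared distances to plant.
#' @param region integer vector of vertex/feature indices (spatial plants).
#' @param window numeric length-2, half-open `[t0, t1)` window in ms
#'   (temporal plants).
#' @param band numeric length-2 `[lo, hi]` frequency band in Hz, or a band
#'   preset name (temporal plants).
#' @param signal_scale amplitude multiplier of the condition structure.
#' @param noise_sd additive noise standard deviation (>= 0).
#' @param seed integer seed making the generated dataset reproducible.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(target_rdm, region = NULL, window = NULL, band = NULL,
                       signal_scale = 1, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(target_rdm, "rdm"))
  if (min(target_rdm) < 0) stop("target RDM entries must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(region) && length(region) == 0L) stop("region must be non-empty")
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1L] < window[2L])
  }
  structure(list(target_rdm = target_rdm, region = region, window = window,
                 band = band, signal_scale = signal_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Embed a target RDM as condition patterns
#'
#' Constructs a conditions x features pattern matrix whose pairwise squared
#' Euclidean distances reproduce the entries of `target_rdm` exactly (up to a
#' single global scale: here scale 1, provided the target is Euclidean-
#' embeddable). Two constructions are available. The default is classical
#' multidimensional scaling of the double-centered squared-distance matrix,
#' which needs at most `n_conditions - 1` dimensions and reproduces the
#' target distances exactly. With `equal_norms = TRUE` the patterns are
#' drawn from the Gram matrix `G = c 11' - D/2` (with the target first
#' blended towards a full-rank simplex geometry by a strictly monotone
#' uniform shift, and `c` grown until G is positive semi-definite): every
#' condition pattern then has the same norm and the pairwise squared
#' distances are an exactly affine -- hence rank-identical -- transform of
#' the target. Equal norms make Pearson correlations between patterns
#' exactly affine in the planted distances, which the channel-correlation
#' model-RDM generators rely on. Unused feature dimensions are filled by a
#' seeded random rotation, so all features carry signal while distances are
#' untouched.
#'
#' @param target_rdm an [rdm]; entries are interpreted as squared distances.
#' @param n_features number of features (columns) of the output; must be at
#'   least the embedding rank of the target.
#' @param seed integer seed for the rotation (determinism: identical seeds
#'   give bit-identical patterns).
#' @param equal_norms logical; use the equal-norm Gram construction.
#' @return numeric matrix, conditions x features, with condition labels as
#'   row names.
#' @examples
#' d <- matrix(c(0, 4, 4, 0), 2, 2)
#' p <- plant_condition_patterns(rdm(d, c("a", "b")), n_features = 3)
#' dist(p)  # sqrt(4) = 2
#' @export
plant_condition_patterns <- function(target_rdm, n_features, seed = 1L,
                                     equal_norms = FALSE) {
  stopifnot(inherits(target_rdm, "rdm"))
  D <- unclass(target_rdm)
  if (min(D) < 0) stop("target RDM entries must be nonnegative")
  n <- nrow(D)
  if (equal_norms) {
    # Regularize towards a full-rank simplex geometry: adding a common
    # constant to every off-diagonal squared distance is strictly monotone
    # (rank order, including ties, is preserved exactly) and lifts the
    # centered Gram off its low-rank null space, so the equal-norm Gram
    # G = cc 11' - D/2 becomes PSD at a small common norm cc. Small cc keeps
    # the relative spread of pattern correlations large, which the
    # correlation-RDM generators need for noise robustness.
    M <- max(D)
    if (M > 0) {
      gamma <- 0.25
      D <- (1 - gamma) * D + gamma * M * (1 - diag(n))
    }
    cc <- max(.Machine$double.eps, max(D) / 2)
    for (k in 0:20) {
      G <- cc * 2^k - D / 2
      e <- eigen(G, symmetric = TRUE)
      if (min(e$values) >= -1e-9 * max(e$values)) break
    }
  } else {
    J <- diag(n) - 1 / n
    B <- -0.5 * J %*% D %*% J
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  }
  tol <- 1e-9 * max(abs(e$values), 1)
  if (min(e$values) < -1e-6 * max(abs(e$values), 1)) {
    warning("target RDM is not exactly Euclidean-embeddable; ",
            "negative eigenvalues clipped, distances are approximate")
  }
  vals <- pmax(e$values, 0)
  keep <- vals > tol
  r <- sum(keep)
  if (n_features < r) {
    stop(sprintf(
      "n_features (%d) is below the embedding rank of the target RDM (%d)",
      n_features, r))
  }
  X <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(vals[keep]), r)
  X <- cbind(X, matrix(0, n, n_features - r))
  # Seeded random rotation: distributes signal over all features without
  # changing pairwise distances (or norms).
  Q <- with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(n_features^2), n_features)))
  })
  out <- X %*% Q
  rownames(out) <- rdm_labels(target_rdm)
  out
}

#' Sample a low-dimensional random condition geometry
#'
#' Draws `n_conditions` points in `dim` dimensions and returns their pairwise
#' squared Euclidean distances as an [rdm]. Low-dimensional targets can be
#' planted into feature sets with few features (the embedding rank equals
#' `dim`).
#'
#' @param labels condition labels (their length sets the number of
#'   conditions).
#' @param dim dimensionality of the generating configuration.
#' @param seed integer seed.
#' @return an [rdm] of kind `data_crossnobis` (squared distances).
#' @export
random_geometry_rdm <- function(labels, dim = 3L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  pts <- with_seed(seed, matrix(stats::rnorm(n * dim), n, dim))
  D <- as.matrix(stats::dist(pts))^2
  rdm(D, labels = labels, kind = "data_crossnobis")
}
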