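#' Adaptive-threshold activity onset detection
#'
#' Detects movement/muscle activity onset in a single-channel signal via its
#' analytic-signal (Hilbert) envelope: the envelope is moving-average
#' smoothed, an adaptive threshold (envelope mean + 1 SD, recomputed per
#' call) is applied, and the onset is the first sample at which the smoothed
#' envelope exceeds the threshold continuously for at least
#' `duration_threshold_ms`. Short supra-threshold transients are thereby
#' ignored.
#'
#' @param signal numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param duration_threshold_ms minimum supra-threshold duration (default
#'   200 ms).
#' @param smoothing_ms moving-average smoothing window (default 5 ms; 0
#'   disables smoothing).
#' @return the onset sample index (1-based), or `NA_integer_` if no
#'   sufficiently long supra-threshold segment exists (e.g. a constant
#'   signal).
#' @export
detect_onset <- function(signal, fs, duration_threshold_ms = 200,
                         smoothing_ms = 5) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  dur_samples <- max(1L, as.integer(round(duration_threshold_ms / 1000 * fs)))
  if (length(signal) <= dur_samples) {
    stop("signal shorter than the duration threshold")
  }
  # subtract the median (the resting level, robust to the activity itself)
  # before taking the analytic-signal envelope; mirror-pad so the circular
  # FFT Hilbert transform sees no wrap-around discontinuity
  x <- signal - stats::median(signal)
  env <- analytic_envelope(c(x, rev(x)))[seq_along(x)]
  if (smoothing_ms > 0) {
    env <- moving_average(env, as.integer(round(smoothing_ms / 1000 * fs)))
  }
  # adaptive threshold: resting envelope level + 1 SD, recomputed per trial;
  # the lower quartile estimates the resting level robustly (the mean or
  # median would be dragged up by the activity itself and by the slow decay
  # of the Hilbert component around sustained activity)
  thr <- stats::quantile(env, 0.25, names = FALSE) + stats::sd(env)
  if (!is.finite(thr) || stats::sd(env) == 0) return(NA_integer_)
  above <- env > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= dur_samples)
  if (!length(ok)) return(NA_integer_)
  s <- starts[ok[1L]]
  # refine to the steepest envelope rise near the crossing: the smoothed
  # envelope starts rising before abrupt activity (Hilbert precursor), so
  # the first crossing alone is systematically early for sharp onsets
  hi <- min(length(env) - 1L, s + dur_samples)
  if (hi > s) {
    slopes <- env[(s + 1L):(hi + 1L)] - env[s:hi]
    s <- s + which.max(slopes) - 1L
  }
  as.integer(s)
}

#' Earliest onset across channels of one trial
#'
#' Runs [detect_onset] on every channel of a trial and returns the earliest
#' detected onset (a conservative estimate of movement onset), in ms relative
#' to the epoch's alignment event. Trials in which no channel yields an onset
#' are flagged with `NA` for exclusion.
#'
#' @param epochs a [channel_epochs] object.
#' @param trial trial index.
#' @param ... passed to [detect_onset].
#' @return onset time in ms, or `NA_real_` if no channel detects an onset.
#' @export
earliest_onset <- function(epochs, trial, ...) {
  stopifnot(inherits(epochs, "channel_epochs"))
  d <- dim(epochs$data)
  idx <- vapply(seq_len(d[2L]), function(ch) {
    detect_onset(epochs$data[trial, ch, ], fs = epochs$fs, ...)
  }, integer(1L))
  if (all(is.na(idx))) return(NA_real_)
  epochs$t0_ms + (min(idx, na.rm = TRUE) - 1L) / epochs$fs * 1000
}

#' Cross-modality onset validation
#'
#' Compares onset estimates from two modalities (e.g. data glove vs EMG) and
#' flags trials whose discrepancy exceeds `max_discrepancy_ms` (default
#' +/- 100 ms) for exclusion. Trials with a missing onset in either modality
#' are also excluded.
#'
#' @param onset_a,onset_b numeric vectors of per-trial onsets in ms.
#' @param max_discrepancy_ms exclusion threshold in ms.
#' @return logical vector: `TRUE` where the trial is kept.
#' @export
validate_onsets <- function(onset_a, onset_b, max_discrepancy_ms = 100) {
  stopifnot(length(onset_a) == length(onset_b))
  keep <- !is.na(onset_a) & !is.na(onset_b) &
    abs(onset_a - onset_b) <= max_discrepancy_ms
  keep
}

#' Per-condition trial averages
#'
#' Averages trials within each condition, preserving channel and sample
#' dimensions.
#'
#' @param epochs a [channel_epochs] object.
#' @param conditions condition order of the output; defaults to the unique
#'   labels in order of first appearance. Conditions without trials are
#'   rejected.
#' @return numeric array, conditions x channels x samples, with condition
#'   labels on the first dimension.
#' @export
average_by_condition <- function(epochs, conditions = NULL) {
  stopifnot(inherits(epochs, "channel_epochs"))
  conditions <- conditions %||% unique(epochs$labels)
  missing <- setdiff(conditions, epochs$labels)
  if (length(missing)) {
    stop("conditions without any trial: ", paste(missing, collapse = ", "))
  }
  d <- dim(epochs$data)
  out <- array(NA_real_, c(length(conditions), d[2L], d[3L]),
               dimnames = list(conditions, NULL, NULL))
  for (i in seq_along(conditions)) {
    sel <- epochs$labels == conditions[i]
    out[i, , ] <- colMeans(epochs$data[sel, , , drop = FALSE], dims = 1L)
  }
  out
}

#' Channel-wise correlation model RDM (1 - r)
#'
#' For every condition pair, each channel's average timecourses are
#' correlated (Pearson), the per-channel correlations are Fisher
#' z-transformed and averaged across channels, the average is transformed
#' back, and the dissimilarity is 1 minus the resulting correlation. This is
#' the construction behind both the kinematic (data glove) and the muscle
#' (EMG envelope) model RDMs.
#'
#' Channels whose timecourse is constant for a pair (undefined correlation)
#' are dropped from that pair's average with a warning; correlations of
#' exactly +/- 1 are clipped to +/- (1 - 1e-10) before `atanh` so that
#' averaging stays finite on noiseless inputs.
#'
#' @param cond_avgs conditions x channels x samples array, as returned by
#'   [average_by_condition].
#' @return an [rdm] of kind `model_1mr`.
#' @export
channel_correlation_rdm <- function(cond_avgs) {
  stopifnot(length(dim(cond_avgs)) == 3L)
  n <- dim(cond_avgs)[1L]
  n_ch <- dim(cond_avgs)[2L]
  if (dim(cond_avgs)[3L] < 2L) stop("need at least 2 samples per channel")
  labels <- dimnames(cond_avgs)[[1L]] %||% paste0("cond", seq_len(n))
  sds <- apply(cond_avgs, c(1L, 2L), stats::sd)
  vals <- matrix(0, n, n)
  dropped_any <- FALSE
  for (k in seq_len(n - 1L)) {
    for (l in (k + 1L):n) {
      use <- sds[k, ] > 0 & sds[l, ] > 0
      if (!all(use)) dropped_any <- TRUE
      if (!any(use)) {
        stop(sprintf("all channels constant for pair (%s, %s)",
                     labels[k], labels[l]))
      }
      r <- vapply(which(use), function(ch) {
        stats::cor(cond_avgs[k, ch, ], cond_avgs[l, ch, ])
      }, numeric(1L))
      r <- pmin(pmax(r, -(1 - 1e-10)), 1 - 1e-10)
      rbar <- tanh(mean(atanh(r)))
      vals[k, l] <- vals[l, k] <- 1 - rbar
    }
  }
  if (dropped_any) {
    warning("constant channel timecourses dropped from some pair averages")
  }
  rdm(vals, labels = labels, kind = "model_1mr")
}

#' Multivariate noise normalization of trials
#'
#' Whitens the channel dimension of epoched trials by the error covariance
#' across channels, estimated from within-condition deviations (each trial
#' minus its condition-mean trial) pooled over trials and samples. The
#' covariance is shrunk towards its diagonal by `shrinkage`, and the trials
#' are multiplied along the channel dimension by the inverse of its lower
#' Cholesky factor. After normalization the pooled error covariance is
#' (approximately) the identity. Triangular whitening is used here because it
#' makes the normalized output exactly invariant to per-channel rescaling of
#' the input (any whitening yields identical crossnobis distances; the
#' triangular one also fixes the output itself).
#'
#' @param epochs a [channel_epochs] object with >= 2 trials per condition.
#' @param shrinkage fraction in \[0, 1\] blending the covariance with its
#'   diagonal.
#' @return a [channel_epochs] object with whitened channels.
#' @export
mnn_trials <- function(epochs, shrinkage = 0.05) {
  stopifnot(inherits(epochs, "channel_epochs"))
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  counts <- table(epochs$labels)
  if (any(counts < 2L)) {
    stop("every condition needs >= 2 trials to estimate the error covariance")
  }
  d <- dim(epochs$data)
  conds <- unique(epochs$labels)
  S <- matrix(0, d[2L], d[2L])
  n_obs <- 0L
  for (cond in conds) {
    sel <- which(epochs$labels == cond)
    avg <- colMeans(epochs$data[sel, , , drop = FALSE], dims = 1L)
    for (i in sel) {
      E <- epochs$data[i, , ] - avg  # channels x samples
      S <- S + tcrossprod(E)
      n_obs <- n_obs + d[3L]
    }
  }
  S <- S / n_obs
  S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), d[2L])
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (is.null(L)) {
    stop("error covariance is singular; use shrinkage > 0")
  }
  W <- solve(L)  # lower-triangular whitener, W S W' = I
  for (i in seq_len(d[1L])) {
    epochs$data[i, , ] <- W %*% epochs$data[i, , ]
  }
  epochs
}

#' Ethological action model RDM
#'
#' A categorical model RDM: movement pairs in the same ethological category
#' (precision prehensile, power prehensile, nonprehensile) get dissimilarity
#' 0, pairs in different categories get 1. The binary coding is the default;
#' `between_value` allows a graded alternative.
#'
#' @param movements a [movement_set].
#' @param between_value dissimilarity assigned across categories (default 1).
#' @return an [rdm] of kind `model_categorical` (or `data_crossnobis` when a
#'   non-binary `between_value` is used).
#' @export
ethological_rdm <- function(movements, between_value = 1) {
  stopifnot(inherits(movements, "movement_set"))
  cat <- movements$categories
  vals <- outer(cat, cat, FUN = function(a, b) ifelse(a == b, 0, between_value))
  kind <- if (identical(between_value, 1)) "model_categorical" else
    "data_crossnobis"
  rdm(vals, labels = movements$labels, kind = kind)
}

#' Deterministic dendrogram leaf order of an RDM
#'
#' Average-linkage agglomerative clustering of the RDM (treated as a distance
#' matrix), with ties broken deterministically by lowest condition index: at
#' every step the merged pair is the one with minimal linkage distance and,
#' among ties, smallest (first, then second) lowest original index; leaf
#' order expands each merge with the lower-index subtree first. On an
#' all-equal RDM this yields the identity permutation.
#'
#' @param x an [rdm] (asymmetric input is rejected by the `rdm` constructor).
#' @return integer permutation of condition indices (the leaf order).
#' @export
cluster_order <- function(x) {
  stopifnot(inherits(x, "rdm"))
  D <- unclass(x)
  n <- nrow(D)
  if (n == 1L) return(1L)
  # Active clusters: list of member index vectors (original order preserved),
  # keyed by their minimal member index for tie-breaking.
  clusters <- lapply(seq_len(n), identity)
  dmat <- D
  diag(dmat) <- Inf
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  repeat {
    act <- which(active)
    if (length(act) == 1L) break
    # find minimal distance pair among active clusters, tie-break by the
    # smaller (min-member, then other min-member) indices
    best <- NULL
    best_d <- Inf
    for (ai in seq_along(act)) {
      i <- act[ai]
      if (ai == length(act)) break
      for (j in act[(ai + 1L):length(act)]) {
        dij <- dmat[i, j]
        if (dij < best_d - 1e-12) {
          best <- c(i, j); best_d <- dij
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    # merge j into i; order members with the lower-index subtree first
    first <- if (min(clusters[[i]]) <= min(clusters[[j]])) i else j
    second <- if (first == i) j else i
    merged <- c(clusters[[first]], clusters[[second]])
    # average linkage update
    for (k in which(active)) {
      if (k == i || k == j) next
      dmat[i, k] <- dmat[k, i] <-
        (sizes[i] * dmat[i, k] + sizes[j] * dmat[j, k]) / (sizes[i] + sizes[j])
    }
    clusters[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  clusters[[which(active)]]
}

#' Stress-minimizing (nonclassical) multidimensional scaling
#'
#' Embeds an RDM into `n_dims` dimensions by minimizing metric stress with
#' SMACOF-style majorization (iterated Guttman transforms). The first start
#' is the classical-scaling solution; the remaining `n_restarts - 1` starts
#' are seeded random configurations, and the best solution by stress is
#' returned. Reported stress is normalized Kruskal stress-1,
#' `sqrt(sum((delta - d)^2) / sum(d^2))`.
#'
#' @param x an [rdm]; entries are treated as target distances.
#' @param n_dims embedding dimensionality (default 3); must be below the
#'   number of conditions.
#' @param n_restarts number of starts (default 100).
#' @param seed integer seed for the random restarts.
#' @param max_iter,tol majorization iteration controls.
#' @return a list of class `mds_embedding` with elements `points`
#'   (conditions x n_dims) and `stress`.
#' @export
mds_embed <- function(x, n_dims = 3L, n_restarts = 100L, seed = 1L,
                      max_iter = 500L, tol = 1e-12) {
  stopifnot(inherits(x, "rdm"))
  n <- nrow(x)
  if (n_dims < 1L) stop("n_dims must be >= 1")
  if (n_dims >= n) stop("n_dims must be below the number of conditions")
  delta <- unclass(x)
  if (max(delta) == 0) {
    pts <- matrix(0, n, n_dims, dimnames = list(rdm_labels(x), NULL))
    return(structure(list(points = pts, stress = 0), class = "mds_embedding"))
  }
  smacof_run <- function(X) {
    d <- as.matrix(stats::dist(X))
    s_old <- Inf
    for (it in seq_len(max_iter)) {
      dm <- d
      dm[dm == 0] <- Inf  # avoid division by zero; B entry becomes 0
      Bv <- -delta / dm
      diag(Bv) <- 0
      diag(Bv) <- -rowSums(Bv)
      X <- (Bv %*% X) / n
      d <- as.matrix(stats::dist(X))
      s <- sum((delta - d)^2) / 2
      if (abs(s_old - s) < tol * max(s, 1)) break
      s_old <- s
    }
    list(X = X, raw = s, d = d)
  }
  init_classical <- suppressWarnings(
    stats::cmdscale(stats::as.dist(delta), k = n_dims))
  if (ncol(init_classical) < n_dims) {
    init_classical <- cbind(init_classical,
                            matrix(0, n, n_dims - ncol(init_classical)))
  }
  seeds <- derive_seeds(seed, max(0L, n_restarts - 1L))
  best <- smacof_run(init_classical)
  if (n_restarts > 1L) {
    scale0 <- max(delta)
    for (i in seq_len(n_restarts - 1L)) {
      X0 <- with_seed(seeds[i], matrix(stats::rnorm(n * n_dims, sd = scale0),
                                       n, n_dims))
      cand <- smacof_run(X0)
      if (cand$raw < best$raw) best <- cand
    }
  }
  stress1 <- sqrt(sum((delta - best$d)^2) / sum(best$d^2))
  pts <- best$X
  dimnames(pts) <- list(rdm_labels(x), NULL)
  structure(list(points = pts, stress = stress1), class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points in %d dims, stress-1 = %.4g\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}
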