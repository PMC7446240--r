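# Sliding-window temporal RSA on band-filtered source time series.

#' Frequency band presets
#'
#' Canonical oscillatory bands: alpha 7-14 Hz, beta 15-30 Hz, gamma
#' 30-100 Hz, broadband 7-100 Hz.
#'
#' @param band preset name or numeric `c(lo, hi)` in Hz.
#' @return numeric length-2 vector `c(lo, hi)`.
#' @export
band_limits <- function(band) {
  if (is.numeric(band)) {
    stopifnot(length(band) == 2L, band[1L] > 0, band[1L] < band[2L])
    return(as.numeric(band))
  }
  presets <- list(alpha = c(7, 14), beta = c(15, 30), gamma = c(30, 100),
                  broadband = c(7, 100))
  if (!band %in% names(presets)) {
    stop("unknown band '", band, "'; use ",
         paste(names(presets), collapse = "/"), " or c(lo, hi)")
  }
  presets[[band]]
}

#' Zero-phase band-pass filter epochs
#'
#' Applies a 4th-order Butterworth band-pass forwards and backwards
#' (zero phase) to every trial and channel.
#'
#' @param epochs a [channel_epochs] object.
#' @param band preset name or `c(lo, hi)` in Hz; the upper edge must stay
#'   below the Nyquist frequency.
#' @param order Butterworth design order (default 4).
#' @return a [channel_epochs] object with a `band` element.
#' @export
bandpass <- function(epochs, band, order = 4L) {
  stopifnot(inherits(epochs, "channel_epochs"))
  bl <- band_limits(band)
  if (bl[2L] >= epochs$fs / 2) {
    stop(sprintf("band upper edge %g Hz reaches the Nyquist frequency (%g Hz)",
                 bl[2L], epochs$fs / 2))
  }
  flt <- signal::butter(order, bl / (epochs$fs / 2), type = "pass")
  d <- dim(epochs$data)
  n <- d[3L]
  # zero-phase application: multiply every series' spectrum by the filter's
  # squared magnitude response (the forward-backward gain), in one pass over
  # a samples x (trials * channels) matrix
  w <- 2 * pi * (seq_len(n) - 1L) / n
  ew <- exp(-1i * outer(w, seq_along(flt$b) - 1L))
  H <- as.vector(ew %*% flt$b) / as.vector(ew %*% flt$a)
  gain2 <- Mod(H)^2
  X <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), nrow = n)
  Y <- Re(stats::mvfft(stats::mvfft(X) * gain2, inverse = TRUE)) / n
  epochs$data <- aperm(array(Y, c(n, d[1L], d[2L])), c(2L, 3L, 1L))
  epochs$band <- if (is.character(band)) band else paste0(bl[1L], "-", bl[2L], "Hz")
  epochs
}

#' Partition trials and average within partitions
#'
#' Splits each condition's trials into `n_partitions` partitions (seeded
#' shuffle, then round-robin so sizes differ by at most one trial, with the
#' remainder going to the first partitions) and averages within each
#' partition. The partition means are the cross-validation folds of the
#' temporal analysis.
#'
#' @param epochs a [channel_epochs] object.
#' @param n_partitions number of partitions (default 10).
#' @param seed integer seed for the trial shuffle.
#' @return an object of class `partition_means`: `data` (partitions x
#'   conditions x channels x samples array), `labels`, `fs`, `t0_ms`.
#' @export
partition_average <- function(epochs, n_partitions = 10L, seed = 1L) {
  stopifnot(inherits(epochs, "channel_epochs"))
  n_partitions <- as.integer(n_partitions)
  conds <- unique(epochs$labels)
  counts <- table(epochs$labels)
  short <- names(counts)[counts < n_partitions]
  if (length(short)) {
    stop("too few trials for ", n_partitions, " partitions in condition(s): ",
         paste(short, collapse = ", "))
  }
  d <- dim(epochs$data)
  out <- array(0, c(n_partitions, length(conds), d[2L], d[3L]),
               dimnames = list(NULL, conds, NULL, NULL))
  seeds <- derive_seeds(seed, length(conds))
  for (ci in seq_along(conds)) {
    idx <- which(epochs$labels == conds[ci])
    idx <- with_seed(seeds[ci], sample(idx))
    assignment <- rep_len(seq_len(n_partitions), length(idx))
    for (p in seq_len(n_partitions)) {
      sel <- idx[assignment == p]
      out[p, ci, , ] <- colMeans(epochs$data[sel, , , drop = FALSE], dims = 1L)
    }
  }
  structure(list(data = out, labels = conds, fs = epochs$fs,
                 t0_ms = epochs$t0_ms), class = "partition_means")
}

#' Sliding-window scheme
#'
#' Half-open windows `[s, s + width)` advanced in steps of `step_ms` across
#' the half-open epoch, under the end-strict convention: a window is kept
#' only if its end lies strictly before the epoch end. A 2 s epoch with
#' 20 ms windows and 5 ms steps yields 396 windows.
#'
#' @param width_ms window width in ms.
#' @param step_ms step between window starts in ms (> 0).
#' @param epoch half-open epoch `[t_start, t_end)` in ms.
#' @return an object of class `window_scheme`.
#' @export
window_scheme <- function(width_ms = 20, step_ms = 5, epoch = c(-500, 1500)) {
  stopifnot(length(epoch) == 2L, epoch[1L] < epoch[2L])
  if (step_ms <= 0) stop("step_ms must be > 0")
  if (width_ms > diff(epoch)) stop("window width exceeds the epoch")
  structure(list(width_ms = width_ms, step_ms = step_ms, epoch = epoch),
            class = "window_scheme")
}

#' @rdname window_scheme
#' @export
window_starts <- function(scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  starts <- seq(scheme$epoch[1L], scheme$epoch[2L], by = scheme$step_ms)
  starts[starts + scheme$width_ms < scheme$epoch[2L]]  # end-strict
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("<window_scheme> width %g ms, step %g ms, epoch [%g, %g) ms: %d windows\n",
              x$width_ms, x$step_ms, x$epoch[1L], x$epoch[2L],
              length(window_starts(x))))
  invisible(x)
}

#' Sliding-window crossnobis RDM timecourse
#'
#' Per window, the feature vector of each condition and partition is the
#' concatenation of all (channel x within-window sample) values; the
#' crossnobis RDM is computed across partitions (each partition in turn as
#' fold A against the mean of the rest). With `mnn = TRUE` the channel
#' dimension is first noise-normalized by the error covariance across
#' channels estimated from partition-level deviations from the condition
#' means (shrinkage-regularized, triangular whitening).
#'
#' @param pm a `partition_means` object (see [partition_average]).
#' @param scheme a [window_scheme].
#' @param mnn apply multivariate noise normalization (default TRUE).
#' @param shrinkage covariance shrinkage for the normalization.
#' @param normalize_v divide distances by the feature count (default TRUE).
#' @return an object of class `rdm_timecourse`: `starts_ms`, `rdms`
#'   (n x n x n_windows array), `labels`, `scheme`, `band`.
#' @export
sliding_rdms <- function(pm, scheme = window_scheme(), mnn = TRUE,
                         shrinkage = 0.05, normalize_v = TRUE) {
  stopifnot(inherits(pm, "partition_means"), inherits(scheme, "window_scheme"))
  dm <- dim(pm$data)
  if (dm[1L] < 2L) stop("cross-validation needs >= 2 partitions")
  if (mnn) pm <- mnn_partition_means(pm, shrinkage = shrinkage)
  t_ms <- pm$t0_ms + (seq_len(dm[4L]) - 1L) / pm$fs * 1000
  starts <- window_starts(scheme)
  n <- dm[2L]
  n_ch <- dm[3L]
  # flatten each partition once: conditions x (channel, sample) features
  part_mats <- lapply(seq_len(dm[1L]), function(p) {
    matrix(pm$data[p, , , , drop = FALSE], nrow = n)
  })
  rdms <- array(NA_real_, c(n, n, length(starts)),
                dimnames = list(pm$labels, pm$labels, NULL))
  for (w in seq_along(starts)) {
    sel <- which(t_ms >= starts[w] & t_ms < starts[w] + scheme$width_ms)
    if (!length(sel)) stop("empty window at ", starts[w], " ms")
    cols <- rep((sel - 1L) * n_ch, each = n_ch) + seq_len(n_ch)
    folds <- lapply(part_mats, function(m) m[, cols, drop = FALSE])
    d <- crossnobis_rdm(fold_patterns(folds, labels = pm$labels),
                        scheme = "loo", normalize_v = normalize_v)
    rdms[, , w] <- unclass(d)
  }
  structure(list(starts_ms = starts, rdms = rdms, labels = pm$labels,
                 scheme = scheme, band = attr(pm, "band")),
            class = "rdm_timecourse")
}

# Noise-normalize the channel dimension of partition means using the error
# covariance across channels from partition deviations around condition
# means, pooled over partitions, conditions and samples.
mnn_partition_means <- function(pm, shrinkage = 0.05) {
  d <- dim(pm$data)
  cond_mean <- colMeans(pm$data, dims = 1L)       # conditions x channels x samples
  S <- matrix(0, d[3L], d[3L])
  n_obs <- 0L
  for (p in seq_len(d[1L])) {
    for (ci in seq_len(d[2L])) {
      E <- pm$data[p, ci, , ] - cond_mean[ci, , ]  # channels x samples
      S <- S + tcrossprod(E)
      n_obs <- n_obs + d[4L]
    }
  }
  S <- S / n_obs
  S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), d[3L])
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (is.null(L)) stop("channel error covariance is singular; increase shrinkage")
  W <- solve(L)
  for (p in seq_len(d[1L])) {
    for (ci in seq_len(d[2L])) {
      pm$data[p, ci, , ] <- W %*% pm$data[p, ci, , ]
    }
  }
  pm
}

#' Model-correlation timecourse
#'
#' Spearman (or, given a control model, partial Spearman) correlation of the
#' data RDM at every window with a candidate model RDM.
#'
#' @param rdm_tc an `rdm_timecourse`.
#' @param model an [rdm].
#' @param control optional competing-model [rdm] to partial out.
#' @return numeric vector of rho values with attribute `starts_ms`.
#' @export
model_timecourse <- function(rdm_tc, model, control = NULL) {
  stopifnot(inherits(rdm_tc, "rdm_timecourse"))
  if (!identical(rdm_labels(model), rdm_tc$labels)) {
    model <- rdm_reorder(model, rdm_tc$labels)
  }
  D <- tc_rank_matrix(rdm_tc)
  mstd <- col_standardize(matrix(rank(lower_tri(unclass(model)))))
  if (is.null(control)) {
    rho <- as.vector(crossprod(D, mstd))
  } else {
    if (!identical(rdm_labels(control), rdm_tc$labels)) {
      control <- rdm_reorder(control, rdm_tc$labels)
    }
    cstd <- col_standardize(matrix(rank(lower_tri(unclass(control)))))
    r_dm <- as.vector(crossprod(D, mstd))
    r_dc <- as.vector(crossprod(D, cstd))
    r_mc <- as.vector(crossprod(mstd, cstd))
    rho <- (r_dm - r_dc * r_mc) / sqrt((1 - r_dc^2) * (1 - r_mc^2))
  }
  attr(rho, "starts_ms") <- rdm_tc$starts_ms
  rho
}

# Ranked, standardized lower-tri vectors of all window RDMs (pairs x windows)
tc_rank_matrix <- function(rdm_tc) {
  n <- length(rdm_tc$labels)
  sel <- lower.tri(matrix(0, n, n))
  v <- apply(rdm_tc$rdms, 3L, function(m) m[sel])
  col_standardize(col_ranks(v))
}

#' Cluster-based permutation inference on a model timecourse
#'
#' Tests when a candidate model is encoded: the model RDM's condition labels
#' are shuffled `n_perm` times and the correlation timecourse recomputed to
#' build a per-window null; windows whose observed rho exceeds the per-window
#' `(1 - cluster_p)` null quantile form candidate clusters (maximal
#' contiguous runs); each cluster's mass (sum of rho over the run) is
#' compared against the permutation distribution of the maximal cluster
#' mass, and clusters with `p <= fwe_alpha` are significant. One-sided
#' (positive encoding).
#'
#' @param rdm_tc an `rdm_timecourse`.
#' @param model candidate [rdm].
#' @param control optional [rdm] partialled out of every correlation
#'   (observed and null).
#' @param n_perm model-label shuffles (default 1000); must be at least
#'   `1 / fwe_alpha`.
#' @param cluster_p cluster-forming level (default 0.01).
#' @param fwe_alpha family-wise cluster level (default 0.001).
#' @param seed shuffle seed.
#' @return an object of class `cluster_result`: `clusters` (data frame with
#'   `start_ms`, `end_ms`, `mass`, `p`), `rho` (observed timecourse),
#'   `threshold` (per-window forming threshold), and parameters.
#' @export
cluster_inference <- function(rdm_tc, model, control = NULL, n_perm = 1000L,
                              cluster_p = 0.01, fwe_alpha = 0.001, seed = 1L) {
  stopifnot(inherits(rdm_tc, "rdm_timecourse"), inherits(model, "rdm"))
  if (fwe_alpha * n_perm < 1) {
    stop("n_perm must be at least 1 / fwe_alpha for the cluster quantile")
  }
  if (!identical(rdm_labels(model), rdm_tc$labels)) {
    model <- rdm_reorder(model, rdm_tc$labels)
  }
  if (!is.null(control) && !identical(rdm_labels(control), rdm_tc$labels)) {
    control <- rdm_reorder(control, rdm_tc$labels)
  }
  n <- length(rdm_tc$labels)
  D <- tc_rank_matrix(rdm_tc)                     # pairs x windows (std ranks)
  mv <- lower_tri(unclass(model))
  if (!is.null(control)) {
    cv <- lower_tri(unclass(control))
    if (isTRUE(all.equal(mv, cv))) stop("model and control RDMs are identical")
    cstd <- col_standardize(matrix(rank(cv)))
  }
  idx_full <- full_index_matrix(n)
  sel <- lower.tri(matrix(0, n, n))
  perms <- with_seed(seed, replicate(n_perm, sample(n), simplify = FALSE))
  # model vectors: observed first, then the shuffles
  mr <- rank(mv)
  Mv <- vapply(perms, function(p) mr[idx_full[p, p][sel]],
               numeric(length(mv)))
  Mall <- col_standardize(cbind(rank(mv), Mv))
  if (is.null(control)) {
    R <- crossprod(D, Mall)                       # windows x (1 + n_perm)
  } else {
    r_dm <- crossprod(D, Mall)
    r_dc <- as.vector(crossprod(D, cstd))         # windows
    r_mc <- as.vector(crossprod(Mall, cstd))      # 1 + n_perm
    denom <- sqrt(outer(1 - r_dc^2, 1 - r_mc^2))
    denom[denom < 1e-12] <- NA_real_
    R <- (r_dm - outer(r_dc, r_mc)) / denom
  }
  rho_obs <- R[, 1L]
  R_null <- R[, -1L, drop = FALSE]
  thr <- apply(R_null, 1L, stats::quantile, probs = 1 - cluster_p,
               na.rm = TRUE, names = FALSE)
  starts <- rdm_tc$starts_ms
  width <- rdm_tc$scheme$width_ms
  find_clusters <- function(rho_t) {
    above <- !is.na(rho_t) & rho_t > thr
    if (!any(above)) return(NULL)
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    begs <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    data.frame(first = begs[keep], last = ends[keep],
               mass = vapply(keep, function(k) {
                 sum(rho_t[begs[k]:ends[k]])
               }, numeric(1L)))
  }
  null_max_mass <- vapply(seq_len(n_perm), function(p) {
    cl <- find_clusters(R_null[, p])
    if (is.null(cl)) 0 else max(cl$mass)
  }, numeric(1L))
  obs <- find_clusters(rho_obs)
  clusters <- if (is.null(obs)) {
    data.frame(start_ms = numeric(0), end_ms = numeric(0),
               mass = numeric(0), p = numeric(0))
  } else {
    p_vals <- vapply(obs$mass, function(m) {
      (1 + sum(null_max_mass >= m)) / (n_perm + 1)
    }, numeric(1L))
    data.frame(start_ms = starts[obs$first],
               end_ms = starts[obs$last] + width,
               mass = obs$mass, p = p_vals)
  }
  structure(list(clusters = clusters, rho = rho_obs, threshold = thr,
                 starts_ms = starts, cluster_p = cluster_p,
                 fwe_alpha = fwe_alpha, n_perm = n_perm, seed = seed,
                 null_max_mass = null_max_mass),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sig <- x$clusters[x$clusters$p <= x$fwe_alpha, , drop = FALSE]
  cat(sprintf("<cluster_result> %d candidate clusters, %d significant at alpha = %g\n",
              nrow(x$clusters), nrow(sig), x$fwe_alpha))
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  [%g, %g) ms  mass %.2f  p = %.4g\n",
                  sig$start_ms[i], sig$end_ms[i], sig$mass[i], sig$p[i]))
    }
  }
  invisible(x)
}

significant_clusters <- function(x) {
  x$clusters[x$clusters$p <= x$fwe_alpha, , drop = FALSE]
}

#' Time-resolved noise ceiling (upper bound)
#'
#' Applies [noise_ceiling_upper] per window across subjects' RDM
#' timecourses.
#'
#' @param subject_rdm_tcs list of `rdm_timecourse`s with identical window
#'   schemes and labels.
#' @return numeric ceiling vector with attribute `starts_ms`.
#' @export
temporal_noise_ceiling <- function(subject_rdm_tcs) {
  stopifnot(is.list(subject_rdm_tcs), length(subject_rdm_tcs) >= 2L)
  ref <- subject_rdm_tcs[[1L]]
  for (s in subject_rdm_tcs) {
    if (!identical(s$starts_ms, ref$starts_ms) ||
        !identical(s$labels, ref$labels)) {
      stop("subject RDM timecourses have mismatching windows or labels")
    }
  }
  n_win <- length(ref$starts_ms)
  ceil <- vapply(seq_len(n_win), function(w) {
    rdms <- lapply(subject_rdm_tcs, function(s) {
      rdm(s$rdms[, , w], labels = s$labels, kind = "data_crossnobis")
    })
    noise_ceiling_upper(rdms)
  }, numeric(1L))
  attr(ceil, "starts_ms") <- ref$starts_ms
  ceil
}

#' Fit a sliding-window temporal RSA
#'
#' End-to-end temporal analysis of one session of epoched source data:
#' band-pass filtering, optional baseline correction, partitioning and
#' within-partition averaging, sliding-window crossnobis RDMs with
#' multivariate noise normalization, model (or partial) correlation
#' timecourse, and cluster-based permutation inference.
#'
#' @param epochs a [channel_epochs] object.
#' @param model candidate [rdm].
#' @param control optional competing-model [rdm] (partial correlation).
#' @param band frequency band preset or `c(lo, hi)` Hz (default
#'   `"broadband"`).
#' @param scheme a [window_scheme] (default 20 ms / 5 ms over the epoch).
#' @param n_partitions cross-validation partitions (default 10).
#' @param baseline_window optional `[t0, t1)` ms baseline to subtract.
#' @param mnn multivariate noise normalization (default TRUE).
#' @param n_perm,cluster_p,fwe_alpha cluster inference parameters (defaults
#'   1000 shuffles, 0.01 forming level, 0.001 family-wise level).
#' @param seed seed for partitioning and shuffles.
#' @return an object of class `temporal_rsa`: `rho` timecourse, `clusters`
#'   (a `cluster_result`), the `rdm_timecourse`, and call parameters.
#' @export
temporal_rsa <- function(epochs, model, control = NULL, band = "broadband",
                         scheme = NULL, n_partitions = 10L,
                         baseline_window = NULL, mnn = TRUE,
                         n_perm = 1000L, cluster_p = 0.01,
                         fwe_alpha = 0.001, seed = 1L) {
  stopifnot(inherits(epochs, "channel_epochs"))
  if (is.null(scheme)) {
    d <- dim(epochs$data)
    scheme <- window_scheme(epoch = c(epochs$t0_ms,
                                      epochs$t0_ms + d[3L] / epochs$fs * 1000))
  }
  ep <- bandpass(epochs, band)
  if (!is.null(baseline_window)) ep <- baseline_correct(ep, baseline_window)
  pm <- partition_average(ep, n_partitions = n_partitions, seed = seed)
  tc <- sliding_rdms(pm, scheme = scheme, mnn = mnn)
  tc$band <- if (is.character(band)) band else paste(band, collapse = "-")
  cl <- cluster_inference(tc, model, control = control, n_perm = n_perm,
                          cluster_p = cluster_p, fwe_alpha = fwe_alpha,
                          seed = seed)
  structure(list(rho = cl$rho, clusters = cl, rdm_timecourse = tc,
                 model = model, control = control,
                 params = list(band = tc$band, n_partitions = n_partitions,
                               n_perm = n_perm, cluster_p = cluster_p,
                               fwe_alpha = fwe_alpha, seed = seed)),
            class = "temporal_rsa")
}

#' @export
print.temporal_rsa <- function(x, ...) {
  cat(sprintf("Temporal RSA (%s band), %d windows\n",
              x$params$band, length(x$rho)))
  cat(sprintf("  peak rho %.4f at %g ms\n", max(x$rho),
              x$clusters$starts_ms[which.max(x$rho)]))
  print(x$clusters)
  invisible(x)
}

#' @export
summary.temporal_rsa <- function(object, ...) print(object)

#' @export
plot.temporal_rsa <- function(x, ...) {
  t <- x$clusters$starts_ms
  graphics::plot(t, x$rho, type = "l", xlab = "window start (ms)",
                 ylab = "Spearman rho", main = sprintf("Temporal RSA (%s)",
                                                       x$params$band), ...)
  graphics::lines(t, x$clusters$threshold, col = "grey60", lty = 3)
  sig <- significant_clusters(x$clusters)
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      graphics::rect(sig$start_ms[i], graphics::par("usr")[3L],
                     sig$end_ms[i], graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("steelblue", 0.2),
                     border = NA)
    }
    graphics::lines(t, x$rho)
  }
  graphics::abline(v = 0, col = "darkgreen", lty = 2)
  invisible(x)
}
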