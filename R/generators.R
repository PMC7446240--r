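# Synthetic glove / EMG / MEG session generators with planted geometry.

# Condition template bank: for each condition a channels x samples template
# whose channel-wise (1 - r) model RDM is exactly affine in the planted
# squared distances. Construction: an orthonormal basis of raised-cosine
# bumps (orthogonalized against the constant and a common movement bump) is
# weighted by an equal-norm embedding of the target RDM; every channel
# carries an affinely rescaled copy, so per-channel Pearson correlations are
# identical across channels and exactly affine in the planted distances.
condition_templates <- function(target_rdm, n_channels, n_samples,
                                movement_frac = 2 / 3, signal_scale = 1,
                                seed = 1L, nonnegative = FALSE,
                                baseline = 0) {
  n_cond <- nrow(target_rdm)
  if (n_samples < n_cond + 2L) {
    stop("epoch too short to carry ", n_cond, " condition basis functions")
  }
  t_idx <- seq_len(n_samples)
  move_len <- max(2L, floor(n_samples * movement_frac))
  bump <- function(center, width) {
    u <- (t_idx - center) / width
    ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
  }
  common <- bump(move_len / 2, move_len / 2)
  centers <- seq(move_len * 0.15, move_len * 0.9, length.out = n_cond)
  width <- max(2, (centers[2L] - centers[1L]) * 1.5)
  raw <- vapply(centers, bump, numeric(n_samples), width = width)
  basis_in <- cbind(1, common, raw)
  qrd <- qr(basis_in)
  Q <- qr.Q(qrd)
  if (qrd$rank < n_cond + 2L) {
    stop("raised-cosine basis is rank deficient for this epoch length")
  }
  phi <- Q[, 3:(n_cond + 2L), drop = FALSE]  # orthonormal, zero-mean, _|_ common
  coef <- plant_condition_patterns(target_rdm, n_features = n_cond,
                                   seed = seed, equal_norms = TRUE)
  # scale so the condition-specific component has unit average sample SD at
  # signal_scale = 1
  comp <- phi %*% t(coef)  # samples x conditions
  coef <- coef / stats::sd(as.vector(comp))
  gains <- seq(0.8, 1.2, length.out = n_channels)
  templates <- array(0, c(n_cond, n_channels, n_samples),
                     dimnames = list(rownames(coef), NULL, NULL))
  cond_part <- signal_scale * tcrossprod(coef, phi)  # conditions x samples
  for (ch in seq_len(n_channels)) {
    templates[, ch, ] <- gains[ch] *
      (matrix(common, n_cond, n_samples, byrow = TRUE) + cond_part)
  }
  if (nonnegative) {
    # shift each channel by a constant so the template envelope stays >= 0
    # (a per-channel constant leaves Pearson correlations untouched)
    for (ch in seq_len(n_channels)) {
      lo <- min(templates[, ch, ])
      templates[, ch, ] <- templates[, ch, ] - min(lo, 0) + baseline
    }
  } else if (baseline != 0) {
    templates <- templates + baseline
  }
  templates
}

# Shared trial assembly: per run one block per condition, trials_per_block
# trials per block; each trial = condition template + iid Gaussian noise.
assemble_session <- function(templates, fs, n_runs, trials_per_block,
                             noise_sd, seed, t0_ms = 0) {
  n_cond <- dim(templates)[1L]
  n_ch <- dim(templates)[2L]
  n_samp <- dim(templates)[3L]
  cond_names <- dimnames(templates)[[1L]]
  n_trials <- n_runs * n_cond * trials_per_block
  data <- array(0, c(n_trials, n_ch, n_samp))
  labels <- character(n_trials)
  run_ids <- integer(n_trials)
  seeds <- derive_seeds(seed, n_runs)
  i <- 0L
  for (r in seq_len(n_runs)) {
    with_seed(seeds[r], {
      block_order <- sample(n_cond)  # random-without-replacement block order
      for (k in block_order) {
        for (tr in seq_len(trials_per_block)) {
          i <- i + 1L
          noise <- if (noise_sd > 0) {
            matrix(stats::rnorm(n_ch * n_samp, sd = noise_sd), n_ch)
          } else 0
          data[i, , ] <- templates[k, , ] + noise
          labels[i] <- cond_names[k]
          run_ids[i] <- r
        }
      }
    })
  }
  ep <- channel_epochs(data, fs = fs, labels = labels, t0_ms = t0_ms)
  ep$run <- run_ids
  ep
}

#' Simulate a data-glove session
#'
#' Generates epoched 14-channel kinematic recordings at 60 Hz with a planted
#' representational geometry: per-condition smooth displacement templates
#' (raised-cosine bumps over the 1.6 s movement period, flat over the 0.8 s
#' rest) whose channel-correlation model RDM is exactly rank-equivalent to
#' `spec$target_rdm`; each trial is its condition template plus i.i.d.
#' Gaussian noise.
#'
#' @param movements a [movement_set].
#' @param spec a [plant_spec] (its `target_rdm` labels must match the
#'   movement set).
#' @param n_runs task runs (default 5, the behavioral protocol).
#' @param trials_per_block movement trials per block (default 8).
#' @return a [channel_epochs] object (14 channels, 60 Hz, 2.4 s trials) with
#'   a `$run` element giving each trial's run.
#' @export
gen_glove_session <- function(movements, spec, n_runs = 5L,
                              trials_per_block = 8L) {
  stopifnot(inherits(movements, "movement_set"), inherits(spec, "plant_spec"))
  if (trials_per_block < 1L) stop("trials_per_block must be >= 1")
  check_plant_labels(spec, movements)
  fs <- 60
  p <- task_protocol("behavioral")
  n_samples <- round((p$movement_s + p$rest_s) * fs)  # 2.4 s trials
  templates <- condition_templates(
    rdm_reorder(spec$target_rdm, movements$labels),
    n_channels = 14L, n_samples = n_samples,
    movement_frac = p$movement_s / (p$movement_s + p$rest_s),
    signal_scale = spec$signal_scale, seed = spec$seed)
  assemble_session(templates, fs = fs, n_runs = n_runs,
                   trials_per_block = trials_per_block,
                   noise_sd = spec$noise_sd, seed = spec$seed + 1L)
}

#' Simulate an EMG session
#'
#' Generates epoched 15-channel rectified-EMG-envelope recordings with a
#' planted representational geometry. Templates are nonnegative envelope
#' shapes (2.0 s post-onset trials); the channel-correlation model RDM of
#' the noiseless output is rank-equivalent to `spec$target_rdm`. The native
#' 2048 Hz rate can be decimated for speed.
#'
#' @param movements a [movement_set].
#' @param spec a [plant_spec].
#' @param n_runs task runs (default 5; one block per condition per run).
#' @param trials_per_block trials per block (default 1, one epoch per
#'   condition per run).
#' @param fs sampling rate in Hz (default 2048).
#' @param decimate integer factor by which to reduce the sampling rate.
#' @param baseline nonnegative envelope baseline offset (negative values are
#'   rejected: a rectified envelope cannot be negative).
#' @return a [channel_epochs] object (15 channels, 2.0 s trials).
#' @export
gen_emg_session <- function(movements, spec, n_runs = 5L,
                            trials_per_block = 1L, fs = 2048,
                            decimate = 1L, baseline = 0.05) {
  stopifnot(inherits(movements, "movement_set"), inherits(spec, "plant_spec"))
  if (baseline < 0) stop("negative envelope baseline requested; envelopes are nonnegative")
  check_plant_labels(spec, movements)
  decimate <- as.integer(decimate)
  if (decimate < 1L) stop("decimate must be >= 1")
  fs_out <- fs / decimate
  n_samples <- round(2.0 * fs_out)  # 2.0 s trials relative to onset
  templates <- condition_templates(
    rdm_reorder(spec$target_rdm, movements$labels),
    n_channels = 15L, n_samples = n_samples, movement_frac = 0.8,
    signal_scale = spec$signal_scale, seed = spec$seed,
    nonnegative = TRUE, baseline = baseline)
  assemble_session(templates, fs = fs_out, n_runs = n_runs,
                   trials_per_block = trials_per_block,
                   noise_sd = spec$noise_sd, seed = spec$seed + 1L)
}

#' Simulate an MEG-like source-space session
#'
#' Generates epoched virtual-sensor time series with a condition geometry
#' confined to a chosen frequency band and time window. Condition-specific
#' source amplitude patterns (from [plant_condition_patterns]) modulate a
#' band-limited oscillatory carrier (a sinusoid at the band's centre
#' frequency under a raised-cosine taper spanning `spec$window`); outside
#' the window and band the data are 1/f-amplitude background noise only.
#'
#' The background amplitude is fixed so that, at the defaults
#' (`signal_scale = 1`, `noise_sd = 1`, 26 conditions, 50 trials), the
#' recovered model-correlation timecourse peaks near 0.3 -- a realistic
#' effect size for time-resolved RSA.
#'
#' @param plant a [plant_spec] with `window` (ms) and `band` set.
#' @param movements a [movement_set].
#' @param n_sources number of virtual sensors (default 31).
#' @param fs sampling rate in Hz (default 600).
#' @param epoch half-open epoch `[t_pre, t_post)` in ms relative to movement
#'   onset (default `c(-500, 1500)`).
#' @param trials_per_condition trials per movement (default 50).
#' @return a [channel_epochs] object.
#' @export
gen_meg_session <- function(plant, movements, n_sources = 31L, fs = 600,
                            epoch = c(-500, 1500),
                            trials_per_condition = 50L) {
  stopifnot(inherits(plant, "plant_spec"), inherits(movements, "movement_set"))
  check_plant_labels(plant, movements)
  band <- band_limits(plant$band %||% "beta")
  if (band[2L] >= fs / 2) stop("plant band reaches the Nyquist frequency")
  if (is.null(plant$window)) stop("plant$window must be set for temporal plants")
  if (plant$window[1L] < epoch[1L] || plant$window[2L] > epoch[2L]) {
    stop("plant window must lie inside the epoch")
  }
  labels <- movements$labels
  n_cond <- length(labels)
  n_samples <- round((epoch[2L] - epoch[1L]) / 1000 * fs)
  t_ms <- epoch[1L] + (seq_len(n_samples) - 1L) / fs * 1000
  seeds <- derive_seeds(plant$seed, 2L)
  pat <- plant_condition_patterns(plant$target_rdm, n_features = n_sources,
                                  seed = seeds[1L])
  pat <- pat[labels, , drop = FALSE]
  pat <- pat / max(stats::sd(as.vector(pat)), .Machine$double.eps)
  f0 <- mean(band)
  carrier <- sin(2 * pi * f0 * (t_ms - plant$window[1L]) / 1000)
  u <- (t_ms - mean(plant$window)) / (diff(plant$window) / 2)
  taper <- ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
  carrier <- carrier * taper
  # confine the tapered carrier to the plant band: the taper's spectral
  # sidelobes would otherwise leak condition structure into adjacent bands
  flt <- signal::butter(4L, band / (fs / 2), type = "pass")
  carrier <- signal::filtfilt(flt, carrier)
  carrier <- carrier / max(abs(carrier))
  # background: white noise shaped to 1/f amplitude below the Nyquist
  noise_amp <- 100  # fixed so planted effects at scale 1 give rho peaks ~0.3
  freqs <- seq(0, fs / 2, length.out = floor(n_samples / 2) + 1L)
  shape <- 1 / pmax(freqs, 1)
  full_shape <- c(shape, rev(shape[2:(length(shape) - if (n_samples %% 2L) 0L else 1L)]))
  n_trials <- n_cond * trials_per_condition
  data <- array(0, c(n_trials, n_sources, n_samples))
  labels_out <- rep(labels, each = trials_per_condition)
  with_seed(seeds[2L], {
    for (i in seq_len(n_trials)) {
      k <- match(labels_out[i], labels)
      w <- matrix(stats::rnorm(n_sources * n_samples), n_sources)
      spec_w <- t(apply(w, 1L, function(x) {
        Re(stats::fft(stats::fft(x) * full_shape, inverse = TRUE) / n_samples)
      }))
      spec_w <- spec_w / stats::sd(as.vector(spec_w))
      sig <- plant$signal_scale * outer(pat[k, ], carrier)
      data[i, , ] <- sig + plant$noise_sd * noise_amp * spec_w
    }
  })
  channel_epochs(data, fs = fs, labels = labels_out, t0_ms = epoch[1L])
}

check_plant_labels <- function(spec, movements) {
  if (!setequal(rdm_labels(spec$target_rdm), movements$labels)) {
    stop("plant target RDM labels must match the movement set")
  }
  invisible(TRUE)
}
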