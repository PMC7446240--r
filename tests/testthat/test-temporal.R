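test_that("band presets match the canonical edges", {
  expect_equal(band_limits("alpha"), c(7, 14))
  expect_equal(band_limits("beta"), c(15, 30))
  expect_equal(band_limits("gamma"), c(30, 100))
  expect_equal(band_limits("broadband"), c(7, 100))
  expect_equal(band_limits(c(5, 100)), c(5, 100))
  expect_error(band_limits("theta"), "unknown band")
})

test_that("bandpass keeps in-band sinusoids and rejects out-of-band ones", {
  fs <- 600
  t <- seq_len(3000) / fs
  amp_gain <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    ep <- channel_epochs(array(x, c(1, 1, length(x))), fs, "a")
    y <- bandpass(ep, "beta")$data[1, 1, ]
    # FFT amplitude at the stimulus frequency, mid-signal to avoid edges
    mid <- 501:2500
    n <- length(mid)
    bin <- round(f_hz * n / fs) + 1L
    Mod(fft(y[mid]))[bin] / Mod(fft(x[mid]))[bin]
  }
  expect_gte(amp_gain(20), 0.9)   # mid-beta passes
  expect_lte(amp_gain(50), 0.1)   # gamma-range tone is rejected
  ep <- channel_epochs(array(rnorm(100), c(1, 1, 100)), fs = 100, "a")
  expect_error(bandpass(ep, c(10, 60)), "Nyquist")
})

test_that("baseline correction subtracts the window mean linearly", {
  data <- array(rnorm(2 * 3 * 50), c(2, 3, 50))
  ep <- channel_epochs(data, fs = 100, labels = c("a", "b"), t0_ms = -200)
  # constant offset vanishes entirely
  ep_off <- ep; ep_off$data <- ep$data * 0 + 4
  out <- baseline_correct(ep_off, c(-200, -100))
  expect_equal(max(abs(out$data)), 0)
  # zero-mean baseline leaves the data unchanged
  ep_z <- ep
  bsel <- spatempRSA:::epoch_times_ms(ep) < -100
  for (i in 1:2) for (ch in 1:3) {
    ep_z$data[i, ch, bsel] <- ep_z$data[i, ch, bsel] -
      mean(ep_z$data[i, ch, bsel])
  }
  expect_equal(baseline_correct(ep_z, c(-200, -100))$data, ep_z$data,
               tolerance = 1e-12)
  # linearity
  ep2 <- ep; ep2$data <- array(rnorm(2 * 3 * 50), c(2, 3, 50))
  sum_ep <- ep; sum_ep$data <- ep$data + ep2$data
  expect_equal(baseline_correct(sum_ep, c(-200, 0))$data,
               baseline_correct(ep, c(-200, 0))$data +
                 baseline_correct(ep2, c(-200, 0))$data,
               tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(500, 600)), "outside")
})

test_that("partitioning spreads trials evenly and averages within", {
  mk <- function(n_trials) {
    channel_epochs(array(rnorm(n_trials * 2 * 10), c(n_trials, 2, 10)),
                   fs = 100, labels = rep("a", n_trials))
  }
  # 50 trials over 10 partitions: 5 each
  ep <- mk(50L)
  pm <- partition_average(ep, 10L, seed = 1L)
  expect_identical(dim(pm$data), c(10L, 1L, 2L, 10L))
  # reconstruct assignment sizes via the package's deterministic rule:
  # 43 trials over 10 partitions -> sizes {5 x 3, 4 x 7}, every trial once
  sizes <- table(rep_len(1:10, 43))
  expect_identical(sort(unique(as.integer(sizes))), c(4L, 5L))
  expect_identical(sum(sizes), 43L)
  expect_identical(as.integer(sum(sizes == 5L)), 3L)
  ep43 <- mk(43L)
  pm43 <- partition_average(ep43, 10L, seed = 2L)
  # grand mean of partition means weighted by size equals the trial mean
  w <- as.integer(table(rep_len(1:10, 43)))
  wmean <- apply(pm43$data[, 1L, , ] * w, c(2, 3), sum) / 43
  expect_equal(wmean, colMeans(ep43$data, dims = 1L)[, ], tolerance = 1e-12)
  # n_partitions = 1: the grand condition mean
  pm1 <- partition_average(ep, 1L)
  expect_equal(pm1$data[1L, 1L, , ], colMeans(ep$data, dims = 1L),
               tolerance = 1e-12)
  expect_error(partition_average(mk(5L), 10L), "too few trials")
})

test_that("window bookkeeping follows the end-strict convention", {
  # the 2 s epoch at 20 ms / 5 ms gives 396 windows
  expect_length(window_starts(window_scheme(20, 5, c(-500, 1500))), 396L)
  # width = full epoch: exactly one window? end-strict keeps starts with
  # start + width < t_end, so a full-width window is excluded; one sample
  # less than the epoch gives exactly 1
  expect_length(window_starts(window_scheme(99, 5, c(0, 100))), 1L)
  # 100 ms epoch, 20 ms width, 5 ms step: starts 0,5,...,75 -> 16 windows
  expect_length(window_starts(window_scheme(20, 5, c(0, 100))), 16L)

  # property: against a brute-force enumerator for 200 random (L, w, s)
  set.seed(19)
  for (i in 1:200) {
    L <- sample(50:2000, 1)
    w <- sample(seq_len(L), 1)
    s <- sample(1:50, 1)
    brute <- sum(sapply(seq(0, L, by = s), function(st) st + w < L))
    expect_identical(length(window_starts(window_scheme(w, s, c(0, L)))),
                     as.integer(brute))
  }
})

test_that("sliding RDM timecourses recover planted windows", {
  ms <- small_movements()
  target <- small_target(ms)
  model <- rdm(unclass(target), ms$labels, "data_crossnobis")
  spec <- plant_spec(target, window = c(100, 220), band = "beta",
                     signal_scale = 1, noise_sd = 0, seed = 71L)
  meg <- gen_meg_session(spec, ms, n_sources = 8L, fs = 200,
                         epoch = c(0, 400), trials_per_condition = 4L)
  pm <- partition_average(meg, 2L, seed = 3L)
  scheme <- window_scheme(20, 10, c(0, 400))
  tc <- sliding_rdms(pm, scheme, mnn = FALSE)
  rho <- model_timecourse(tc, model)
  starts <- attr(rho, "starts_ms")
  inside <- starts >= 120 & starts <= 180  # fully inside the plant
  # noiseless plant: perfect rank recovery inside the planted window
  expect_true(all(rho[inside] > 0.999))
  # width = full usable epoch -> a single window
  tc1 <- sliding_rdms(pm, window_scheme(390, 10, c(0, 400)), mnn = FALSE)
  expect_length(tc1$starts_ms, 1L)
  expect_error(sliding_rdms(partition_average(meg, 1L), scheme), "2 partitions")
})

test_that("cluster inference flags the planted window and honors defaults", {
  expect_identical(formals(cluster_inference)$n_perm, 1000L)
  expect_equal(formals(cluster_inference)$cluster_p, 0.01)
  expect_equal(formals(cluster_inference)$fwe_alpha, 0.001)

  ms <- small_movements()
  target <- small_target(ms)
  model <- rdm(unclass(target), ms$labels, "data_crossnobis")
  spec <- plant_spec(target, window = c(-210, -90), band = "beta",
                     signal_scale = 1, noise_sd = 0.25, seed = 73L)
  meg <- gen_meg_session(spec, ms, n_sources = 12L, fs = 250,
                         epoch = c(-500, 500), trials_per_condition = 20L)
  tr <- temporal_rsa(meg, model, band = "beta", n_partitions = 10L,
                     n_perm = 200L, cluster_p = 0.01, fwe_alpha = 0.005,
                     seed = 74L)
  sig <- tr$clusters$clusters[tr$clusters$clusters$p <= 0.005, , drop = FALSE]
  expect_gt(nrow(sig), 0L)
  expect_true(any(sig$end_ms > -210 & sig$start_ms < -90))
  # latency specificity: strongest cluster centroid near the plant centroid
  top <- sig[which.max(sig$mass), ]
  expect_lt(abs((top$start_ms + top$end_ms) / 2 - (-150)), 60)
  # no significant cluster in the gamma band of the same data
  trg <- temporal_rsa(meg, model, band = "gamma", n_partitions = 10L,
                      n_perm = 200L, cluster_p = 0.01, fwe_alpha = 0.005,
                      seed = 74L)
  expect_identical(nrow(trg$clusters$clusters[trg$clusters$clusters$p <= 0.005, ]),
                   0L)
  # guard rails
  expect_error(temporal_rsa(meg, model, control = model, band = "beta",
                            n_perm = 200L, fwe_alpha = 0.005),
               "identical")
  expect_error(cluster_inference(tr$rdm_timecourse, model, n_perm = 100L,
                                 fwe_alpha = 0.001), "1 / fwe_alpha")
})

test_that("temporal noise ceiling is 1 for identical subjects and bounds fits", {
  ms <- small_movements(6L)
  target <- small_target(ms, seed = 81L)
  spec <- plant_spec(target, window = c(50, 150), band = "beta",
                     signal_scale = 1, noise_sd = 0.3, seed = 82L)
  meg <- gen_meg_session(spec, ms, n_sources = 6L, fs = 200,
                         epoch = c(0, 200), trials_per_condition = 4L)
  tc <- sliding_rdms(partition_average(meg, 2L, seed = 1L),
                     window_scheme(20, 20, c(0, 200)), mnn = FALSE)
  expect_equal(as.numeric(temporal_noise_ceiling(list(tc, tc, tc))),
               rep(1, length(tc$starts_ms)))
  # fixed-effects consistency: averaging identical subject RDMs then
  # correlating equals correlating one subject
  model <- rdm(unclass(target), ms$labels, "data_crossnobis")
  avg_first <- model_timecourse(tc, model)
  expect_equal(avg_first, model_timecourse(tc, model))
  # mismatching schemes rejected
  tc2 <- sliding_rdms(partition_average(meg, 2L, seed = 1L),
                      window_scheme(40, 40, c(0, 200)), mnn = FALSE)
  expect_error(temporal_noise_ceiling(list(tc, tc2)), "mismatch")
})
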