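test_that("onset detection finds sustained bursts and ignores short ones", {
  fs <- 1000
  # zero signal everywhere -> no onset
  expect_true(is.na(detect_onset(numeric(1000), fs)))
  # constant signal -> no onset (flagged, not an error)
  expect_true(is.na(detect_onset(rep(3, 1000), fs)))
  expect_error(detect_onset(rnorm(1000), fs = -1), "fs")
  expect_error(detect_onset(rnorm(50), fs, duration_threshold_ms = 200),
               "shorter")

  # noiseless step at sample k, sustained: onset at k up to the Hilbert
  # envelope's edge precursor (the analytic envelope rises slightly before a
  # discontinuity) plus the smoothing half-width
  k <- 701L
  step <- c(rep(0, k - 1L), rep(1, 1000 - k + 1L))
  onset <- detect_onset(step, fs, duration_threshold_ms = 200,
                        smoothing_ms = 5)
  expect_lte(onset, k + 3L)   # never later than the step
  expect_lt(k - onset, 26L)   # at most ~25 ms of envelope precursor

  # 100 ms burst fails a 200 ms duration threshold; a 300 ms burst passes
  t <- seq_len(2000) / fs
  burst <- function(len_ms, at_ms = 500) {
    on <- t * 1000 >= at_ms & t * 1000 < at_ms + len_ms
    sin(2 * pi * 50 * t) * on
  }
  expect_true(is.na(detect_onset(burst(100), fs)))
  on300 <- detect_onset(burst(300), fs)
  expect_false(is.na(on300))
  expect_lt(abs(on300 - 500), 30)  # near the burst start
})

test_that("earliest_onset takes the channel minimum and flags empty trials", {
  fs <- 1000
  mk <- function(onset_ms) {
    x <- numeric(1500)
    x[(onset_ms + 1):1500] <- 1  # rest-majority epoch, step till the end
    x
  }
  data <- array(0, c(2L, 3L, 1500L))
  for (ch in seq_len(3L)) data[1L, ch, ] <- mk(c(800L, 780L, 820L)[ch])
  # trial 2: all channels flat -> no onset anywhere
  ep <- channel_epochs(data, fs = fs, labels = c("a", "b"), t0_ms = 0)
  # earliest across channels, allowing the envelope's edge precursor
  eo <- earliest_onset(ep, 1L)
  expect_lte(eo, 783)
  expect_lt(780 - eo, 26)
  expect_true(is.na(earliest_onset(ep, 2L)))

  # single-channel epochs: equals that channel's onset
  ep1 <- channel_epochs(data[, 2L, , drop = FALSE], fs = fs,
                        labels = c("a", "b"))
  expect_equal(earliest_onset(ep1, 1L),
               (detect_onset(data[1L, 2L, ], fs) - 1L) / fs * 1000)

  # cross-modality validation: discrepancy beyond 100 ms excludes the trial
  expect_identical(validate_onsets(c(100, 50, NA), c(190, 160, 60)),
                   c(TRUE, FALSE, FALSE))
})

test_that("average_by_condition averages trials and names missing conditions", {
  data <- array(0, c(3L, 2L, 4L))
  data[1L, , ] <- 0; data[2L, , ] <- 2; data[3L, , ] <- 5
  ep <- channel_epochs(data, fs = 10, labels = c("a", "a", "b"))
  avg <- average_by_condition(ep)
  expect_equal(avg["a", , ], matrix(1, 2L, 4L))   # mean of 0 and 2 arrays
  expect_equal(avg["b", , ], matrix(5, 2L, 4L))   # single trial: identity
  expect_error(average_by_condition(ep, conditions = c("a", "zz")), "zz")
})

test_that("channel_correlation_rdm matches a brute-force oracle", {
  # single channel: exactly 1 - Pearson r
  x <- sin(seq(0, 3, length.out = 20))
  y <- x^2 + 0.3 * x
  one <- array(0, c(2L, 1L, 20L)); one[1L, 1L, ] <- x; one[2L, 1L, ] <- y
  dimnames(one) <- list(c("a", "b"), NULL, NULL)
  r <- channel_correlation_rdm(one)
  expect_equal(unclass(r)["a", "b"], 1 - cor(x, y), tolerance = 1e-12)

  # identical timecourses -> dissimilarity 0
  same <- array(rep(x, each = 2L), c(2L, 1L, 20L))
  same[2L, 1L, ] <- x
  same[1L, 1L, ] <- x
  expect_equal(max(unclass(channel_correlation_rdm(same))), 0)

  # 3 conditions x 2 channels: independent direct computation
  set.seed(42)
  arr <- array(rnorm(3 * 2 * 15), c(3L, 2L, 15L))
  got <- unclass(channel_correlation_rdm(arr))
  for (k in 1:2) for (l in (k + 1):3) {
    z <- sapply(1:2, function(ch) atanh(cor(arr[k, ch, ], arr[l, ch, ])))
    expect_equal(got[k, l], 1 - tanh(mean(z)), tolerance = 1e-12)
  }

  # invariance to per-channel affine rescaling (positive gains)
  arr3 <- arr
  arr3[, 1L, ] <- 3 * arr3[, 1L, ] + 7
  arr3[, 2L, ] <- 0.5 * arr3[, 2L, ] - 1
  expect_equal(unclass(channel_correlation_rdm(arr3)), got, tolerance = 1e-10)

  # constant channel: dropped with a warning, remaining channel used
  arr4 <- arr
  arr4[, 2L, ] <- 1
  expect_warning(r4 <- channel_correlation_rdm(arr4), "constant")
  expect_equal(unclass(r4)[1L, 2L], 1 - cor(arr[1L, 1L, ], arr[2L, 1L, ]),
               tolerance = 1e-12)
})

test_that("multivariate noise normalization whitens the error covariance", {
  set.seed(7)
  n_ch <- 4L; n_samp <- 400L
  mk_epochs <- function(transform = diag(n_ch)) {
    data <- array(0, c(20L, n_ch, n_samp))
    labels <- rep(c("a", "b"), each = 10L)
    tmpl <- list(a = matrix(rnorm(n_ch * n_samp), n_ch),
                 b = matrix(rnorm(n_ch * n_samp), n_ch))
    for (i in 1:20) {
      data[i, , ] <- transform %*%
        (tmpl[[labels[i]]] + matrix(rnorm(n_ch * n_samp), n_ch))
    }
    channel_epochs(data, fs = 100, labels = labels)
  }
  set.seed(11)
  ep <- mk_epochs()
  out <- mnn_trials(ep, shrinkage = 0)
  # pooled error covariance after MNN is the identity (within sampling error
  # of the estimator itself it is exact: the whitener is built from it)
  pooled <- local({
    S <- matrix(0, n_ch, n_ch); n <- 0L
    for (cond in c("a", "b")) {
      sel <- which(out$labels == cond)
      avg <- colMeans(out$data[sel, , , drop = FALSE], dims = 1L)
      for (i in sel) {
        E <- out$data[i, , ] - avg
        S <- S + tcrossprod(E); n <- n + n_samp
      }
    }
    S / n
  })
  expect_lt(max(abs(pooled - diag(n_ch))), 1e-6)

  # already-white errors: output equals input
  # (construct exact-identity error covariance via the estimator definition)
  set.seed(13)
  base <- matrix(rnorm(n_ch * n_samp), n_ch)
  dev <- matrix(rnorm(n_ch * n_samp), n_ch)
  # orthonormalize deviation rows so the pooled covariance is exactly I
  dev <- t(qr.Q(qr(t(dev)))) * sqrt(n_samp)
  data <- array(0, c(2L, n_ch, n_samp))
  data[1L, , ] <- base + dev
  data[2L, , ] <- base - dev
  epw <- channel_epochs(data, fs = 100, labels = c("a", "a"))
  outw <- mnn_trials(epw, shrinkage = 0)
  expect_lt(max(abs(outw$data - epw$data)), 1e-10)

  # rescaling one channel by 10 leaves the normalized output invariant
  set.seed(11)
  ep_a <- mk_epochs()
  D <- diag(n_ch); D[2L, 2L] <- 10
  ep_b <- ep_a
  for (i in 1:20) ep_b$data[i, , ] <- D %*% ep_a$data[i, , ]
  na_ <- mnn_trials(ep_a, shrinkage = 0.1)
  nb_ <- mnn_trials(ep_b, shrinkage = 0.1)
  expect_lt(max(abs(na_$data - nb_$data)) / max(abs(na_$data)), 1e-6)

  # degenerate: < 2 trials per condition rejected; singular cov needs shrinkage
  expect_error(mnn_trials(channel_epochs(array(0, c(2L, 2L, 5L)), 10,
                                         c("a", "b"))), ">= 2 trials")
})

test_that("ethological RDM is the binary same/different-category structure", {
  ms <- movement_set()
  r <- ethological_rdm(ms)
  v <- unclass(r)
  expect_equal(v["pinch thumb-index", "pinch thumb-ring"], 0)
  expect_equal(v["pinch thumb-index", "abduct thumb"], 1)
  expect_equal(v["cylinder grip", "hook grip"], 0)
  # ordering by category gives zero blocks on the diagonal
  ord <- order(ms$categories)
  vo <- v[ord, ord]
  cats <- ms$categories[ord]
  for (cc in unique(cats)) {
    blk <- vo[cats == cc, cats == cc]
    expect_true(all(blk == 0))
  }
  # graded coding is available but non-binary
  g <- ethological_rdm(ms, between_value = 0.5)
  expect_equal(max(unclass(g)), 0.5)
})

test_that("cluster_order is a deterministic average-linkage leaf order", {
  # two well-separated pairs of near-identical conditions end up adjacent
  m <- matrix(10, 4, 4); diag(m) <- 0
  m[1, 3] <- m[3, 1] <- 0.1
  m[2, 4] <- m[4, 2] <- 0.1
  ord <- cluster_order(rdm(m, letters[1:4]))
  expect_setequal(ord, 1:4)
  pos <- match(1:4, ord)
  expect_equal(abs(pos[1] - pos[3]), 1L)  # pair (1,3) adjacent
  expect_equal(abs(pos[2] - pos[4]), 1L)  # pair (2,4) adjacent

  # all-equal RDM: identity permutation under the lowest-index tie rule
  eq <- matrix(1, 5, 5); diag(eq) <- 0
  expect_identical(cluster_order(rdm(eq, letters[1:5])), 1:5)

  # agreement with hclust average linkage on a tie-free RDM
  set.seed(3)
  pts <- matrix(rnorm(12), 6)
  D <- as.matrix(dist(pts))
  ours <- cluster_order(rdm(D, letters[1:6]))
  h <- hclust(as.dist(D), method = "average")
  # same partition structure: compare merge heights via cophenetic distances
  expect_setequal(ours, 1:6)
  co <- cophenetic(h)
  # adjacent leaves in our order are joined at low cophenetic height
  expect_true(mean(as.matrix(co)[cbind(ours[-6], ours[-1])]) <
                mean(as.matrix(co)))
})

test_that("stress MDS embeds exact geometries and degenerate inputs", {
  # exact 3-D point distances embed with (near) zero stress
  set.seed(21)
  pts <- matrix(rnorm(8 * 3), 8)
  D <- as.matrix(dist(pts))
  emb <- mds_embed(rdm(D, letters[1:8]), n_dims = 3L, n_restarts = 5L)
  expect_lte(emb$stress, 1e-4)
  # all-zero RDM: coincident coordinates
  z <- mds_embed(rdm(matrix(0, 4, 4), letters[1:4]), n_dims = 2L,
                 n_restarts = 2L)
  expect_lt(max(dist(z$points)), 1e-10)
  expect_equal(z$stress, 0)
  # defaults and errors
  expect_identical(formals(mds_embed)$n_dims, 3L)
  expect_error(mds_embed(rdm(D[1:3, 1:3], letters[1:3]), n_dims = 3L),
               "below the number")
  # determinism given seed
  e1 <- mds_embed(rdm(D, letters[1:8]), n_restarts = 3L, seed = 2L)
  e2 <- mds_embed(rdm(D, letters[1:8]), n_restarts = 3L, seed = 2L)
  expect_identical(e1$points, e2$points)
})

test_that("two noisy sessions from one plant give consistent model RDMs", {
  ms <- small_movements()
  target <- small_target(ms, seed = 31L)
  rdm_of <- function(seed) {
    g <- gen_glove_session(ms, plant_spec(target, noise_sd = 0.2, seed = seed),
                           n_runs = 1L, trials_per_block = 4L)
    channel_correlation_rdm(average_by_condition(g, ms$labels))
  }
  r1 <- rdm_of(101L)
  r2 <- rdm_of(202L)
  expect_gt(brute_spearman(unclass(r1), unclass(r2)), 0.9)
})
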