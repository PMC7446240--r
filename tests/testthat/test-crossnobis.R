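test_that("noise covariance matches hand arithmetic and shrinkage limits", {
  # 2-feature toy residuals, shrinkage 0: (1/T) R'R by hand
  R <- matrix(c(1, 2, -1, 3,
                0.5, -1, 2, 1), ncol = 2)
  S <- estimate_noise_cov(R, shrinkage = 0)
  expect_equal(S$values, crossprod(R) / 4, tolerance = 1e-12)

  # orthonormal columns scaled by sqrt(T) -> identity
  Q <- qr.Q(qr(matrix(rnorm(30), 10))) * sqrt(10)
  expect_equal(estimate_noise_cov(Q, shrinkage = 0)$values, diag(3),
               tolerance = 1e-10)

  # full shrinkage -> diagonal of the sample covariance
  S1 <- estimate_noise_cov(R, shrinkage = 1)
  expect_equal(S1$values, diag(diag(crossprod(R) / 4)), tolerance = 1e-12)

  # auto shrinkage lies in [0, 1]; NaN residuals rejected
  set.seed(2)
  Sa <- estimate_noise_cov(matrix(rnorm(40), 10), shrinkage = "auto")
  expect_gte(Sa$shrinkage, 0); expect_lte(Sa$shrinkage, 1)
  expect_error(estimate_noise_cov(matrix(c(NA, 1, 2, 3), 2)), "NA")
  expect_error(estimate_noise_cov(matrix(1, 1, 2), 0), "2 time points")
})

test_that("whitening divides by the noise scale and round-trips", {
  P <- matrix(rnorm(12), 3)
  expect_equal(whiten_patterns(P, diag(4)), P, tolerance = 1e-12)
  # diagonal covariance diag(4, 9, 1, 1): columns divided by (2, 3, 1, 1)
  W <- whiten_patterns(P, diag(c(4, 9, 1, 1)))
  expect_equal(W, sweep(P, 2, c(2, 3, 1, 1), "/"), tolerance = 1e-12)
  # round trip through the covariance square root
  set.seed(4)
  A <- crossprod(matrix(rnorm(40), 10, 4)) / 10
  sq <- with(eigen(A, symmetric = TRUE),
             vectors %*% (t(vectors) * sqrt(values)))
  expect_equal(whiten_patterns(P %*% sq, A), P, tolerance = 1e-8)
  expect_error(whiten_patterns(P, diag(3)), "disagree")
})

test_that("whitening by estimated covariance normalizes residuals", {
  # whiten_patterns(estimate_noise_cov) drives the residual covariance to
  # the identity as T grows (T = 10000, V = 5, Frobenius tolerance 0.05)
  set.seed(9)
  mix <- matrix(rnorm(25), 5)
  R <- matrix(rnorm(10000 * 5), 10000) %*% mix
  ncov <- estimate_noise_cov(R, shrinkage = 0)
  Rw <- whiten_patterns(R, ncov)
  expect_lt(norm(crossprod(Rw) / 10000 - diag(5), "F"), 0.05)
})

test_that("crossnobis equals the direct squared Mahalanobis on clean folds", {
  set.seed(5)
  n <- 6L; V <- 8L
  P <- matrix(rnorm(n * V), n, V, dimnames = list(letters[1:n], NULL))
  Sig <- crossprod(matrix(rnorm(V * V), V)) / V + diag(V)
  Pw <- whiten_patterns(P, Sig)
  folds <- fold_patterns(list(Pw, Pw, Pw))
  got <- crossnobis_rdm(folds)
  # oracle: d2(k,l) = (P_k - P_l) Sigma^-1 (P_k - P_l)' / V
  Sinv <- solve(Sig)
  for (k in 1:(n - 1)) for (l in (k + 1):n) {
    dkl <- P[k, ] - P[l, ]
    expect_equal(unclass(got)[k, l],
                 drop(dkl %*% Sinv %*% dkl) / V, tolerance = 1e-8)
  }
  # identical conditions across folds -> exactly zero distance
  P2 <- Pw; P2[2L, ] <- P2[1L, ]
  z <- crossnobis_rdm(fold_patterns(list(P2, P2)))
  expect_equal(unclass(z)[1L, 2L], 0, tolerance = 1e-12)
  # both fold schemes agree on noiseless equal folds
  expect_equal(unclass(crossnobis_rdm(folds, scheme = "pairs")),
               unclass(got), tolerance = 1e-10)
  expect_error(crossnobis_rdm(fold_patterns(list(Pw))), "2 folds")
})

test_that("crossnobis is unbiased under the null", {
  # identical condition means: the signed mean distance straddles zero
  set.seed(6)
  n_sim <- 300L
  means <- replicate(n_sim, {
    folds <- fold_patterns(lapply(1:4, function(i) matrix(rnorm(5 * 6), 5)))
    mean(spatempRSA:::lower_tri(unclass(crossnobis_rdm(folds))))
  })
  expect_lt(abs(mean(means)) / (sd(means) / sqrt(n_sim)), 3)  # within 3 SE
  # sign test: positives and negatives both occur at ~half rate
  p_sign <- binom.test(sum(means > 0), n_sim)$p.value
  expect_gt(p_sign, 0.001)
})

test_that("spearman_rdm matches brute force and is rank-invariant", {
  set.seed(8)
  D <- as.matrix(dist(matrix(rnorm(8), 4)))
  M <- as.matrix(dist(matrix(rnorm(8), 4)))
  r1 <- spearman_rdm(rdm(D, letters[1:4]), rdm(M, letters[1:4]))
  expect_equal(r1$rho, brute_spearman(D, M), tolerance = 1e-12)
  expect_identical(r1$n_pairs, 6L)
  # model vs itself -> 1; vs rank-reversed copy -> -1
  expect_equal(spearman_rdm(rdm(D, letters[1:4]), rdm(D, letters[1:4]))$rho, 1)
  Drev <- max(D) - D; diag(Drev) <- 0
  expect_equal(spearman_rdm(rdm(Drev, letters[1:4]), rdm(D, letters[1:4]))$rho,
               -1)
  # invariance under strictly monotone transforms of either RDM
  r2 <- spearman_rdm(rdm(sqrt(D), letters[1:4]), rdm(exp(M) - 1, letters[1:4]))
  expect_equal(r2$rho, r1$rho, tolerance = 1e-12)
  # constant model rejected; mismatched labels rejected
  expect_error(spearman_rdm(rdm(D, letters[1:4]),
                            rdm(matrix(1, 4, 4) - diag(4), letters[1:4])),
               "constant")
  expect_error(spearman_rdm(rdm(D, letters[1:4]), rdm(M, LETTERS[1:4])),
               "labels")
})

test_that("partial spearman discounts the control model", {
  set.seed(10)
  n <- 8L
  labs <- letters[1:n]
  M <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  # control with exactly zero rank correlation to the model:
  # build by permuting the model entries until the rank correlation vanishes
  mv <- M[lower.tri(M)]
  rm_ <- rank(mv)
  repeat {
    cv <- sample(mv)
    if (abs(cor(rank(cv), rm_)) < 1e-12) break
  }
  C <- matrix(0, n, n); C[lower.tri(C)] <- cv; C <- C + t(C)
  D <- M  # data generated exactly from the model
  pr <- partial_spearman_rdm(rdm(D, labs), rdm(M, labs), rdm(C, labs))
  sr <- spearman_rdm(rdm(D, labs), rdm(M, labs))
  expect_equal(pr$rho, sr$rho, tolerance = 1e-10)
  expect_equal(pr$rho, 1, tolerance = 1e-10)

  # data generated from the control: partial rho of the model is ~ 0
  set.seed(12)
  rhos <- replicate(100, {
    Mx <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    cpts <- matrix(rnorm(n * 3), n)
    Cx <- as.matrix(dist(cpts))
    # data carry (almost) exactly the control geometry
    Dx <- as.matrix(dist(cpts + 0.15 * matrix(rnorm(n * 3), n)))
    partial_spearman_rdm(rdm(Dx, labs), rdm(Mx, labs), rdm(Cx, labs))$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)

  expect_error(partial_spearman_rdm(rdm(D, labs), rdm(M, labs), rdm(M, labs)),
               "identical")
})

test_that("noise ceiling bounds achievable model fit", {
  ms <- small_movements(6L)
  base <- small_target(ms, seed = 41L)
  # all subjects identical -> ceiling exactly 1
  subs <- replicate(4, base, simplify = FALSE)
  expect_equal(noise_ceiling_upper(subs), 1)
  # two rank-opposite subjects: finite, reported under the tie rule
  m <- unclass(base)
  opp <- max(m) - m; diag(opp) <- 0
  r2 <- noise_ceiling_upper(list(base, rdm(opp, ms$labels)))
  expect_true(is.finite(r2))
  # noisy subjects: ceiling >= mean subject-vs-truth rho in expectation
  set.seed(14)
  diffs <- replicate(100, {
    subjects <- lapply(1:5, function(i) {
      noise <- as.matrix(dist(matrix(rnorm(6 * 3), 6)))
      rdm(m + 0.7 * noise, ms$labels)
    })
    ceiling_v <- noise_ceiling_upper(subjects)
    truth_v <- mean(sapply(subjects, function(s)
      brute_spearman(unclass(s), m)))
    ceiling_v - truth_v
  })
  expect_gt(mean(diffs), 0)
  expect_error(noise_ceiling_upper(list(base,
                                        rdm(m, rev(ms$labels)))), "labels")
})
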