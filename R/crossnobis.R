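#' Noise covariance from GLM residuals
#'
#' Estimates the feature x feature noise covariance from a T x V residual
#' matrix as `(1/T) R'R`, optionally shrunk towards its diagonal. With
#' `shrinkage = "auto"` the shrinkage intensity is chosen analytically
#' (Ledoit-Wolf/Schafer-Strimmer style: the ratio of the summed sampling
#' variances of the off-diagonal entries to their summed squares). A relative
#' eigenvalue floor of `1e-8 * max eigenvalue` is recorded and enforced when
#' the covariance is inverted, keeping searchlight-sized V x V inversions
#' well posed when V approaches or exceeds T.
#'
#' @param residuals numeric T x V matrix (time points x features), T >= 2.
#' @param shrinkage fraction in \[0, 1\], or `"auto"`.
#' @return an object of class `noise_cov`: list with `values` (V x V matrix)
#'   and `shrinkage` (the fraction used).
#' @export
estimate_noise_cov <- function(residuals, shrinkage = "auto") {
  R <- as.matrix(residuals)
  if (anyNA(R) || any(!is.finite(R))) stop("residuals contain NA/Inf")
  T_ <- nrow(R)
  if (T_ < 2L) stop("need at least 2 time points")
  S <- crossprod(R) / T_
  if (identical(shrinkage, "auto")) {
    # sampling variance of each entry of S, estimated from the per-timepoint
    # products w_t = r_t r_t'
    M2 <- crossprod(R^2) / T_            # mean of w^2
    varS <- (M2 - S^2) / (T_ - 1L)       # var of the mean of w over t
    off <- !diag(nrow(S))
    denom <- sum(S[off]^2)
    shrinkage <- if (denom > 0) min(1, max(0, sum(varS[off]) / denom)) else 0
  }
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  Ssh <- (1 - shrinkage) * S + shrinkage * diag(diag(S), nrow(S))
  structure(list(values = Ssh, shrinkage = shrinkage), class = "noise_cov")
}

#' @export
print.noise_cov <- function(x, ...) {
  cat(sprintf("<noise_cov> %d features, shrinkage = %.3g\n",
              nrow(x$values), x$shrinkage))
  invisible(x)
}

#' Spatially prewhiten condition patterns
#'
#' Multiplies a conditions x V pattern matrix on the right by the symmetric
#' inverse square root of the noise covariance, so that pattern differences
#' are expressed in units of the noise (Mahalanobis geometry). Eigenvalues
#' below the relative floor `1e-8 * max` are raised to the floor before
#' inversion.
#'
#' @param patterns conditions x V numeric matrix.
#' @param cov a [noise_cov] (or plain V x V matrix).
#' @return conditions x V whitened matrix.
#' @export
whiten_patterns <- function(patterns, cov) {
  P <- as.matrix(patterns)
  S <- if (inherits(cov, "noise_cov")) cov$values else as.matrix(cov)
  if (ncol(P) != nrow(S)) stop("pattern and covariance dimensions disagree")
  P %*% sym_inv_sqrt(S)
}

#' Per-fold condition patterns
#'
#' Bundles one conditions x features matrix per cross-validation fold
#' (fMRI runs, MEG partitions), with a shared condition label order.
#'
#' @param folds list of conditions x features matrices, all the same shape.
#' @param labels condition labels (defaults to row names of the first fold).
#' @return an object of class `fold_patterns`.
#' @export
fold_patterns <- function(folds, labels = NULL) {
  stopifnot(is.list(folds), length(folds) >= 1L)
  folds <- lapply(folds, as.matrix)
  dims <- vapply(folds, dim, integer(2L))
  if (!all(dims == dims[, 1L])) stop("all folds must share the same shape")
  labels <- labels %||% rownames(folds[[1L]]) %||%
    paste0("cond", seq_len(nrow(folds[[1L]])))
  if (length(labels) != nrow(folds[[1L]])) {
    stop("labels length must equal the number of conditions")
  }
  structure(list(folds = folds, labels = as.character(labels)),
            class = "fold_patterns")
}

#' Cross-validated Mahalanobis (crossnobis) distance RDM
#'
#' Computes, for every condition pair, the cross-validated squared distance
#' between (already whitened or noise-normalized) patterns: the pattern
#' difference measured in one fold is multiplied by the same difference
#' measured in independent data, so that noise does not inflate the distance
#' and the estimator has expectation zero when the condition means are
#' identical (entries may therefore be negative). Under
#' `scheme = "loo"` each fold in turn serves as fold A against the mean of
#' the remaining folds (fold B), and the iterations are averaged; under
#' `scheme = "pairs"` all unordered fold pairs are used. Distances are
#' divided by the number of features when `normalize_v` is `TRUE` (default),
#' making values comparable across searchlights of unequal size.
#'
#' @param folds a [fold_patterns] object with >= 2 folds.
#' @param scheme cross-validation scheme, `"loo"` or `"pairs"`.
#' @param normalize_v divide squared distances by the feature count.
#' @return an [rdm] of kind `data_crossnobis`.
#' @export
crossnobis_rdm <- function(folds, scheme = c("loo", "pairs"),
                           normalize_v = TRUE) {
  stopifnot(inherits(folds, "fold_patterns"))
  scheme <- match.arg(scheme)
  K <- length(folds$folds)
  if (K < 2L) stop("cross-validation needs >= 2 folds")
  n <- nrow(folds$folds[[1L]])
  V <- ncol(folds$folds[[1L]])
  # cross-fold Gram trick: with C = A B', the cross-validated squared
  # distance is (P_k - P_l)_A (P_k - P_l)_B' = C_kk + C_ll - C_kl - C_lk
  C <- matrix(0, n, n)
  if (scheme == "loo") {
    total <- Reduce(`+`, folds$folds)
    for (k in seq_len(K)) {
      A <- folds$folds[[k]]
      C <- C + tcrossprod(A, (total - A) / (K - 1L))
    }
    C <- C / K
  } else {
    cnt <- 0L
    for (a in seq_len(K - 1L)) {
      for (b in (a + 1L):K) {
        C <- C + tcrossprod(folds$folds[[a]], folds$folds[[b]])
        cnt <- cnt + 1L
      }
    }
    C <- C / cnt
  }
  Cs <- (C + t(C)) / 2
  d2 <- outer(diag(Cs), diag(Cs), `+`) - 2 * Cs
  diag(d2) <- 0
  if (normalize_v) d2 <- d2 / V
  rdm(d2, labels = folds$labels, kind = "data_crossnobis")
}

#' Spearman correlation between two RDMs
#'
#' Rank correlation (average ranks for ties) over the lower-triangle
#' off-diagonal entries of two RDMs with matching labels. Rank-based
#' comparison makes no distributional assumption, so model RDMs built from
#' different source data can be compared on an equal footing.
#'
#' @param data,model [rdm] objects with identical labels.
#' @return a list of class `comparison_result`: `rho` and `n_pairs`.
#' @export
spearman_rdm <- function(data, model) {
  stopifnot(inherits(data, "rdm"), inherits(model, "rdm"))
  check_same_labels(data, model)
  dv <- lower_tri(unclass(data))
  mv <- lower_tri(unclass(model))
  if (stats::sd(mv) == 0) {
    stop("model RDM is constant on the lower triangle; rank correlation undefined")
  }
  rho <- stats::cor(rank(dv), rank(mv))
  structure(list(rho = rho, n_pairs = length(dv)), class = "comparison_result")
}

#' Partial Spearman correlation between RDMs
#'
#' Rank-transforms the lower-triangle vectors of `data`, `model` and
#' `control`, then computes the partial Pearson correlation of data with
#' model given control. Used to assess one candidate model while discounting
#' the contribution of a competing model.
#'
#' @param data,model,control [rdm] objects with identical labels; `control`
#'   must be non-constant and not identical to `model`.
#' @return a list of class `comparison_result`: `rho` and `n_pairs`.
#' @export
partial_spearman_rdm <- function(data, model, control) {
  stopifnot(inherits(control, "rdm"))
  check_same_labels(data, model)
  check_same_labels(data, control)
  mv <- lower_tri(unclass(model))
  cv <- lower_tri(unclass(control))
  if (isTRUE(all.equal(mv, cv))) stop("model and control RDMs are identical")
  if (stats::sd(mv) == 0 || stats::sd(cv) == 0) {
    stop("model/control RDM constant on the lower triangle")
  }
  dv <- lower_tri(unclass(data))
  rd <- rank(dv); rm_ <- rank(mv); rc <- rank(cv)
  r_dm <- stats::cor(rd, rm_)
  r_dc <- stats::cor(rd, rc)
  r_mc <- stats::cor(rm_, rc)
  denom <- sqrt((1 - r_dc^2) * (1 - r_mc^2))
  if (denom == 0) stop("control RDM is rank-collinear with data or model")
  rho <- (r_dm - r_dc * r_mc) / denom
  structure(list(rho = rho, n_pairs = length(dv)), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> rho = %.4f over %d pairs\n",
              x$rho, x$n_pairs))
  invisible(x)
}

#' Upper bound of the noise ceiling
#'
#' The achievable model fit is bounded by inter-subject consistency: each
#' subject's RDM is Spearman-correlated with the unweighted cross-subject
#' average RDM, and the correlations are averaged. Because each subject's
#' data contribute to the average, this is an upper bound.
#'
#' @param subject_rdms list of >= 2 [rdm] objects with identical labels.
#' @return the ceiling value (mean Spearman rho).
#' @export
noise_ceiling_upper <- function(subject_rdms) {
  stopifnot(is.list(subject_rdms), length(subject_rdms) >= 2L)
  labs <- rdm_labels(subject_rdms[[1L]])
  for (s in subject_rdms) {
    if (!identical(rdm_labels(s), labs)) {
      stop("subject RDMs have mismatching labels")
    }
  }
  avg <- Reduce(`+`, lapply(subject_rdms, unclass)) / length(subject_rdms)
  av <- lower_tri(avg)
  mean(vapply(subject_rdms, function(s) {
    sv <- lower_tri(unclass(s))
    if (stats::sd(sv) == 0 || stats::sd(av) == 0) return(0)
    stats::cor(rank(sv), rank(av))
  }, numeric(1L)))
}

#' Lower bound of the noise ceiling (utility)
#'
#' Leave-one-out variant: each subject's RDM is correlated with the average
#' of the other subjects' RDMs. Provided as a descriptive utility alongside
#' [noise_ceiling_upper].
#' @inheritParams noise_ceiling_upper
#' @return the lower-bound value.
#' @export
noise_ceiling_lower <- function(subject_rdms) {
  stopifnot(is.list(subject_rdms), length(subject_rdms) >= 2L)
  total <- Reduce(`+`, lapply(subject_rdms, unclass))
  mean(vapply(seq_along(subject_rdms), function(i) {
    others <- (total - unclass(subject_rdms[[i]])) / (length(subject_rdms) - 1L)
    sv <- lower_tri(unclass(subject_rdms[[i]]))
    ov <- lower_tri(others)
    if (stats::sd(sv) == 0 || stats::sd(ov) == 0) return(0)
    stats::cor(rank(sv), rank(ov))
  }, numeric(1L)))
}
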