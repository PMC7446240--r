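# Surface searchlight RSA: per-vertex crossnobis RDMs, model-comparison maps,
# omnibus (max-statistic) permutation thresholds, group summaries.

#' Per-vertex crossnobis data RDMs
#'
#' For every searchlight: restrict the per-run condition patterns to the
#' searchlight's features, estimate the local noise covariance from the
#' pooled run residuals, spatially prewhiten, and compute the crossnobis RDM
#' across runs. Searchlights with fewer than 2 features are marked missing.
#'
#' @param patterns_by_run list (one per run) of condition x feature matrices
#'   over the full feature set.
#' @param residuals_by_run list (one per run) of time x feature residual
#'   matrices.
#' @param searchlights a [searchlight_set].
#' @param shrinkage covariance shrinkage (see [estimate_noise_cov]).
#' @param scheme cross-validation scheme (see [crossnobis_rdm]).
#' @return a list: `rdm_vectors` (n_pairs x n_vertices matrix of
#'   lower-triangle RDM vectors, NA columns for missing vertices) and
#'   `labels`.
#' @export
searchlight_data_rdms <- function(patterns_by_run, residuals_by_run,
                                  searchlights, shrinkage = "auto",
                                  scheme = "loo") {
  stopifnot(inherits(searchlights, "searchlight_set"),
            length(patterns_by_run) >= 2L,
            length(patterns_by_run) == length(residuals_by_run))
  labels <- rownames(patterns_by_run[[1L]]) %||%
    paste0("cond", seq_len(nrow(patterns_by_run[[1L]])))
  n <- length(labels)
  nv <- length(searchlights$features)
  out <- matrix(NA_real_, n_pairs(n), nv)
  for (v in seq_len(nv)) {
    feats <- searchlights$features[[v]]
    if (length(feats) < 2L) next
    res <- do.call(rbind, lapply(residuals_by_run, function(r) {
      r[, feats, drop = FALSE]
    }))
    ncov <- estimate_noise_cov(res, shrinkage = shrinkage)
    folds <- lapply(patterns_by_run, function(p) {
      whiten_patterns(p[, feats, drop = FALSE], ncov)
    })
    d <- crossnobis_rdm(fold_patterns(folds, labels = labels), scheme = scheme)
    out[, v] <- lower_tri(unclass(d))
  }
  list(rdm_vectors = out, labels = labels)
}

#' Searchlight model-correlation map
#'
#' Spearman-correlates each searchlight's crossnobis data RDM with a model
#' RDM and assigns the resulting rho to the searchlight's central vertex.
#'
#' @inheritParams searchlight_data_rdms
#' @param model an [rdm] with labels matching the patterns.
#' @return a `stat_map`: list with `values` (per-vertex rho, NA where
#'   missing) and bookkeeping fields.
#' @export
searchlight_rho_map <- function(patterns_by_run, residuals_by_run,
                                searchlights, model, shrinkage = "auto",
                                scheme = "loo") {
  dr <- searchlight_data_rdms(patterns_by_run, residuals_by_run,
                              searchlights, shrinkage, scheme)
  rho_map_from_rdms(dr, model, searchlights)
}

rho_map_from_rdms <- function(dr, model, searchlights) {
  stopifnot(inherits(model, "rdm"))
  if (!identical(rdm_labels(model), dr$labels)) {
    model <- rdm_reorder(model, dr$labels)
  }
  mv <- rank(lower_tri(unclass(model)))
  if (stats::sd(mv) == 0) stop("model RDM is constant on the lower triangle")
  vals <- apply(dr$rdm_vectors, 2L, function(dv) {
    if (anyNA(dv)) return(NA_real_)
    stats::cor(rank(dv), mv)
  })
  structure(list(values = vals, threshold = NULL, mask = NULL,
                 alpha = NULL, n_perm = NULL, seed = NULL,
                 diameter_mm = searchlights$diameter_mm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  ok <- is.finite(x$values)
  cat(sprintf("<stat_map> %d vertices (%d missing), rho in [%.3f, %.3f]\n",
              length(x$values), sum(!ok), min(x$values[ok]), max(x$values[ok])))
  if (!is.null(x$threshold)) {
    cat(sprintf("  omnibus threshold %.4f (alpha = %g, %d permutations), %d significant\n",
                x$threshold, x$alpha, x$n_perm, sum(x$mask, na.rm = TRUE)))
  }
  invisible(x)
}

#' Omnibus (max-statistic) permutation threshold for a searchlight map
#'
#' Fixed-effects randomization test: for each permutation the condition
#' labels of every searchlight's data RDM are permuted (rows and columns of
#' the RDM, one shared permutation per iteration), the full rho map is
#' recomputed, and its spatial maximum recorded. The threshold is the
#' `ceiling(alpha * n_perm)`-th largest of the maximum-rho null distribution,
#' which controls the family-wise error across vertices at level `alpha`;
#' the mask marks vertices at or above it.
#'
#' @inheritParams searchlight_rho_map
#' @param n_perm number of label permutations (default 10000).
#' @param alpha family-wise error level (default 0.01).
#' @param seed integer seed recorded in the output.
#' @param data_rdms optionally, precomputed output of
#'   [searchlight_data_rdms] (skips recomputation).
#' @return a `stat_map` with `threshold`, `mask` and the null `max_dist`.
#' @export
omnibus_threshold <- function(patterns_by_run = NULL, residuals_by_run = NULL,
                              searchlights, model, n_perm = 10000L,
                              alpha = 0.01, seed = 1L, shrinkage = "auto",
                              scheme = "loo", data_rdms = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_perm < 100L) stop("use at least 100 permutations")
  dr <- data_rdms %||% searchlight_data_rdms(
    patterns_by_run, residuals_by_run, searchlights, shrinkage, scheme)
  map <- rho_map_from_rdms(dr, model, searchlights)
  n <- length(dr$labels)
  if (!identical(rdm_labels(model), dr$labels)) {
    model <- rdm_reorder(model, dr$labels)
  }
  mv <- rank(lower_tri(unclass(model)))
  mstd <- (mv - mean(mv)) / sqrt(sum((mv - mean(mv))^2))
  idx_full <- full_index_matrix(n)
  lower_sel <- lower.tri(matrix(0, n, n))
  perms <- with_seed(seed, replicate(n_perm, sample(n), simplify = FALSE))
  # per permutation: index vector mapping the canonical lower-tri vector to
  # the label-permuted one (shared across vertices)
  IDX <- vapply(perms, function(p) idx_full[p, p][lower_sel], integer(sum(lower_sel)))
  ok <- which(!apply(dr$rdm_vectors, 2L, anyNA))
  max_dist <- rep(-Inf, n_perm)
  for (v in ok) {
    # a label permutation reindexes the RDM vector, so its ranks are the
    # reindexed ranks: rank once, standardize once, then index
    sdv <- rank(dr$rdm_vectors[, v])
    sdv <- (sdv - mean(sdv)) / sqrt(sum((sdv - mean(sdv))^2))
    rho_p <- as.vector(crossprod(matrix(sdv[IDX], nrow = nrow(IDX)), mstd))
    max_dist <- pmax(max_dist, rho_p)
  }
  thr <- sort(max_dist, decreasing = TRUE)[ceiling(alpha * n_perm)]
  map$threshold <- thr
  map$mask <- !is.na(map$values) & map$values >= thr
  map$alpha <- alpha
  map$n_perm <- n_perm
  map$seed <- seed
  map$max_dist <- max_dist
  map
}

#' Group heatmap of binarized searchlight masks
#'
#' Counts, per vertex, the number of subjects whose thresholded searchlight
#' map is significant there.
#'
#' @param subject_masks list of `stat_map`s with masks, or of logical
#'   vectors, all over the same mesh.
#' @return integer vector of per-vertex counts (max is the subject count).
#' @export
group_heatmap <- function(subject_masks) {
  masks <- lapply(subject_masks, function(m) {
    if (inherits(m, "stat_map")) {
      if (is.null(m$mask)) stop("stat_map has no mask; threshold it first")
      m$mask
    } else as.logical(m)
  })
  lens <- lengths(masks)
  if (length(unique(lens)) != 1L) stop("masks are over different meshes")
  counts <- Reduce(`+`, lapply(masks, function(m) as.integer(m & !is.na(m))))
  counts
}

# Exact one-sided signed-rank p-value under the sign-flip null (P(V >= v)),
# with average ranks for tied magnitudes; zero differences are dropped and
# an all-zero vector gives p = 1. Exact for any n via integer dynamic
# programming over doubled ranks.
signed_rank_p <- function(d) {
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (!length(nz)) return(1)
  r2 <- as.integer(round(2 * rank(abs(nz))))
  v_obs <- sum(r2[nz > 0])
  tot <- sum(r2)
  cnt <- numeric(tot + 1L)
  cnt[1L] <- 1
  for (w in r2) {
    cnt <- cnt + c(rep(0, w), cnt[seq_len(tot + 1L - w)])
  }
  sum(cnt[(v_obs + 1L):(tot + 1L)]) / 2^length(r2)
}

#' Contrast two models' searchlight maps across subjects
#'
#' Per vertex, a one-sided Wilcoxon signed-rank test on the subject-wise rho
#' differences (A - B), with an exact sign-flip null (computed by dynamic
#' programming, so ties are handled exactly), followed by Benjamini-Hochberg
#' FDR correction across analyzed vertices. Vertices with all-zero
#' differences get p = 1.
#'
#' @param maps_A,maps_B lists of unthresholded `stat_map`s (or numeric
#'   vectors), same subjects and mesh in both.
#' @param fdr_alpha FDR level (default 0.05).
#' @return a list of class `map_contrast`: `p`, `p_fdr`, `significant`
#'   (logical per vertex), `fdr_alpha`.
#' @export
contrast_model_maps <- function(maps_A, maps_B, fdr_alpha = 0.05) {
  vals <- function(m) if (inherits(m, "stat_map")) m$values else as.numeric(m)
  A <- do.call(rbind, lapply(maps_A, vals))
  B <- do.call(rbind, lapply(maps_B, vals))
  if (!all(dim(A) == dim(B))) stop("map lists differ in subjects or mesh")
  if (nrow(A) < 5L) stop("need >= 5 subjects for the signed-rank contrast")
  nv <- ncol(A)
  p <- rep(NA_real_, nv)
  for (v in seq_len(nv)) {
    d <- A[, v] - B[, v]
    if (anyNA(d)) next
    p[v] <- signed_rank_p(d)
  }
  analyzed <- which(!is.na(p))
  p_fdr <- rep(NA_real_, nv)
  p_fdr[analyzed] <- stats::p.adjust(p[analyzed], method = "BH")
  structure(list(p = p, p_fdr = p_fdr,
                 significant = !is.na(p_fdr) & p_fdr <= fdr_alpha,
                 fdr_alpha = fdr_alpha),
            class = "map_contrast")
}

#' @export
print.map_contrast <- function(x, ...) {
  cat(sprintf("<map_contrast> %d vertices analyzed, %d significant at FDR %g\n",
              sum(!is.na(x$p)), sum(x$significant), x$fdr_alpha))
  invisible(x)
}

#' Fit a surface searchlight RSA
#'
#' End-to-end spatial analysis of one session: first-level GLM per run
#' (boxcar x gamma HRF + temporal derivative per condition), searchlight
#' construction at `diameter_mm`, per-searchlight noise-normalized
#' crossnobis RDMs, Spearman comparison against a model RDM, and (optionally)
#' an omnibus permutation threshold.
#'
#' @param session an `fmri_session` (see [gen_fmri_session]), or a list with
#'   `runs` (each `series` voxel x time + `events`), `mesh`, `tr_s`,
#'   `labels`.
#' @param model an [rdm].
#' @param diameter_mm searchlight diameter (default 10).
#' @param n_perm permutations for the omnibus threshold; 0 skips inference.
#' @param alpha omnibus family-wise error level (default 0.01).
#' @param seed permutation seed.
#' @param shrinkage,scheme forwarded to the crossnobis machinery.
#' @return an object of class `searchlight_rsa`: the `stat_map`, the fitted
#'   GLMs, the searchlight set, and call parameters.
#' @export
searchlight_rsa <- function(session, model, diameter_mm = 10,
                            n_perm = 10000L, alpha = 0.01, seed = 1L,
                            shrinkage = "auto", scheme = "loo") {
  fits <- lapply(session$runs, function(r) {
    fit_glm(r$series, r$events, tr_s = session$tr_s,
            conditions = session$labels)
  })
  patterns <- lapply(fits, `[[`, "patterns")
  residuals <- lapply(fits, `[[`, "residuals")
  sls <- build_searchlights(session$mesh, diameter_mm = diameter_mm)
  dr <- searchlight_data_rdms(patterns, residuals, sls,
                              shrinkage = shrinkage, scheme = scheme)
  map <- if (n_perm > 0L) {
    omnibus_threshold(searchlights = sls, model = model, n_perm = n_perm,
                      alpha = alpha, seed = seed, data_rdms = dr)
  } else {
    rho_map_from_rdms(dr, model, sls)
  }
  structure(list(map = map, searchlights = sls, glm_fits = fits,
                 model = model, mesh = session$mesh,
                 params = list(diameter_mm = diameter_mm, n_perm = n_perm,
                               alpha = alpha, seed = seed)),
            class = "searchlight_rsa")
}

#' @export
print.searchlight_rsa <- function(x, ...) {
  cat("Surface searchlight RSA\n")
  print(x$map)
  invisible(x)
}

#' @export
summary.searchlight_rsa <- function(object, ...) {
  v <- object$map$values
  peak <- which.max(v)
  cat("Surface searchlight RSA\n")
  cat(sprintf("  searchlights: %d (diameter %g mm)\n",
              length(v), object$params$diameter_mm))
  cat(sprintf("  peak rho %.4f at vertex %d\n", v[peak], peak))
  if (!is.null(object$map$threshold)) {
    cat(sprintf("  omnibus threshold %.4f (alpha %g, %d perms): %d significant vertices\n",
                object$map$threshold, object$params$alpha,
                object$params$n_perm, sum(object$map$mask, na.rm = TRUE)))
  }
  invisible(object)
}

#' @export
plot.searchlight_rsa <- function(x, ...) {
  v <- x$map$values
  graphics::hist(v, breaks = 30, main = "Searchlight rho map",
                 xlab = "Spearman rho", ...)
  if (!is.null(x$map$threshold)) {
    graphics::abline(v = x$map$threshold, col = "red", lty = 2)
  }
  invisible(x)
}
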