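# fMRI forward model and first-level GLM.

#' Gamma haemodynamic response function
#'
#' Single-gamma HRF (no undershoot) with shape 7 and scale 1 s, i.e. mode
#' (peak) at 6 s, normalized to peak amplitude 1.
#'
#' @param t time in seconds (>= 0).
#' @param shape,scale gamma parameters; defaults give a 6 s peak.
#' @return HRF values at `t`.
#' @export
gamma_hrf <- function(t, shape = 7, scale = 1) {
  h <- stats::dgamma(t, shape = shape, scale = scale)
  peak <- stats::dgamma((shape - 1) * scale, shape = shape, scale = scale)
  h / peak
}

# Condition regressors: per condition a boxcar convolved with the gamma HRF,
# plus its temporal derivative; built on a 0.1 s grid and sampled at volume
# acquisition times. Shared by the generator and the GLM so that noiseless
# recovery is exact.
condition_design <- function(events, n_vols, tr_s, conditions = NULL,
                             dt = 0.1) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) stop("event table is empty")
  conditions <- conditions %||% unique(events$condition)
  unknown <- setdiff(events$condition, conditions)
  if (length(unknown)) {
    stop("events reference unknown conditions: ", paste(unknown, collapse = ", "))
  }
  total_s <- n_vols * tr_s
  grid <- seq(0, total_s + 32, by = dt)
  hrf <- gamma_hrf(seq(0, 32, by = dt))
  vol_t <- (seq_len(n_vols) - 1L) * tr_s
  X <- matrix(0, n_vols, 2L * length(conditions))
  cn <- character(2L * length(conditions))
  for (i in seq_along(conditions)) {
    box <- numeric(length(grid))
    ev <- events[events$condition == conditions[i], , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      box[grid >= ev$onset_s[r] & grid < ev$onset_s[r] + ev$duration_s[r]] <- 1
    }
    reg_fine <- stats::convolve(box, rev(hrf), type = "open")[seq_along(grid)] * dt
    reg <- stats::approx(grid, reg_fine, xout = vol_t, rule = 2)$y
    dreg <- c(0, diff(reg)) / tr_s
    X[, 2L * i - 1L] <- reg
    X[, 2L * i] <- dreg
    cn[2L * i - 1L] <- as.character(conditions[i])
    cn[2L * i] <- paste0(conditions[i], ":deriv")
  }
  colnames(X) <- cn
  X
}

#' Simulate an fMRI-like session on a surface mesh
#'
#' Forward model for surface-sampled BOLD data with a planted
#' representational geometry: inside `plant$region` the condition activation
#' patterns (betas) realize `plant$target_rdm` via
#' [plant_condition_patterns]; outside the region betas are pure Gaussian
#' noise of matched scale. Each run's time series is the condition design
#' (boxcar convolved with a gamma HRF) times the betas plus AR(1) noise, and
#' comes with an event table (block onsets, durations, conditions; one block
#' per condition per run in seeded random order, with optional rest blocks).
#'
#' @param mesh a [surface_mesh] with >= 50 vertices (smaller meshes are
#'   allowed with `strict = FALSE` for scaled-down simulations).
#' @param plant a [plant_spec] whose `region` indexes mesh vertices.
#' @param movements a [movement_set].
#' @param n_runs number of runs.
#' @param tr_s repetition time in seconds (default 1.5).
#' @param block_s block duration in seconds (default 17).
#' @param n_rest_blocks rest blocks inserted per run (default 0 for compact
#'   simulated runs).
#' @param ar_coef AR(1) coefficient of the noise (default 0.3).
#' @param strict enforce the >= 50 vertex precondition.
#' @return a list of class `fmri_session`: `runs` (each with `series`, a
#'   voxel x time matrix, and `events`), `betas` (the generating condition x
#'   voxel matrix), `mesh`, `plant`, `tr_s`.
#' @export
gen_fmri_session <- function(mesh, plant, movements, n_runs = 4L, tr_s = 1.5,
                             block_s = 17, n_rest_blocks = 0L, ar_coef = 0.3,
                             strict = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(plant, "plant_spec"),
            inherits(movements, "movement_set"))
  if (strict && n_vertices(mesh) < 50L) {
    stop("mesh must have >= 50 vertices (use strict = FALSE to scale down)")
  }
  region <- plant$region
  if (is.null(region)) stop("plant$region must index mesh vertices")
  if (any(region < 1L) || any(region > n_vertices(mesh))) {
    stop("plant region lies outside the mesh")
  }
  labels <- movements$labels
  if (!identical(sort(labels), sort(rdm_labels(plant$target_rdm)))) {
    stop("plant target RDM labels must match the movement set")
  }
  n_cond <- length(labels)
  nv <- n_vertices(mesh)
  seeds <- derive_seeds(plant$seed, 2L + n_runs)
  pat <- plant_condition_patterns(
    plant$target_rdm, n_features = length(region), seed = seeds[1L])
  pat <- pat[labels, , drop = FALSE]
  betas <- matrix(0, n_cond, nv, dimnames = list(labels, NULL))
  betas[, region] <- plant$signal_scale * pat
  outside <- setdiff(seq_len(nv), region)
  if (length(outside)) {
    # null vertices: noise-only betas of comparable magnitude
    amp <- plant$signal_scale * stats::sd(as.vector(pat))
    betas[, outside] <- with_seed(seeds[2L],
      matrix(stats::rnorm(n_cond * length(outside), sd = amp), n_cond))
  }
  n_blocks <- n_cond + n_rest_blocks
  n_vols <- ceiling((n_blocks * block_s) / tr_s) + 4L
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run <- with_seed(seeds[2L + r], {
      order_r <- sample(n_blocks)
      is_rest <- order_r > n_cond
      cond_seq <- ifelse(is_rest, "rest", labels[pmin(order_r, n_cond)])
      events_all <- data.frame(
        onset_s = (seq_len(n_blocks) - 1L) * block_s,
        duration_s = block_s,
        condition = cond_seq, stringsAsFactors = FALSE)
      events <- events_all[events_all$condition != "rest", , drop = FALSE]
      X <- condition_design(events, n_vols, tr_s, conditions = labels)
      main <- X[, seq(1L, ncol(X), by = 2L), drop = FALSE]  # HRF regressors
      Y <- main %*% betas
      if (plant$noise_sd > 0) {
        eps <- matrix(stats::rnorm(n_vols * nv), n_vols, nv)
        for (t in 2:n_vols) eps[t, ] <- ar_coef * eps[t - 1L, ] + eps[t, ]
        Y <- Y + plant$noise_sd * eps
      }
      list(series = t(Y), events = events, events_with_rest = events_all)
    })
    runs[[r]] <- run
  }
  structure(list(runs = runs, betas = betas, mesh = mesh, plant = plant,
                 tr_s = tr_s, labels = labels),
            class = "fmri_session")
}

#' First-level GLM on one run
#'
#' Ordinary least squares with, per condition, a boxcar regressor convolved
#' with a gamma HRF plus its temporal derivative (52 condition regressors for
#' 26 conditions), and an intercept. Returns the per-condition main-regressor
#' estimates (the activation patterns used downstream) and the residual
#' matrix that feeds the noise-covariance estimate.
#'
#' @param run_series voxel x time numeric matrix.
#' @param events event table (`onset_s`, `duration_s`, `condition`).
#' @param tr_s repetition time in seconds.
#' @param conditions condition order of the output patterns.
#' @return a list of class `glm_fit`: `patterns` (condition x voxel),
#'   `residuals` (time x voxel), `design` (time x regressors, intercept
#'   last), `n_condition_regressors`.
#' @export
fit_glm <- function(run_series, events, tr_s, conditions = NULL) {
  Y <- t(as.matrix(run_series))  # time x voxel
  n_vols <- nrow(Y)
  conditions <- conditions %||% unique(events$condition)
  X <- condition_design(events, n_vols, tr_s, conditions = conditions)
  n_cond_reg <- ncol(X)
  Xf <- cbind(X, intercept = 1)
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[(qrX$rank + 1L):ncol(Xf)]]
    stop("rank-deficient design; aliased columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  res <- Y - Xf %*% beta
  main_rows <- seq(1L, n_cond_reg, by = 2L)
  patterns <- beta[main_rows, , drop = FALSE]
  rownames(patterns) <- as.character(conditions)
  structure(list(patterns = patterns, residuals = res, design = Xf,
                 n_condition_regressors = n_cond_reg),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d condition regressors (+ intercept), %d voxels, %d volumes\n",
              x$n_condition_regressors, ncol(x$patterns), nrow(x$residuals)))
  invisible(x)
}
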