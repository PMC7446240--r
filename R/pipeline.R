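#' Run the full pipeline from a declarative config
#'
#' Executes simulate -> model RDMs -> analysis (searchlight and/or temporal)
#' from a YAML configuration, writing all stage outputs plus a manifest
#' (package version, seed, parameters, output checksums) under the output
#' directory. The config schema is strict: unknown keys are rejected, so
#' typos in permutation counts or alpha levels cannot pass silently.
#'
#' Config structure (see `inst/extdata/demo_config.yaml` for a worked
#' example):
#' \preformatted{
#' seed: 7
#' out_dir: results
#' n_conditions: 12            # leading subset of the 26-movement set
#' geometry_dim: 3
#' glove: {n_runs: 2, trials_per_block: 4, noise_sd: 0.2, signal_scale: 1}
#' fmri:  {subdivisions: 1, radius_mm: 8, n_runs: 4, noise_sd: 1,
#'         signal_scale: 1, region_size: 12, diameter_mm: 10,
#'         n_perm: 500, alpha: 0.01}
#' meg:   {n_sources: 12, fs: 250, trials_per_condition: 20, band: beta,
#'         window: [-210, -90], epoch: [-500, 1500], noise_sd: 1,
#'         signal_scale: 1, n_partitions: 10, n_perm: 200,
#'         cluster_p: 0.01, fwe_alpha: 0.005}
#' }
#' The `fmri` and `meg` sections are optional; omitted stages are skipped.
#'
#' @param config_path path to the YAML config.
#' @return (invisibly) a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config_path) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  allowed_top <- c("seed", "out_dir", "n_conditions", "geometry_dim",
                   "glove", "fmri", "meg")
  check_keys(cfg, allowed_top, "top level")
  for (req in c("seed", "out_dir")) {
    if (is.null(cfg[[req]])) stop("config key missing: ", req)
  }
  check_keys(cfg$glove, c("n_runs", "trials_per_block", "noise_sd",
                          "signal_scale"), "glove")
  check_keys(cfg$fmri, c("subdivisions", "radius_mm", "n_runs", "noise_sd",
                         "signal_scale", "region_size", "diameter_mm",
                         "n_perm", "alpha"), "fmri")
  check_keys(cfg$meg, c("n_sources", "fs", "trials_per_condition", "band",
                        "window", "epoch", "noise_sd", "signal_scale",
                        "n_partitions", "n_perm", "cluster_p", "fwe_alpha"),
             "meg")
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 8L)
  ms_full <- movement_set()
  n_cond <- cfg$n_conditions %||% 26L
  labels <- ms_full$labels[seq_len(n_cond)]
  ms <- movement_set(labels, ms_full$categories[labels])
  target <- random_geometry_rdm(labels, dim = cfg$geometry_dim %||% 3L,
                                seed = seeds[1L])
  results <- list()
  outputs <- character(0)
  log_stage <- function(msg) message("[run_pipeline] ", msg)

  # --- glove simulation and kinematic model RDM ------------------------
  g <- cfg$glove %||% list()
  log_stage("simulating glove session")
  glove <- gen_glove_session(
    ms, plant_spec(target, signal_scale = g$signal_scale %||% 1,
                   noise_sd = g$noise_sd %||% 0.2, seed = seeds[2L]),
    n_runs = g$n_runs %||% 2L, trials_per_block = g$trials_per_block %||% 4L)
  kin_rdm <- channel_correlation_rdm(average_by_condition(glove, labels))
  p_kin <- file.path(out_dir, "kinematic_model_rdm.csv")
  write_rdm(kin_rdm, p_kin)
  outputs <- c(outputs, p_kin)
  results$kinematic_rdm <- kin_rdm
  results$ethological_rdm <- ethological_rdm(ms)

  # --- spatial searchlight ---------------------------------------------
  if (!is.null(cfg$fmri)) {
    f <- cfg$fmri
    log_stage("simulating fMRI session and running searchlight RSA")
    mesh <- icosphere_mesh(f$subdivisions %||% 1L, f$radius_mm %||% 8)
    region <- seq_len(f$region_size %||% 12L)
    sess <- gen_fmri_session(
      mesh, plant_spec(target, region = region,
                       signal_scale = f$signal_scale %||% 1,
                       noise_sd = f$noise_sd %||% 1, seed = seeds[3L]),
      ms, n_runs = f$n_runs %||% 4L, strict = FALSE)
    sl <- searchlight_rsa(sess, kin_rdm, diameter_mm = f$diameter_mm %||% 10,
                          n_perm = f$n_perm %||% 500L,
                          alpha = f$alpha %||% 0.01, seed = seeds[4L])
    p_map <- file.path(out_dir, "searchlight_map.tsv")
    utils::write.table(
      data.frame(vertex = seq_along(sl$map$values), rho = sl$map$values,
                 significant = sl$map$mask),
      p_map, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p_map)
    results$searchlight <- sl
  }

  # --- temporal RSA -----------------------------------------------------
  if (!is.null(cfg$meg)) {
    m <- cfg$meg
    log_stage("simulating MEG session and running temporal RSA")
    epoch <- as.numeric(m$epoch %||% c(-500, 1500))
    meg <- gen_meg_session(
      plant_spec(target, window = as.numeric(m$window %||% c(-210, -90)),
                 band = m$band %||% "beta",
                 signal_scale = m$signal_scale %||% 1,
                 noise_sd = m$noise_sd %||% 1, seed = seeds[5L]),
      ms, n_sources = m$n_sources %||% 12L, fs = m$fs %||% 250,
      epoch = epoch, trials_per_condition = m$trials_per_condition %||% 20L)
    tr <- temporal_rsa(meg, kin_rdm, band = m$band %||% "beta",
                       n_partitions = m$n_partitions %||% 10L,
                       n_perm = m$n_perm %||% 200L,
                       cluster_p = m$cluster_p %||% 0.01,
                       fwe_alpha = m$fwe_alpha %||% 0.005,
                       seed = seeds[6L])
    p_cl <- file.path(out_dir, "temporal_clusters.tsv")
    utils::write.table(tr$clusters$clusters, p_cl, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p_cl)
    results$temporal <- tr
  }

  manifest <- list(
    package = "spatempRSA",
    version = as.character(utils::packageVersion("spatempRSA")),
    seed = cfg$seed,
    config = cfg,
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  p_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA)
  log_stage("wrote manifest")
  results$manifest <- manifest
  invisible(results)
}

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(TRUE))
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
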