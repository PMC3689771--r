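# Workflow orchestration: flat key-value config, single-volume detection
# runs, cohort FROC runs and tiered screening, all with reproducible CSV
# outputs.

#' Default pipeline configuration
#'
#' A flat, human-editable list of every pipeline knob with explicit
#' defaults. The named presets A/B/C map to (t3d, t2d) pairs ordered from
#' strict to permissive; the shipped values are site-calibrated on the
#' standard phantom cohort's Pareto frontier (moderate / good / high
#' sensitivity) and should be recalibrated per site or protocol.
#'
#' @return Named list of configuration values.
#' @export
defaultPipelineConfig <- function() {
  list(
    norm_p_low = 6, norm_p_high = 95, norm_out_min = 0, norm_out_max = 255,
    norm_clip = TRUE,
    rst_radii_mm = c(1, 2, 3, 4), rst_alpha = 2, rst_smooth_sigma_factor = 0.5,
    rst_grad_threshold_frac = 0.05, rst_polarity = "dark",
    t3d = 1.0, t2d = 1.0, connectivity = 26,
    minip_slab_thickness_mm = 12, minip_roi_halfwidth_mm = 12,
    minip_halo_voxels = 1,
    eval_tol_mm = 5, eval_scope = "all",
    t3d_grid = seq(0.5, 3, by = 0.5), t2d_grid = seq(0, 3, by = 0.5),
    preset_A = c(2.0, 1.5), preset_B = c(1.5, 0.5), preset_C = c(0.5, 0.0),
    seed = 20130621
  )
}

#' Read / write a pipeline configuration file
#'
#' Flat YAML mapping of the keys in [defaultPipelineConfig()]; unknown keys
#' error, missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @param config configuration list to write.
#' @return `readPipelineConfig` returns the merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    cmbStop("cmbrst_missing_file", "config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    cmbStop("cmbrst_bad_params", "unknown config key(s): %s",
            paste(unknown, collapse = ", "))
  cfg[names(user)] <- lapply(user, unlist)
  cfg
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

configObjects <- function(cfg) {
  list(
    norm = NormalizationSpec(cfg$norm_p_low, cfg$norm_p_high,
                             cfg$norm_out_min, cfg$norm_out_max,
                             cfg$norm_clip),
    rst = RSTParams(cfg$rst_radii_mm, cfg$rst_alpha,
                    cfg$rst_smooth_sigma_factor,
                    cfg$rst_grad_threshold_frac, cfg$rst_polarity),
    minip = MinIPSpec(cfg$minip_slab_thickness_mm, cfg$minip_roi_halfwidth_mm,
                      cfg$minip_halo_voxels))
}

resolveThresholds <- function(cfg, preset = NULL) {
  if (is.null(preset)) return(c(cfg$t3d, cfg$t2d))
  key <- paste0("preset_", preset)
  if (is.null(cfg[[key]]))
    cmbStop("cmbrst_bad_params", "unknown preset '%s'", preset)
  as.numeric(cfg[[key]])
}

stageStop <- function(stage, e) {
  cmbStop("cmbrst_pipeline", "[%s] %s", stage, conditionMessage(e))
}

#' Run detection on one volume/mask pair
#'
#' Full single-volume workflow: read, normalize, 3D transform, stage-1
#' clustering, stage-2 minIP filter; writes `candidates.csv` (passed and
#' rejected, with both scores) and `run_log.txt` (config checksum, per-stage
#' counts and timings) into `outDir`. Any stage failure raises an error
#' naming the stage.
#'
#' @param volumePath,maskPath NIfTI input paths.
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outDir output directory (created if needed).
#' @param preset optional preset name ("A", "B", "C") overriding t3d/t2d.
#' @return Invisibly, a list with the candidate table and output paths.
#' @export
runDetect <- function(volumePath, maskPath, config = defaultPipelineConfig(),
                      outDir, preset = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  vol <- tryCatch(readVolume(volumePath),
                  error = function(e) stageStop("read-volume", e))
  mask <- tryCatch(readVolume(maskPath),
                   error = function(e) stageStop("read-mask", e))
  obj <- configObjects(config)
  thr <- resolveThresholds(config, preset)
  det <- DetectionParams(thr[1], thr[2], config$connectivity)
  norm <- tryCatch(rangeNormalize(vol, mask, obj$norm),
                   error = function(e) stageStop("normalize", e))
  t1 <- proc.time()[["elapsed"]]
  map <- tryCatch(rstTransform(norm, obj$rst),
                  error = function(e) stageStop("rst-3d", e))
  t2 <- proc.time()[["elapsed"]]
  cand <- tryCatch(thresholdAndCluster(map, mask, det, volume = vol),
                   error = function(e) stageStop("threshold-cluster", e))
  n1 <- nrow(cand)
  cand <- tryCatch(filterCandidates(norm, cand, obj$rst, obj$minip, det@t2d),
                   error = function(e) stageStop("minip-2d", e))
  t3 <- proc.time()[["elapsed"]]
  candPath <- file.path(outDir, "candidates.csv")
  writeCandidates(cand, candPath)
  logPath <- file.path(outDir, "run_log.txt")
  writeLines(c(
    sprintf("config_checksum: %s", configChecksum(config)),
    sprintf("volume: %s", volumePath),
    sprintf("mask: %s", maskPath),
    sprintf("t3d: %g", det@t3d), sprintf("t2d: %g", det@t2d),
    sprintf("stage1_candidates: %d", n1),
    sprintf("passed_2d: %d", sum(cand$status == "passed_2d")),
    sprintf("rejected_2d: %d", sum(cand$status == "rejected_2d")),
    sprintf("seconds_normalize: %.2f", t1 - t0),
    sprintf("seconds_rst3d: %.2f", t2 - t1),
    sprintf("seconds_stage2: %.2f", t3 - t2)
  ), logPath)
  invisible(list(candidates = cand, candidatesPath = candPath,
                 logPath = logPath))
}

readManifest <- function(manifestPath) {
  if (!file.exists(manifestPath))
    cmbStop("cmbrst_missing_file", "manifest not found: %s", manifestPath)
  mf <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  if (!all(c("volume", "mask", "truth") %in% names(mf)) || nrow(mf) < 1L)
    cmbStop("cmbrst_bad_manifest",
            "manifest needs >= 1 row with columns volume, mask, truth")
  mf
}

loadCohort <- function(manifestPath) {
  mf <- readManifest(manifestPath)
  cohort <- list()
  for (r in seq_len(nrow(mf))) {
    entry <- tryCatch(
      list(volume = readVolume(mf$volume[r]), mask = readVolume(mf$mask[r]),
           truth = readGroundTruth(mf$truth[r])),
      error = function(e) {
        warning(sprintf("manifest row %d skipped: %s", r,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(entry)) cohort[[length(cohort) + 1L]] <- entry
  }
  if (length(cohort) == 0L)
    cmbStop("cmbrst_bad_manifest", "no usable manifest rows")
  cohort
}

writeFrocCsv <- function(df, path) {
  out <- df
  for (cn in names(out))
    if (is.numeric(out[[cn]])) out[[cn]] <- formatNum(out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the FROC lattice on a cohort manifest
#'
#' Evaluates every (t3d, t2d) combination of the configured grids on the
#' manifest's volumes and writes `froc.csv` (all points) and `frontier.csv`
#' (the Pareto-optimal subset), each carrying the config checksum as its
#' first comment-free column set. Deterministic given config and data.
#'
#' @param manifestPath CSV with columns volume, mask, truth.
#' @param config configuration list.
#' @param outDir output directory.
#' @return Invisibly, list(froc, frontier, paths).
#' @export
runFroc <- function(manifestPath, config = defaultPipelineConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohort <- loadCohort(manifestPath)
  obj <- configObjects(config)
  froc <- frocGrid(cohort, obj$rst, config$t3d_grid, config$t2d_grid,
                   tolMM = config$eval_tol_mm, scope = config$eval_scope,
                   normSpec = obj$norm, minipSpec = obj$minip,
                   connectivity = config$connectivity)
  frontier <- paretoFrontier(froc)
  froc$config_checksum <- configChecksum(config)
  frontier$config_checksum <- configChecksum(config)
  fp <- writeFrocCsv(froc, file.path(outDir, "froc.csv"))
  gp <- writeFrocCsv(frontier, file.path(outDir, "frontier.csv"))
  invisible(list(froc = froc, frontier = frontier, paths = c(fp, gp)))
}

#' Run tiered A -> C screening on a cohort manifest
#'
#' Applies the tiered workflow (strict preset A as a participant-level
#' screen, permissive preset C for screen-positive participants) and writes
#' `tiered.csv` with one row per participant plus the cohort sensitivity in
#' `tiered_summary.txt`.
#'
#' @inheritParams runFroc
#' @return Invisibly, the [tieredScreen()] result.
#' @export
runTiered <- function(manifestPath, config = defaultPipelineConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohort <- loadCohort(manifestPath)
  obj <- configObjects(config)
  res <- tieredScreen(cohort, obj$rst,
                      settingA = resolveThresholds(config, "A"),
                      settingC = resolveThresholds(config, "C"),
                      tolMM = config$eval_tol_mm, scope = config$eval_scope,
                      normSpec = obj$norm, minipSpec = obj$minip,
                      connectivity = config$connectivity)
  pp <- res$perParticipant
  pp$config_checksum <- configChecksum(config)
  utils::write.csv(pp, file.path(outDir, "tiered.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(c(
    sprintf("config_checksum: %s", configChecksum(config)),
    sprintf("tiered_sensitivity: %.17g", res$sensitivity),
    sprintf("flat_A_sensitivity: %.17g", res$flatA),
    sprintf("flat_C_sensitivity: %.17g", res$flatC)
  ), file.path(outDir, "tiered_summary.txt"))
  invisible(res)
}
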