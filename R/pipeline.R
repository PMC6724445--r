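#' Write a synthetic case to a directory of standard files
#'
#' Writes `tree.json`, `mask.png`, `geom.json`, `ecg.csv` and `truth.json`
#' (ground-truth pose, CTA phase, true R peaks) for a case built by
#' [generate_case()].
#'
#' @param case a `synthetic_case`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tree_json(case$tree, file.path(dir, "tree.json"))
  write_mask_png(case$mask, file.path(dir, "mask.png"))
  write_geometry(case$geom, file.path(dir, "geom.json"))
  write_ecg_csv(case$ecg, file.path(dir, "ecg.csv"))
  jsonlite::write_json(
    list(true_pose = list(t = case$true_pose$t, r = case$true_pose$r),
         cta_phase = case$cta_phase, r_peaks = case$r_peaks,
         frame_times = case$ecg$frame_times, seed = case$seed,
         scale = case$scale),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full registration pipeline on files
#'
#' Orchestrates the pipeline on a case stored as files: optional cardiac
#' phase matching (reported when an ECG is given), importance assignment,
#' initial alignment plus staged Powell registration, and — when a
#' ground-truth pose is available — evaluation. Writes `result.json` (pose,
#' AADD trace, candidate frames, metrics) and `metrics.csv` to `out_dir`.
#'
#' @param tree_path centerline-tree JSON
#' @param mask_path 2D centerline mask PNG
#' @param geom_path geometry sidecar JSON
#' @param out_dir output directory
#' @param ecg_path optional ECG CSV
#' @param cta_phase CTA reconstruction-window phase (required with
#'   `ecg_path`)
#' @param truth_path optional truth JSON (as written by [write_case()])
#' @param config nested configuration list (see [default_config()])
#' @return the `registration_result`, invisibly, with `$metrics` and
#'   `$candidates` attached when computed
#' @export
run_pipeline <- function(tree_path, mask_path, geom_path, out_dir,
                         ecg_path = NULL, cta_phase = NULL,
                         truth_path = NULL, config = default_config()) {
  t0 <- proc.time()[["elapsed"]]
  tree <- read_tree_json(tree_path)
  mask <- read_mask_png(mask_path)
  geom <- read_geometry(geom_path)
  cl2d <- centerline2d(mask = mask, pixel_spacing = mean(geom$pixel_spacing))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  candidates <- NULL
  if (!is.null(ecg_path)) {
    truth <- if (!is.null(truth_path)) {
      jsonlite::read_json(truth_path, simplifyVector = TRUE)
    }
    frame_times <- if (!is.null(truth)) truth$frame_times else numeric()
    ecg <- read_ecg_csv(ecg_path, frame_times)
    if (is.null(cta_phase) && !is.null(truth)) cta_phase <- truth$cta_phase
    if (length(ecg$frame_times) > 0L && !is.null(cta_phase)) {
      candidates <- select_candidate_frames(ecg, cta_phase,
                                            tol = config$cardiac$tol)
      inform(sprintf("cardiac sync: %d candidate frame(s), best phase dist %.3g",
                     nrow(candidates), candidates$phase_dist[1]))
    }
  } else {
    inform("no ECG supplied; registering the given frame without phase matching")
  }

  tree <- resample_tree(tree, config$resample_step)
  tree <- label_segments(tree)
  tree <- classify_subbranches(tree,
    reference_counts = unlist(config$importance$reference_counts))
  tree <- assign_importance(tree,
                            alpha_max = config$importance$alpha_max,
                            alpha_min = config$importance$alpha_min,
                            decay = config$importance$decay_per_mm)
  res <- register_vessels(tree, cl2d, geom, config_to_registration(config))
  res$candidates <- candidates

  metrics <- NULL
  if (!is.null(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    gt_pose <- rigid_transform(t = truth$true_pose$t, r = truth$true_pose$r)
    metrics <- evaluate_registration(res, tree, mask, gt_pose,
                                     plane = config$evaluation$plane)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  }
  res$metrics <- metrics

  elapsed <- proc.time()[["elapsed"]] - t0
  jsonlite::write_json(
    list(pose = list(t = res$pose$t, r = res$pose$r),
         initial_pose = list(t = res$initial_pose$t, r = res$initial_pose$r),
         aadd_trace = as.list(setNames(res$trace$aadd, res$trace$stage)),
         n_eval = res$n_eval,
         candidates = if (!is.null(candidates)) candidates$frame,
         metrics = if (!is.null(metrics)) as.list(metrics)),
    file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA)
  inform(sprintf("pipeline finished in %.2f s (final AADD %.4g mm)",
                 elapsed, res$final_aadd))
  invisible(res)
}
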