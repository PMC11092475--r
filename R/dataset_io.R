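# Dataset-level commands: write a phantom to disk, and run the localizer
# and RSFC stages against an on-disk dataset. Layout is BIDS-like but not
# validated: anatomy + per-run NIfTI/TSV files plus a truth JSON.

#' Simulate a phantom dataset to disk
#'
#' Writes labeled anatomy (NIfTI + JSON label sidecar), task runs with
#' events and motion tables, rest runs with motion and eye-closure tables,
#' and a ground-truth JSON, then returns the provenance record.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param ... passed to [phantom_dataset].
#' @return the provenance list, invisibly.
#' @export
tl_simulate <- function(out_dir, seed = 1, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- phantom_dataset(seed = seed, ...)
  write_volume(ds$anatomy$labels, file.path(out_dir, "anatomy_labels.nii.gz"))
  write_volume(ds$anatomy$brain, file.path(out_dir, "brain_mask.nii.gz"))
  for (r in seq_along(ds$task$runs)) {
    tag <- sprintf("task_run-%d", r)
    write_volume(ds$task$runs[[r]], file.path(out_dir, paste0(tag, "_bold.nii.gz")))
    write_events_table(ds$task$schedules[[r]],
                       file.path(out_dir, paste0(tag, "_events.tsv")))
    write_tsv(ds$task$motion[[r]], file.path(out_dir, paste0(tag, "_motion.tsv")))
  }
  for (r in seq_along(ds$rest$runs)) {
    tag <- sprintf("rest_run-%d", r)
    write_volume(ds$rest$runs[[r]], file.path(out_dir, paste0(tag, "_bold.nii.gz")))
    write_tsv(ds$rest$motion[[r]], file.path(out_dir, paste0(tag, "_motion.tsv")))
    write_tsv(ds$rest$eye_logs[[r]], file.path(out_dir, paste0(tag, "_eyeclosure.tsv")))
  }
  truth <- list(task = ds$task$truth[c("auditory_amplitudes",
                                       "visual_amplitudes",
                                       "t1_decay_factors", "noise_sd")],
                rest = ds$rest$truth, seed = seed)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov <- list(command = "simulate", seed = seed,
               n_task_runs = length(ds$task$runs),
               n_rest_runs = length(ds$rest$runs),
               package_version = as.character(utils::packageVersion("thalamoloc")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance_simulate.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}

read_dataset_runs <- function(dir, prefix, tr = NULL) {
  bolds <- sort(list.files(dir, sprintf("^%s_run-[0-9]+_bold\\.nii(\\.gz)?$",
                                        prefix), full.names = TRUE))
  lapply(bolds, read_volume, tr = tr)
}

#' Run the localizer on an on-disk dataset
#'
#' @param data_dir dataset directory written by [tl_simulate] (or with the
#'   same layout).
#' @param out_dir output directory for fROI masks and the QC report.
#' @param config a [pipeline_config].
#' @param tr optional TR override when reading BOLD runs.
#' @return the [localize_froi] result, invisibly.
#' @export
tl_localize <- function(data_dir, out_dir, config = pipeline_config(),
                        tr = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- read_label_volume(file.path(data_dir, "anatomy_labels.nii.gz"))
  brain_img <- read_volume(file.path(data_dir, "brain_mask.nii.gz"))
  brain <- mask_volume(brain_img$data > 0.5, brain_img$affine)
  runs <- read_dataset_runs(data_dir, "task", tr)
  if (!length(runs)) stop("no task runs found in ", data_dir, call. = FALSE)
  params <- timing_params(runs[[1]]$tr)
  schedules <- lapply(seq_along(runs), function(r)
    read_events_table(file.path(data_dir, sprintf("task_run-%d_events.tsv", r)),
                      params))
  motion <- lapply(seq_along(runs), function(r)
    read_tsv(file.path(data_dir, sprintf("task_run-%d_motion.tsv", r))))
  res <- localize_froi(runs, schedules, motion, labels, labels, brain, config)
  for (nm in names(res$froi))
    write_volume(res$froi[[nm]], file.path(out_dir, paste0("froi_", nm, ".nii.gz")))
  report <- list(sizes = as.list(res$sizes), qc_flags = res$qc_flags,
                 tsr_sizes = res$provenance$tsr_sizes,
                 n_runs = res$provenance$n_runs)
  jsonlite::write_json(report, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Run resting-state validation on an on-disk dataset
#'
#' @param data_dir dataset directory containing rest runs and anatomy.
#' @param froi_dir directory with `froi_*.nii.gz` masks from [tl_localize].
#' @param out_dir output directory for the connectivity and Dice report.
#' @param config a [pipeline_config].
#' @param tr optional TR override when reading BOLD runs.
#' @return the [rsfc_participant] result plus Dice report, invisibly.
#' @export
tl_rsfc <- function(data_dir, froi_dir, out_dir, config = pipeline_config(),
                    tr = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- read_label_volume(file.path(data_dir, "anatomy_labels.nii.gz"))
  brain_img <- read_volume(file.path(data_dir, "brain_mask.nii.gz"))
  brain <- mask_volume(brain_img$data > 0.5, brain_img$affine)
  runs <- read_dataset_runs(data_dir, "rest", tr)
  if (!length(runs)) stop("no rest runs found in ", data_dir, call. = FALSE)
  motion <- lapply(seq_along(runs), function(r)
    read_tsv(file.path(data_dir, sprintf("rest_run-%d_motion.tsv", r))))
  eye_logs <- lapply(seq_along(runs), function(r) {
    p <- file.path(data_dir, sprintf("rest_run-%d_eyeclosure.tsv", r))
    if (file.exists(p)) read_tsv(p) else NULL
  })
  froi <- lapply(c(mgn_left = "mgn_left", mgn_right = "mgn_right",
                   lgn_left = "lgn_left", lgn_right = "lgn_right"),
                 function(nm) {
    img <- read_volume(file.path(froi_dir, paste0("froi_", nm, ".nii.gz")))
    mask_volume(img$data > 0.5, img$affine)
  })
  rois <- c(froi,
            list(ac_left = build_primary_ac_roi(labels, "ac_l"),
                 ac_right = build_primary_ac_roi(labels, "ac_r"),
                 vc_left = build_primary_vc_roi(labels, "vc_l"),
                 vc_right = build_primary_vc_roi(labels, "vc_r")))
  res <- rsfc_participant(runs, rois, labels, brain, motion, eye_logs,
                          config = config)
  # overlap benchmark between fROIs and the anatomical cortex ROIs
  bilat <- function(a, b) mask_volume(a$data | b$data, a$affine)
  dice_report <- list(
    mgn_vs_ac = dice(bilat(froi$mgn_left, froi$mgn_right),
                     bilat(rois$ac_left, rois$ac_right)),
    lgn_vs_vc = dice(bilat(froi$lgn_left, froi$lgn_right),
                     bilat(rois$vc_left, rois$vc_right)))
  out <- list(connectivity = as.list(res$connectivity),
              run_kept = res$run_kept,
              retained_seconds = res$retained_seconds,
              participant_kept = res$participant_kept,
              exclusions = res$exclusions, dice = dice_report)
  jsonlite::write_json(out, file.path(out_dir, "rsfc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(dice = dice_report)))
}
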