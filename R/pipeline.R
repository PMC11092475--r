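#' Pipeline configuration
#'
#' Bundles the tunable parameters of the localizer and RSFC stages with
#' their standard defaults: 4 mm FWHM smoothing for map-level computations
#' (ROI series always come from unsmoothed data), top/bottom 10% cortex
#' thresholds with a 10-voxel minimum cluster, adaptive thalamic threshold
#' numerators 32 (MGN) and 20 (LGN), 18-connectivity clustering, a minimum
#' of two task runs, and a left/right fROI asymmetry bound of 3.
#'
#' @param fwhm_mm Gaussian smoothing FWHM in mm (default 4).
#' @param cortex_fraction fraction of search-mask voxels kept when
#'   thresholding the cortex contrast (default 0.10).
#' @param min_cluster minimum cortex cluster size in voxels (default 10).
#' @param mgn_numerator,lgn_numerator adaptive-threshold numerators.
#' @param connectivity cluster contiguity: 6, 18 or 26 (default 18).
#' @param min_runs minimum number of task runs (default 2).
#' @param asymmetry_bound QC bound on left/right fROI size ratio
#'   (default 3).
#' @param censor a [censor_config].
#' @param band band-pass edges in Hz (default c(0.009, 0.08)).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fwhm_mm = 4, cortex_fraction = 0.10,
                            min_cluster = 10L, mgn_numerator = 32,
                            lgn_numerator = 20, connectivity = 18L,
                            min_runs = 2L, asymmetry_bound = 3,
                            censor = censor_config(),
                            band = c(0.009, 0.08)) {
  stopifnot(fwhm_mm >= 0, cortex_fraction > 0, cortex_fraction <= 1,
            min_cluster >= 1, mgn_numerator > 0, lgn_numerator > 0,
            connectivity %in% c(6L, 18L, 26L), min_runs >= 1,
            asymmetry_bound > 1, length(band) == 2, band[1] < band[2])
  structure(list(fwhm_mm = fwhm_mm, cortex_fraction = cortex_fraction,
                 min_cluster = as.integer(min_cluster),
                 mgn_numerator = mgn_numerator,
                 lgn_numerator = lgn_numerator,
                 connectivity = as.integer(connectivity),
                 min_runs = as.integer(min_runs),
                 asymmetry_bound = asymmetry_bound,
                 censor = censor, band = band),
            class = "pipeline_config")
}

# Mean series of an iteratively eroded tissue compartment.
compartment_series <- function(series_list, labels, name) {
  m <- erode_compartment_mask(label_mask(labels, name))
  lapply(series_list, function(s) mask_mean_series(s, m))
}

#' Localize MGN and LGN fROIs from task runs
#'
#' Runs the full localizer: smoothing, WM/CSF compartment extraction,
#' sparse-design GLM and Auditory - Visual contrast, cortex cluster
#' selection and series extraction, TSR construction with nuisance masks,
#' partial-correlation coactivation maps, adaptive thresholding,
#' cross-modal overlap removal, largest-cluster fROI extraction, and QC.
#'
#' @param task_runs list of [vol_series] task runs (unsmoothed).
#' @param schedules list of matching [build_run_schedule] results.
#' @param motion list of matching motion tables (volumes x 6).
#' @param thalamic_labels,parcellation [label_volume]s on the BOLD grid
#'   (may be the same object).
#' @param brain a [mask_volume] of in-brain voxels.
#' @param config a [pipeline_config].
#' @return a `froi_result`: fROI and TSR masks, sizes, QC flags, the
#'   contrast map, and provenance.
#' @export
localize_froi <- function(task_runs, schedules, motion,
                          thalamic_labels, parcellation = thalamic_labels,
                          brain, config = pipeline_config()) {
  n_runs <- length(task_runs)
  if (n_runs < config$min_runs)
    stop("need at least ", config$min_runs, " task runs, got ", n_runs,
         call. = FALSE)
  stopifnot(length(schedules) == n_runs, length(motion) == n_runs)

  smoothed <- lapply(task_runs, smooth_gaussian, fwhm_mm = config$fwhm_mm)
  wm_series <- compartment_series(task_runs, parcellation, "wm")
  csf_series <- compartment_series(task_runs, parcellation, "csf")

  design <- build_design_matrix(schedules, motion, wm_series, csf_series)
  betas <- fit_glm(smoothed, design, brain)
  contrast <- contrast_auditory_minus_visual(betas)

  cortex <- build_cortex_search_masks(parcellation)
  ac_l <- select_cortex_cluster(contrast, cortex$ac_left, "upper",
                                config$cortex_fraction, config$min_cluster,
                                config$connectivity)
  ac_r <- select_cortex_cluster(contrast, cortex$ac_right, "upper",
                                config$cortex_fraction, config$min_cluster,
                                config$connectivity)
  vc_l <- select_cortex_cluster(contrast, cortex$vc_left, "lower",
                                config$cortex_fraction, config$min_cluster,
                                config$connectivity)
  vc_r <- select_cortex_cluster(contrast, cortex$vc_right, "lower",
                                config$cortex_fraction, config$min_cluster,
                                config$connectivity)
  smooth_cat <- smoothed
  ac_series <- unlist(lapply(smooth_cat, extract_cortex_series, ac_l, ac_r))
  vc_series <- unlist(lapply(smooth_cat, extract_cortex_series, vc_l, vc_r))

  tsrs <- list(
    mgn_left = build_tsr(thalamic_labels, parcellation, "mgn", "l"),
    mgn_right = build_tsr(thalamic_labels, parcellation, "mgn", "r"),
    lgn_left = build_tsr(thalamic_labels, parcellation, "lgn", "l"),
    lgn_right = build_tsr(thalamic_labels, parcellation, "lgn", "r"))

  wm_mask <- label_mask(parcellation, "wm")
  gm_mask <- build_global_gm_mask(parcellation)
  gm_series <- unlist(lapply(task_runs, mask_mean_series, gm_mask))

  k <- ncol(schedules[[1]]$acquisition_times)
  vic <- unlist(lapply(schedules, function(s)
    rep(seq_len(k), times = nrow(s$trials))))
  run_id <- rep(seq_len(n_runs),
                vapply(schedules, n_volumes_scheduled, integer(1)))
  base_nuis <- cbind(wm = unlist(wm_series), csf = unlist(csf_series),
                     gm = gm_series,
                     vol2 = as.numeric(vic == 2L),
                     vol3 = as.numeric(vic == 3L),
                     stats::model.matrix(~ 0 + factor(run_id)))

  mgn_sizes <- c(sum(tsrs$mgn_left$mask$data), sum(tsrs$mgn_right$mask$data))
  lgn_sizes <- c(sum(tsrs$lgn_left$mask$data), sum(tsrs$lgn_right$mask$data))

  froi <- list(); thresholded <- list()
  for (nm in names(tsrs)) {
    tsr <- tsrs[[nm]]
    local_wm <- build_local_wm_mask(tsr, wm_mask)
    lw_series <- unlist(lapply(task_runs, mask_mean_series, local_wm))
    nuis <- cbind(base_nuis, local_wm = lw_series)
    map_ac <- coactivation_map(smooth_cat, tsr, ac_series, nuis)
    map_vc <- coactivation_map(smooth_cat, tsr, vc_series, nuis)
    sizes <- if (tsr$nucleus == "mgn") mgn_sizes else lgn_sizes
    numerator <- if (tsr$nucleus == "mgn") config$mgn_numerator
                 else config$lgn_numerator
    thr <- remove_cross_modal_overlap(
      adaptive_threshold(map_ac, sizes, numerator),
      adaptive_threshold(map_vc, sizes, numerator))
    thresholded[[nm]] <- thr
    chosen <- if (tsr$nucleus == "mgn") thr$ac else thr$vc
    froi[[nm]] <- extract_froi(chosen, config$connectivity)
  }

  masks <- list(mgn_left = froi$mgn_left$mask, mgn_right = froi$mgn_right$mask,
                lgn_left = froi$lgn_left$mask, lgn_right = froi$lgn_right$mask)
  flags <- qc_flags(masks$mgn_left, masks$mgn_right,
                    masks$lgn_left, masks$lgn_right,
                    config$asymmetry_bound)
  structure(list(
    froi = masks,
    sizes = vapply(masks, function(m) sum(m$data), numeric(1)),
    qc_flags = flags,
    tsrs = tsrs,
    thresholded = thresholded,
    contrast = contrast,
    cortex_clusters = list(ac_left = ac_l, ac_right = ac_r,
                           vc_left = vc_l, vc_right = vc_r),
    provenance = list(n_runs = n_runs, config = config,
                      tsr_sizes = list(mgn = mgn_sizes, lgn = lgn_sizes))),
    class = "froi_result")
}

#' @export
print.froi_result <- function(x, ...) {
  cat("<froi_result> sizes:",
      paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), "\n")
  if (length(x$qc_flags)) cat("  QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  else cat("  QC: clean\n")
  invisible(x)
}

#' Resting-state connectivity for one participant
#'
#' Per run: extracts unsmoothed ROI and compartment series, applies
#' mode-1000 normalization, linear detrend, eye-closure censoring combined
#' with any precomputed censor mask, retention pruning, band-pass filtering
#' with interpolation and edge discard, then computes the four ROI-pair
#' partial-correlation estimates (MGN-AC, MGN-VC, LGN-AC, LGN-VC) with the
#' 28-column nuisance set; run-level estimates are averaged over kept runs.
#'
#' @param rest_runs list of [vol_series] (unsmoothed).
#' @param rois named list of [mask_volume]s: `mgn_left`, `mgn_right`,
#'   `lgn_left`, `lgn_right`, `ac_left`, `ac_right`, `vc_left`, `vc_right`.
#' @param parcellation a [label_volume] providing `wm` and `csf` labels.
#' @param brain in-brain [mask_volume].
#' @param motion list of per-run motion tables.
#' @param eye_logs list of per-run eye-closure data.frames (onset/offset
#'   seconds), or NULL for none.
#' @param censor_masks optional list of per-run precomputed keep vectors
#'   (e.g. from LPF-FD/GEV-DV thresholding), combined by AND with the
#'   eye-closure mask.
#' @param config a [pipeline_config].
#' @return list with `connectivity` (named participant-level estimates),
#'   `runs` (per-run detail), `run_kept`, `participant_kept`, and
#'   `exclusions` (text reasons, empty if retained).
#' @export
rsfc_participant <- function(rest_runs, rois, parcellation, brain,
                             motion, eye_logs = NULL, censor_masks = NULL,
                             config = pipeline_config()) {
  n_runs <- length(rest_runs)
  stopifnot(length(motion) == n_runs)
  cfg <- config$censor
  wm_cm <- erode_compartment_mask(label_mask(parcellation, "wm"))
  csf_cm <- erode_compartment_mask(label_mask(parcellation, "csf"))
  roi_names <- c("mgn_left", "mgn_right", "lgn_left", "lgn_right",
                 "ac_left", "ac_right", "vc_left", "vc_right")
  stopifnot(all(roi_names %in% names(rois)))

  keeps <- vector("list", n_runs)
  run_series <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    s <- rest_runs[[r]]
    n_vol <- dim(s$data)[4]
    scale_f <- 1000 / estimate_brain_mode(s, brain)
    S <- vapply(roi_names, function(nm) mask_mean_series(s, rois[[nm]]),
                numeric(n_vol))
    S <- cbind(S, wm = mask_mean_series(s, wm_cm),
               csf = mask_mean_series(s, csf_cm))
    S <- detrend_center(S * scale_f)
    run_series[[r]] <- S
    keep <- if (!is.null(eye_logs) && !is.null(eye_logs[[r]]))
      eye_closure_censor(eye_logs[[r]], s$tr, n_vol, cfg)
    else rep(TRUE, n_vol)
    if (!is.null(censor_masks) && !is.null(censor_masks[[r]]))
      keep <- keep & censor_masks[[r]]
    keeps[[r]] <- keep
  }
  tr <- rest_runs[[1]]$tr
  retention <- apply_retention_rules(keeps, tr, cfg)

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    if (!retention$run_kept[r]) next
    bp <- bandpass_with_interpolation(run_series[[r]], retention$masks[[r]],
                                      tr, config$band)
    nuis <- build_rsfc_nuisance(motion[[r]],
                                run_series[[r]][, "wm"],
                                run_series[[r]][, "csf"], tr, config$band)
    nuis <- nuis[bp$retained_index, , drop = FALSE]
    D <- bp$data
    colnames(D) <- colnames(run_series[[r]])
    pair <- function(seed, target)
      roi_pair_connectivity(D[, paste0(seed, "_left")],
                            D[, paste0(seed, "_right")],
                            D[, paste0(target, "_left")],
                            D[, paste0(target, "_right")], nuis)$estimate
    runs[[r]] <- c(mgn_ac = pair("mgn", "ac"), mgn_vc = pair("mgn", "vc"),
                   lgn_ac = pair("lgn", "ac"), lgn_vc = pair("lgn", "vc"))
  }
  kept <- which(retention$run_kept)
  exclusions <- character(0)
  if (sum(retention$run_kept) < cfg$min_runs)
    exclusions <- c(exclusions, sprintf(
      "fewer than %d runs retained (%d)", cfg$min_runs,
      sum(retention$run_kept)))
  total <- sum(retention$retained_seconds[retention$run_kept])
  if (total < cfg$min_total)
    exclusions <- c(exclusions, sprintf(
      "less than %gs retained in total (%.1fs)", cfg$min_total, total))
  connectivity <- if (retention$participant_kept)
    colMeans(do.call(rbind, runs[kept])) else NULL
  list(connectivity = connectivity, runs = runs,
       run_kept = retention$run_kept,
       retained_seconds = retention$retained_seconds,
       participant_kept = retention$participant_kept,
       exclusions = exclusions)
}

#' Connectivity table for a simulated cohort
#'
#' Computes the participant-level MGN-AC, MGN-VC, LGN-AC and LGN-VC
#' estimates for a [simulate_rest_cohort] result, using the full RSFC
#' nuisance set after band-pass filtering and edge discard.
#'
#' @param cohort a [simulate_rest_cohort] result.
#' @param tr repetition time in seconds.
#' @param config a [pipeline_config].
#' @param edge_seconds per-end discard duration in seconds; the cohort
#'   generator's short runs use a reduced default of 0 (its series are
#'   generated in-band, with no run-edge discontinuity to trim).
#' @return data.frame with columns mgn_ac, mgn_vc, lgn_ac, lgn_vc.
#' @export
cohort_connectivity_table <- function(cohort, tr = 0.85,
                                      config = pipeline_config(),
                                      edge_seconds = 0) {
  rows <- lapply(cohort, function(p) {
    S <- as.matrix(p$roi)
    bp <- bandpass_with_interpolation(cbind(S, wm = p$wm, csf = p$csf),
                                      NULL, tr, config$band, edge_seconds)
    nuis <- build_rsfc_nuisance(p$motion, p$wm, p$csf, tr, config$band)
    nuis <- nuis[bp$retained_index, , drop = FALSE]
    D <- bp$data
    colnames(D) <- c(colnames(p$roi), "wm", "csf")
    pair <- function(seed, target)
      roi_pair_connectivity(D[, paste0(seed, "_l")], D[, paste0(seed, "_r")],
                            D[, paste0(target, "_l")],
                            D[, paste0(target, "_r")], nuis)$estimate
    c(mgn_ac = pair("mgn", "ac"), mgn_vc = pair("mgn", "vc"),
      lgn_ac = pair("lgn", "ac"), lgn_vc = pair("lgn", "vc"))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Generate a complete phantom dataset in memory
#'
#' Anatomy plus task runs (with schedules and motion) and rest runs (with
#' motion and eye logs), with ground truth.
#'
#' @param seed integer master seed.
#' @param shape phantom grid (default c(48, 48, 48)).
#' @param n_task_runs,n_rest_runs run counts (default 4 each).
#' @param tr repetition time in seconds (default 0.85).
#' @param rest_volumes volumes per rest run (default 400).
#' @param task_spec a [task_effect_spec].
#' @param rest_spec a [rest_connectivity_spec].
#' @return nested list with `anatomy`, `task` (runs, schedules, motion,
#'   truth), and `rest` (runs, motion, eye_logs, truth).
#' @export
phantom_dataset <- function(seed = 1, shape = c(48, 48, 48),
                            n_task_runs = 4L, n_rest_runs = 4L, tr = 0.85,
                            rest_volumes = 400L,
                            task_spec = task_effect_spec(),
                            rest_spec = rest_connectivity_spec()) {
  anatomy <- make_phantom_anatomy(shape, seed = seed)
  params <- timing_params(tr)
  task <- list(runs = list(), schedules = list(), motion = list())
  for (r in seq_len(n_task_runs)) {
    sch <- build_run_schedule(params, seed = seed * 100 + r)
    sim <- simulate_task_run(anatomy, sch, task_spec, seed = seed * 100 + r)
    me <- simulate_motion_and_eyes(n_volumes_scheduled(sch), tr,
                                   seed = seed * 100 + r)
    task$runs[[r]] <- sim$series
    task$schedules[[r]] <- sch
    task$motion[[r]] <- me$motion
    task$truth <- sim$truth
  }
  rest <- list(runs = list(), motion = list(), eye_logs = list())
  for (r in seq_len(n_rest_runs)) {
    sim <- simulate_rest_run(anatomy, rest_spec, tr, rest_volumes,
                             seed = seed * 200 + r)
    me <- simulate_motion_and_eyes(rest_volumes, tr, seed = seed * 200 + r)
    rest$runs[[r]] <- sim$series
    rest$motion[[r]] <- me$motion
    rest$eye_logs[[r]] <- me$eye_closures
    rest$truth <- sim$truth[c("r_mgn_ac", "r_lgn_vc", "r_cross")]
  }
  list(anatomy = anatomy, task = task, rest = rest, seed = seed)
}

#' ROI set for RSFC validation
#'
#' Combines localizer fROIs with the primary anatomical AC/VC ROIs into
#' the named list [rsfc_participant] expects.
#'
#' @param froi_result a [localize_froi] result.
#' @param parcellation a [label_volume] with `ac_l`/`ac_r` (transverse
#'   temporal surrogate) and `vc_l`/`vc_r` (pericalcarine surrogate)
#'   labels.
#' @return named list of eight [mask_volume]s.
#' @export
froi_roi_set <- function(froi_result, parcellation) {
  c(froi_result$froi,
    list(ac_left = build_primary_ac_roi(parcellation, "ac_l"),
         ac_right = build_primary_ac_roi(parcellation, "ac_r"),
         vc_left = build_primary_vc_roi(parcellation, "vc_l"),
         vc_right = build_primary_vc_roi(parcellation, "vc_r")))
}
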