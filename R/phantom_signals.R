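#' Task and rest signal specifications for the phantom
#'
#' `task_effect_spec` describes condition-specific plateau responses sampled
#' at acquisition, a per-cluster T1-relaxation decay (the first volume of
#' each cluster is at factor 1, later volumes lower because the sparse
#' scheme never reaches steady state), additive Gaussian noise, and
#' per-tissue baselines on a mode-1000-like scale. `rest_connectivity_spec`
#' describes planted latent connectivity between MGN and auditory cortex
#' and between LGN and visual cortex, plus nuisance (WM, CSF, global)
#' amplitudes.
#'
#' Defaults emulate typical 3 T task fMRI: ~2% signal change in thalamic
#' nuclei and ~3% in sensory cortex over a ~1000 baseline, with 1% noise.
#'
#' @param auditory_amplitudes,visual_amplitudes named numeric vectors of
#'   response amplitudes (signal units) per structure label.
#' @param t1_decay_factors multiplicative baseline factors for the volumes
#'   of each acquisition cluster; the first must be 1.
#' @param noise_sd additive white-noise standard deviation.
#' @param baseline baseline signal for unlisted in-brain structures.
#' @param tissue_baselines named overrides of `baseline` per label.
#' @return a `task_effect_spec` list.
#' @export
task_effect_spec <- function(auditory_amplitudes = c(mgn_l = 20, mgn_r = 20,
                                                     ac_l = 30, ac_r = 30),
                             visual_amplitudes = c(lgn_l = 20, lgn_r = 20,
                                                   vc_l = 30, vc_r = 30),
                             t1_decay_factors = c(1, 0.97, 0.95),
                             noise_sd = 10,
                             baseline = 1000,
                             tissue_baselines = c(wm = 850, csf = 1100)) {
  if (abs(t1_decay_factors[1] - 1) > 1e-12)
    stop("the first t1 decay factor must be exactly 1", call. = FALSE)
  structure(list(auditory_amplitudes = auditory_amplitudes,
                 visual_amplitudes = visual_amplitudes,
                 t1_decay_factors = t1_decay_factors,
                 noise_sd = noise_sd, baseline = baseline,
                 tissue_baselines = tissue_baselines),
            class = "task_effect_spec")
}

#' @rdname task_effect_spec
#' @param r_mgn_ac,r_lgn_vc target Pearson correlations of the planted
#'   MGN-AC and LGN-VC latent signals (|r| < 1).
#' @param r_cross target cross-modal correlation (e.g. MGN-VC).
#' @param signal_amplitude amplitude of the planted ROI signals.
#' @param wm_amplitude,csf_amplitude,global_amplitude nuisance signal
#'   amplitudes.
#' @export
rest_connectivity_spec <- function(r_mgn_ac = 0.5, r_lgn_vc = 0.5,
                                   r_cross = 0,
                                   signal_amplitude = 10,
                                   wm_amplitude = 5, csf_amplitude = 5,
                                   global_amplitude = 1.5,
                                   noise_sd = 5,
                                   baseline = 1000,
                                   tissue_baselines = c(wm = 850,
                                                        csf = 1100)) {
  rs <- c(r_mgn_ac, r_lgn_vc, r_cross)
  if (any(abs(rs) >= 1))
    stop("planted correlations must satisfy |r| < 1", call. = FALSE)
  if (abs(r_cross) > 1e-12 && sqrt(abs(r_mgn_ac * r_lgn_vc)) < abs(r_cross))
    stop("r_cross is unattainable given r_mgn_ac and r_lgn_vc",
         call. = FALSE)
  structure(list(r_mgn_ac = r_mgn_ac, r_lgn_vc = r_lgn_vc,
                 r_cross = r_cross, signal_amplitude = signal_amplitude,
                 wm_amplitude = wm_amplitude, csf_amplitude = csf_amplitude,
                 global_amplitude = global_amplitude, noise_sd = noise_sd,
                 baseline = baseline, tissue_baselines = tissue_baselines),
            class = "rest_connectivity_spec")
}

baseline_map <- function(anatomy, spec) {
  lab <- anatomy$labels
  base <- array(0, dim(lab$data))
  base[anatomy$brain$data] <- spec$baseline
  for (nm in names(spec$tissue_baselines)) {
    if (nm %in% lab$label_table$name)
      base[label_mask(lab, nm)$data] <- spec$tissue_baselines[[nm]]
  }
  base
}

amplitude_map <- function(anatomy, amplitudes) {
  amp <- array(0, dim(anatomy$labels$data))
  for (nm in names(amplitudes)) {
    if (nm %in% anatomy$labels$label_table$name)
      amp[label_mask(anatomy$labels, nm)$data] <- amplitudes[[nm]]
  }
  amp
}

#' Simulate a clustered-sparse task run
#'
#' Each acquired volume is `baseline * t1_decay(volume-in-cluster) +
#' condition amplitude + Gaussian noise`; structures respond only to their
#' planted modality, and the hemodynamic response is modelled as a plateau
#' sampled at acquisition (no HRF convolution), matching the sparse design
#' where clusters are timed to the response peak.
#'
#' @param anatomy a [make_phantom_anatomy] result.
#' @param schedule a [build_run_schedule] result.
#' @param spec a [task_effect_spec].
#' @param seed integer seed.
#' @return list with `series` ([vol_series]) and `truth` (the planted
#'   amplitudes, decay factors and noise level).
#' @export
simulate_task_run <- function(anatomy, schedule, spec = task_effect_spec(),
                              seed = 1) {
  stopifnot(inherits(anatomy, "phantom_anatomy"),
            inherits(schedule, "trial_schedule"),
            inherits(spec, "task_effect_spec"))
  k <- ncol(schedule$acquisition_times)
  if (length(spec$t1_decay_factors) != k)
    stop("t1_decay_factors length must equal volumes per cluster",
         call. = FALSE)
  shape <- anatomy$shape
  nvox <- prod(shape)
  cond <- rep(schedule$trials$condition, each = k)
  vol_in_cluster <- rep(seq_len(k), times = nrow(schedule$trials))
  t_total <- length(cond)

  base <- as.vector(baseline_map(anatomy, spec))
  amp_a <- as.vector(amplitude_map(anatomy, spec$auditory_amplitudes))
  amp_v <- as.vector(amplitude_map(anatomy, spec$visual_amplitudes))
  brain <- as.vector(anatomy$brain$data)

  rng <- rng_stream(seed, "task")
  m <- rand_norm(rng, nvox * t_total, sd = spec$noise_sd)
  dim(m) <- c(nvox, t_total)
  for (t in seq_len(t_total)) {
    v <- base * spec$t1_decay_factors[vol_in_cluster[t]]
    if (cond[t] == "auditory") v <- v + amp_a
    if (cond[t] == "visual") v <- v + amp_v
    m[, t] <- m[, t] * brain + v
  }
  dim(m) <- c(shape, t_total)
  list(series = vol_series(m, anatomy$labels$affine,
                           tr = schedule$params$tr_seconds),
       truth = list(auditory_amplitudes = spec$auditory_amplitudes,
                    visual_amplitudes = spec$visual_amplitudes,
                    t1_decay_factors = spec$t1_decay_factors,
                    noise_sd = spec$noise_sd, seed = seed))
}

# Band-limited unit-variance noise: white noise pushed through the standard
# 0.009-0.08 Hz zero-phase band-pass, then standardized.
bandlimited_noise <- function(rng, n, tr, band = c(0.009, 0.08)) {
  x <- rand_norm(rng, n)
  y <- butter_bandpass(x, tr, low = band[1], high = band[2])
  as.numeric(scale(y))
}

#' Simulate a resting-state run with planted connectivity
#'
#' Plants band-limited latent signals shared between MGN and AC and between
#' LGN and VC, scaled so ROI pairs reach the target Pearson correlations;
#' adds band-limited WM, CSF and global nuisance signals and white voxel
#' noise on top of tissue baselines.
#'
#' @param anatomy a [make_phantom_anatomy] result.
#' @param spec a [rest_connectivity_spec].
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes (>= 2).
#' @param seed integer seed.
#' @return list with `series` ([vol_series]) and `truth` (planted r values
#'   and the latent ROI/nuisance time courses).
#' @export
simulate_rest_run <- function(anatomy, spec = rest_connectivity_spec(),
                              tr = 0.85, n_volumes = 400, seed = 1) {
  stopifnot(inherits(anatomy, "phantom_anatomy"),
            inherits(spec, "rest_connectivity_spec"), n_volumes >= 2)
  shape <- anatomy$shape
  nvox <- prod(shape)
  rng <- rng_stream(seed, "rest")
  sig <- rest_latent_signals(rng, spec, tr, n_volumes)

  base <- as.vector(baseline_map(anatomy, spec))
  brain_idx <- which(as.vector(anatomy$brain$data))
  struct_idx <- function(nm) which(as.vector(label_mask(anatomy$labels, nm)$data))

  m <- rand_norm(rng, nvox * n_volumes, sd = spec$noise_sd)
  dim(m) <- c(nvox, n_volumes)
  chunk <- 500L
  for (t0 in seq(1L, n_volumes, by = chunk)) {
    tt <- t0:min(t0 + chunk - 1L, n_volumes)
    blk <- m[, tt, drop = FALSE]
    blk <- blk + base  # recycled down columns
    blk[brain_idx, ] <- blk[brain_idx, ] +
      rep(spec$global_amplitude * sig$global[tt], each = length(brain_idx))
    m[, tt] <- blk
  }
  add_sig <- function(nms, x, amp) {
    for (nm in nms) {
      idx <- struct_idx(nm)
      m[idx, ] <<- m[idx, ] + rep(amp * x, each = length(idx))
    }
  }
  add_sig(c("mgn_l", "mgn_r"), sig$mgn, spec$signal_amplitude)
  add_sig(c("ac_l", "ac_r"), sig$ac, spec$signal_amplitude)
  add_sig(c("lgn_l", "lgn_r"), sig$lgn, spec$signal_amplitude)
  add_sig(c("vc_l", "vc_r"), sig$vc, spec$signal_amplitude)
  add_sig("wm", sig$wm, spec$wm_amplitude)
  add_sig("csf", sig$csf, spec$csf_amplitude)
  dim(m) <- c(shape, n_volumes)
  list(series = vol_series(m, anatomy$labels$affine, tr = tr),
       truth = list(r_mgn_ac = spec$r_mgn_ac, r_lgn_vc = spec$r_lgn_vc,
                    r_cross = spec$r_cross, signals = sig, seed = seed))
}

# Latent ROI and nuisance signals with the planted correlation structure:
# x_roi = sqrt(r) u + sqrt(1-r) e, with corr(u1, u2) set so cross-modal
# pairs land at r_cross. The Cholesky-style mixing operates on the
# *realized* series: each idiosyncratic component is orthogonalized
# in-sample against the shared latent before mixing, so the sample
# correlation of every planted pair equals its target exactly (band-limited
# series carry few effective degrees of freedom, so mixing raw draws would
# scatter the realized correlation noticeably around the target).
rest_latent_signals <- function(rng, spec, tr, n) {
  std <- function(x) as.numeric(scale(x))
  basis <- NULL
  draw_orth <- function() {
    x <- bandlimited_noise(rng, n, tr)
    if (!is.null(basis)) x <- residualize(x, basis)[, 1]
    x <- std(x)
    basis <<- cbind(basis, x)
    x
  }
  u1 <- draw_orth()
  w <- draw_orth()
  r1 <- spec$r_mgn_ac; r2 <- spec$r_lgn_vc
  cc <- if (abs(spec$r_cross) < 1e-12 || r1 * r2 <= 0) 0 else
    spec$r_cross / sqrt(r1 * r2)
  u2 <- cc * u1 + sqrt(max(0, 1 - cc^2)) * w
  mix <- function(u, r) {
    e <- draw_orth()
    sqrt(abs(r)) * sign(r) * u + sqrt(1 - abs(r)) * e
  }
  list(mgn = mix(u1, r1), ac = mix(u1, r1),
       lgn = mix(u2, r2), vc = mix(u2, r2),
       wm = bandlimited_noise(rng, n, tr),
       csf = bandlimited_noise(rng, n, tr),
       global = bandlimited_noise(rng, n, tr))
}

#' Simulate motion parameters and eye-closure events
#'
#' Motion traces are smoothed random walks (3 translations in mm, 3
#' rotations in radians). Eye closures are either taken verbatim from
#' `closures` or drawn at random.
#'
#' @param n_volumes number of volumes.
#' @param tr repetition time in seconds.
#' @param seed integer seed.
#' @param translation_step_mm,rotation_step_rad random-walk step SDs; set
#'   both to 0 for motion-free traces.
#' @param closures optional data.frame with columns `onset`, `offset`
#'   (seconds) used verbatim; NULL draws `n_closures` random closures.
#' @param n_closures number of random closures when `closures` is NULL.
#' @return list with `motion` (data.frame, 6 columns) and `eye_closures`
#'   (data.frame onset/offset).
#' @export
simulate_motion_and_eyes <- function(n_volumes, tr = 0.85, seed = 1,
                                     translation_step_mm = 0.02,
                                     rotation_step_rad = 2e-4,
                                     closures = NULL, n_closures = 2L) {
  rng <- rng_stream(seed, "motion")
  walk <- function(step) {
    if (step == 0) return(rep(0, n_volumes))
    x <- cumsum(rand_norm(rng, n_volumes, sd = step))
    stats::filter(c(x[1], x[1], x, x[n_volumes], x[n_volumes]),
                  rep(1 / 5, 5), sides = 2)[3:(n_volumes + 2)]
  }
  motion <- data.frame(trans_x = walk(translation_step_mm),
                       trans_y = walk(translation_step_mm),
                       trans_z = walk(translation_step_mm),
                       rot_x = walk(rotation_step_rad),
                       rot_y = walk(rotation_step_rad),
                       rot_z = walk(rotation_step_rad))
  if (is.null(closures)) {
    run_len <- n_volumes * tr
    if (n_closures > 0 && run_len > 20) {
      onset <- sort(rand_unif(rng, n_closures)) * (run_len - 10)
      dur <- 1 + 5 * rand_unif(rng, n_closures)
      closures <- data.frame(onset = onset,
                             offset = pmin(onset + dur, run_len))
    } else {
      closures <- data.frame(onset = numeric(0), offset = numeric(0))
    }
  } else {
    closures <- as.data.frame(closures)
    stopifnot(all(c("onset", "offset") %in% names(closures)))
  }
  list(motion = motion, eye_closures = closures)
}

#' Simulate a cohort of resting-state ROI time series
#'
#' Cohort-scale counterpart of [simulate_rest_run]: draws, for each
#' participant, the eight ROI mean series (left/right MGN, LGN, AC, VC)
#' plus WM/CSF nuisance series and motion traces directly from the same
#' latent-signal model, without materializing 4D volumes. Used for
#' statistical-calibration studies where hundreds of cohorts are needed.
#'
#' @param n_participants participants per cohort.
#' @param n_volumes volumes per run.
#' @param tr repetition time in seconds.
#' @param spec a [rest_connectivity_spec].
#' @param seed integer seed.
#' @param roi_noise_sd SD of per-hemisphere ROI measurement noise relative
#'   to the unit-variance latent signals (residual voxel noise surviving
#'   ROI averaging).
#' @return list of participants, each with `roi` (data.frame of 8 series),
#'   `wm`, `csf`, and `motion`.
#' @export
simulate_rest_cohort <- function(n_participants, n_volumes = 400, tr = 0.85,
                                 spec = rest_connectivity_spec(), seed = 1,
                                 roi_noise_sd = 0.1) {
  lapply(seq_len(n_participants), function(p) {
    rng <- rng_stream(seed * 1000 + p, "cohort")
    sig <- rest_latent_signals(rng, spec, tr, n_volumes)
    hemi <- function(x) x + rand_norm(rng, n_volumes, sd = roi_noise_sd)
    roi <- data.frame(mgn_l = hemi(sig$mgn), mgn_r = hemi(sig$mgn),
                      lgn_l = hemi(sig$lgn), lgn_r = hemi(sig$lgn),
                      ac_l = hemi(sig$ac), ac_r = hemi(sig$ac),
                      vc_l = hemi(sig$vc), vc_r = hemi(sig$vc))
    motion <- simulate_motion_and_eyes(n_volumes, tr,
                                       seed = seed * 1000 + p)$motion
    list(roi = roi, wm = sig$wm, csf = sig$csf, motion = motion)
  })
}
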