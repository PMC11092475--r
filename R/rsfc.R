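#' Censoring and retention configuration
#'
#' Bundles the resting-state censoring parameters. The LPF-FD threshold and
#' GEV-DV parameter are consumed as precomputed study-level values (their
#' optimization is an external procedure); the remaining fields drive the
#' eye-closure and retention rules implemented here.
#'
#' @param lpf_fd_threshold low-pass-filtered framewise-displacement
#'   censoring threshold in mm (study value 0.07587).
#' @param gev_dv_parameter GEV-DV censoring parameter, arbitrary units
#'   (study value 3.105).
#' @param eye_closure_min minimum eye-closure duration that triggers
#'   censoring, seconds (default 3).
#' @param eye_gap_merge maximum gap between qualifying closures that is
#'   itself censored, seconds (default 30).
#' @param min_segment minimum duration of a contiguous kept segment,
#'   seconds (default 8).
#' @param min_run_retained minimum retained data per run, seconds
#'   (default 90).
#' @param min_runs minimum kept runs per participant (default 2).
#' @param min_total minimum total retained data per participant, seconds
#'   (default 300).
#' @return a `censor_config` list.
#' @export
censor_config <- function(lpf_fd_threshold = 0.07587,
                          gev_dv_parameter = 3.105,
                          eye_closure_min = 3, eye_gap_merge = 30,
                          min_segment = 8, min_run_retained = 90,
                          min_runs = 2L, min_total = 300) {
  vals <- c(lpf_fd_threshold, gev_dv_parameter, eye_closure_min,
            eye_gap_merge, min_segment, min_run_retained, min_runs,
            min_total)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all censoring parameters must be positive", call. = FALSE)
  structure(list(lpf_fd_threshold = lpf_fd_threshold,
                 gev_dv_parameter = gev_dv_parameter,
                 eye_closure_min = eye_closure_min,
                 eye_gap_merge = eye_gap_merge,
                 min_segment = min_segment,
                 min_run_retained = min_run_retained,
                 min_runs = as.integer(min_runs), min_total = min_total),
            class = "censor_config")
}

#' Mode-1000 normalization
#'
#' Divides the series by the modal in-brain value and multiplies by 1000.
#' The mode is estimated as the centre of the fullest bin of a 100-bin
#' histogram over all in-brain values (all voxels, all volumes).
#'
#' @param series a [vol_series].
#' @param brain a [mask_volume] of in-brain voxels.
#' @return the normalized [vol_series].
#' @export
mode1000_normalize <- function(series, brain) {
  mode_val <- estimate_brain_mode(series, brain)
  vol_series(series$data * (1000 / mode_val), series$affine, series$tr)
}

#' @rdname mode1000_normalize
#' @export
estimate_brain_mode <- function(series, brain) {
  stopifnot_same_grid(series, brain)
  d <- dim(series$data)
  nvox <- prod(d[1:3])
  idx <- which(as.vector(brain$data))
  chunk <- max(1L, floor(2e7 / length(idx)))
  chunks <- split(seq_len(d[4]), ceiling(seq_len(d[4]) / chunk))
  block_at <- function(tt) series$data[rep(idx, length(tt)) +
                                         rep((tt - 1) * nvox,
                                             each = length(idx))]
  rng <- range(vapply(chunks, function(tt) range(block_at(tt)), numeric(2)))
  if (!all(is.finite(rng)))
    stop("non-finite in-brain values", call. = FALSE)
  if (rng[1] == rng[2]) {
    if (rng[1] <= 0)
      stop("modal in-brain value is not positive; cannot normalize",
           call. = FALSE)
    return(rng[1])
  }
  breaks <- seq(rng[1], rng[2], length.out = 101)
  counts <- numeric(100)
  for (tt in chunks) {
    b <- findInterval(block_at(tt), breaks, all.inside = TRUE)
    counts <- counts + tabulate(b, nbins = 100)
  }
  k <- which.max(counts)
  mode_val <- (breaks[k] + breaks[k + 1]) / 2
  if (mode_val <= 0)
    stop("modal in-brain value is not positive; cannot normalize",
         call. = FALSE)
  mode_val
}

#' Linear detrend and mean-centre
#'
#' Removes, per voxel (or per column), the least-squares linear trend; the
#' result has mean 0.
#'
#' @param x a [vol_series], numeric vector, or matrix (time in rows).
#' @return same shape as the input.
#' @export
detrend_center <- function(x) {
  detrend_mat <- function(m) {
    n <- nrow(m)
    tt <- seq_len(n)
    X <- cbind(1, tt - mean(tt))
    m - X %*% qr.coef(qr(X), m)
  }
  if (inherits(x, "vol_series")) {
    d <- dim(x$data)
    m <- x$data
    dim(m) <- c(prod(d[1:3]), d[4])
    m <- t(detrend_mat(t(m)))
    dim(m) <- d
    vol_series(m, x$affine, x$tr)
  } else if (is.matrix(x)) {
    detrend_mat(x)
  } else {
    as.numeric(detrend_mat(matrix(x, ncol = 1)))
  }
}

#' Eye-closure censoring
#'
#' Censors volumes overlapping any eye closure longer than
#' `cfg$eye_closure_min` seconds, and additionally the volumes between two
#' qualifying closures less than `cfg$eye_gap_merge` seconds apart (brief
#' reopenings between sleep-like episodes).
#'
#' @param closures data.frame with `onset` and `offset` in seconds.
#' @param tr repetition time in seconds.
#' @param n_volumes volumes in the run.
#' @param cfg a [censor_config].
#' @return logical keep-flag vector of length `n_volumes` (TRUE = keep).
#' @export
eye_closure_censor <- function(closures, tr, n_volumes,
                               cfg = censor_config()) {
  closures <- as.data.frame(closures)
  if (nrow(closures) &&
      (any(closures$offset < closures$onset) || any(closures$onset < 0)))
    stop("malformed eye-closure intervals", call. = FALSE)
  keep <- rep(TRUE, n_volumes)
  vol_start <- (seq_len(n_volumes) - 1) * tr
  vol_end <- vol_start + tr
  qual <- closures[closures$offset - closures$onset > cfg$eye_closure_min, ,
                   drop = FALSE]
  censor_interval <- function(a, b) {
    keep[vol_end > a & vol_start < b] <<- FALSE
  }
  for (i in seq_len(nrow(qual))) censor_interval(qual$onset[i], qual$offset[i])
  if (nrow(qual) >= 2) {
    qual <- qual[order(qual$onset), ]
    for (i in seq_len(nrow(qual) - 1)) {
      gap <- qual$onset[i + 1] - qual$offset[i]
      if (gap > 0 && gap < cfg$eye_gap_merge)
        censor_interval(qual$offset[i], qual$onset[i + 1])
    }
  }
  keep
}

#' Apply segment, run, and participant retention rules
#'
#' Contiguous kept segments shorter than `min_segment` seconds are
#' censored; runs retaining fewer than `min_run_retained` seconds are
#' dropped; the participant is dropped with fewer than `min_runs` kept runs
#' or less than `min_total` seconds in total.
#'
#' @param masks list of per-run logical keep vectors.
#' @param tr repetition time in seconds.
#' @param cfg a [censor_config].
#' @return list with `masks` (pruned keep vectors), `run_kept` (logical per
#'   run), `participant_kept`, and `retained_seconds` per run.
#' @export
apply_retention_rules <- function(masks, tr, cfg = censor_config()) {
  pruned <- lapply(masks, function(keep) {
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in seq_along(r$values)) {
      if (r$values[i] && r$lengths[i] * tr < cfg$min_segment)
        keep[starts[i]:ends[i]] <- FALSE
    }
    keep
  })
  retained <- vapply(pruned, function(k) sum(k) * tr, numeric(1))
  run_kept <- retained >= cfg$min_run_retained
  participant_kept <- sum(run_kept) >= cfg$min_runs &&
    sum(retained[run_kept]) >= cfg$min_total
  list(masks = pruned, run_kept = run_kept,
       participant_kept = participant_kept, retained_seconds = retained)
}

# Second-order zero-phase Butterworth band-pass (applied forward and
# backward via filtfilt). The mean is removed first: the pass band excludes
# DC anyway, and demeaning keeps filter start-up transients from leaking a
# constant offset into the edges.
butter_bandpass <- function(x, tr, low = 0.009, high = 0.08) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  if (is.matrix(x)) {
    apply(x, 2, function(col) signal::filtfilt(bf, col - mean(col)))
  } else {
    signal::filtfilt(bf, x - mean(x))
  }
}

#' Edge-discard volume count
#'
#' Number of volumes discarded from each end of a run after band-pass
#' filtering to remove edge artifacts: `ceiling(edge_seconds / tr)`.
#'
#' @param tr repetition time in seconds.
#' @param edge_seconds discard duration per end (default 22).
#' @return integer volume count.
#' @export
edge_discard_volumes <- function(tr, edge_seconds = 22) {
  as.integer(ceiling(edge_seconds / tr))
}

#' Band-pass filter with censored-point interpolation
#'
#' Censored time points are replaced by linear interpolation (edges held at
#' the nearest retained value), the 0.009-0.08 Hz second-order zero-phase
#' Butterworth filter is applied, the first and last
#' `ceiling(edge_seconds/tr)` volumes are discarded, and censored volumes
#' are finally dropped.
#'
#' @param x numeric vector or matrix (time in rows).
#' @param keep logical keep vector (TRUE = retained); NULL keeps all.
#' @param tr repetition time in seconds.
#' @param band band edges in Hz (default c(0.009, 0.08)).
#' @param edge_seconds duration discarded from each end (default 22).
#' @return list with `data` (retained, filtered values), `retained_index`
#'   (indices into the original run), and `n_edge` per end.
#' @export
bandpass_with_interpolation <- function(x, keep = NULL, tr,
                                        band = c(0.009, 0.08),
                                        edge_seconds = 22) {
  m <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(m)
  if (is.null(keep)) keep <- rep(TRUE, n)
  stopifnot(length(keep) == n)
  if (sum(keep) < 2)
    stop("fewer than 2 retained volumes", call. = FALSE)
  ki <- which(keep)
  for (j in seq_len(ncol(m))) {
    m[, j] <- stats::approx(ki, m[ki, j], xout = seq_len(n),
                            rule = 2)$y
  }
  f <- butter_bandpass(m, tr, band[1], band[2])
  if (!is.matrix(f)) f <- matrix(f, ncol = ncol(m))
  n_edge <- edge_discard_volumes(tr, edge_seconds)
  inner <- seq_len(n) > n_edge & seq_len(n) <= n - n_edge
  retained <- which(inner & keep)
  if (!length(retained))
    stop("no volumes remain after edge discard and censoring",
         call. = FALSE)
  out <- f[retained, , drop = FALSE]
  if (!is.matrix(x)) out <- as.numeric(out)
  list(data = out, retained_index = retained, n_edge = n_edge)
}

#' Build the RSFC nuisance matrix
#'
#' 28 columns: the 6 motion parameters band-pass filtered with the same
#' filter as the data, their squares, their backward-difference derivatives
#' (first element 0), the squares of the derivatives, then WM and CSF
#' compartment signals each with its derivative. Squaring happens after
#' filtering; derivatives are taken after filtering.
#'
#' @param motion data.frame or matrix of 6 motion parameters (rows = volumes).
#' @param wm,csf compartment nuisance series.
#' @param tr repetition time in seconds.
#' @param band band edges for motion filtering (default c(0.009, 0.08)).
#' @param filter_compartments also band-pass WM/CSF before use
#'   (default FALSE).
#' @return numeric matrix (volumes x 28) with named columns.
#' @export
build_rsfc_nuisance <- function(motion, wm, csf, tr,
                                band = c(0.009, 0.08),
                                filter_compartments = FALSE) {
  mp <- as.matrix(motion)
  if (ncol(mp) != 6L) stop("motion table must have 6 columns", call. = FALSE)
  n <- nrow(mp)
  if (length(wm) != n || length(csf) != n)
    stop("WM/CSF series must match the motion table length", call. = FALSE)
  mpf <- butter_bandpass(mp, tr, band[1], band[2])
  if (!is.matrix(mpf)) mpf <- matrix(mpf, ncol = 6)
  deriv <- function(v) c(0, diff(v))
  mpd <- apply(mpf, 2, deriv)
  if (filter_compartments) {
    wm <- butter_bandpass(wm, tr, band[1], band[2])
    csf <- butter_bandpass(csf, tr, band[1], band[2])
  }
  out <- cbind(mpf, mpf^2, mpd, mpd^2, wm, deriv(wm), csf, deriv(csf))
  colnames(out) <- c(paste0("mp", 1:6, "_f"), paste0("mp", 1:6, "_f_sq"),
                     paste0("mp", 1:6, "_d"), paste0("mp", 1:6, "_d_sq"),
                     "wm", "wm_d", "csf", "csf_d")
  out
}

#' ROI-pair partial-correlation connectivity
#'
#' The four pairwise partial correlations (left/right seed with left/right
#' target, residualized on the nuisance matrix plus intercept) averaged
#' into a single run-level estimate.
#'
#' @param seed_left,seed_right,target_left,target_right numeric ROI series
#'   over identical retained volumes (unsmoothed rest data).
#' @param nuisance nuisance matrix over the same volumes, or NULL.
#' @return list with `estimate` (mean of the four) and `pairwise` (named
#'   vector).
#' @export
roi_pair_connectivity <- function(seed_left, seed_right,
                                  target_left, target_right,
                                  nuisance = NULL) {
  R <- residualize(cbind(sl = seed_left, sr = seed_right,
                         tl = target_left, tr = target_right), nuisance)
  pc <- function(a, b) {
    sa <- stats::sd(R[, a]); sb <- stats::sd(R[, b])
    if (sa < 1e-12 || sb < 1e-12)
      stop("degenerate ROI series after residualization", call. = FALSE)
    stats::cor(R[, a], R[, b])
  }
  pairwise <- c(ll = pc("sl", "tl"), lr = pc("sl", "tr"),
                rl = pc("sr", "tl"), rr = pc("sr", "tr"))
  list(estimate = mean(pairwise), pairwise = pairwise)
}

#' Selectivity t-tests across a cohort
#'
#' One-tailed paired t-tests of the four selectivity contrasts —
#' MGN-AC > MGN-VC, MGN-AC > LGN-AC, LGN-VC > LGN-AC, LGN-VC > MGN-VC —
#' with Benjamini-Hochberg FDR adjustment across the four.
#'
#' @param connectivity data.frame with one row per participant and columns
#'   `mgn_ac`, `mgn_vc`, `lgn_ac`, `lgn_vc`.
#' @param alpha significance level applied to adjusted p-values
#'   (default 0.05).
#' @return data.frame with contrast, t, df, p, p_fdr, significant.
#' @export
selectivity_tests <- function(connectivity, alpha = 0.05) {
  req <- c("mgn_ac", "mgn_vc", "lgn_ac", "lgn_vc")
  stopifnot(all(req %in% names(connectivity)))
  if (nrow(connectivity) < 2)
    stop("selectivity tests need at least 2 participants", call. = FALSE)
  contrasts <- list(
    mgn_ac_gt_mgn_vc = c("mgn_ac", "mgn_vc"),
    mgn_ac_gt_lgn_ac = c("mgn_ac", "lgn_ac"),
    lgn_vc_gt_lgn_ac = c("lgn_vc", "lgn_ac"),
    lgn_vc_gt_mgn_vc = c("lgn_vc", "mgn_vc"))
  res <- lapply(contrasts, function(cols) {
    d <- connectivity[[cols[1]]] - connectivity[[cols[2]]]
    n <- length(d)
    s <- stats::sd(d)
    t_stat <- if (s < 1e-15) {
      if (abs(mean(d)) < 1e-15) 0 else sign(mean(d)) * Inf
    } else mean(d) / (s / sqrt(n))
    c(t = t_stat, df = n - 1,
      p = stats::pt(t_stat, df = n - 1, lower.tail = FALSE))
  })
  out <- data.frame(contrast = names(contrasts),
                    t = vapply(res, `[[`, numeric(1), "t"),
                    df = vapply(res, `[[`, numeric(1), "df"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_fdr < alpha
  out
}

#' Whole-brain seed connectivity map
#'
#' Voxelwise partial correlation between each hemisphere's seed series and
#' every in-mask voxel of the (smoothed) rest series, then the voxelwise
#' mean of the two hemisphere maps.
#'
#' @param series a [vol_series] restricted to the analysis volumes.
#' @param mask a [mask_volume] of voxels to map.
#' @param seed_left,seed_right numeric seed series over the same volumes.
#' @param nuisance nuisance matrix, or NULL.
#' @return a [vol_image] of partial correlations (0 outside the mask).
#' @export
seed_connectivity_map <- function(series, mask, seed_left, seed_right,
                                  nuisance = NULL) {
  d <- dim(series$data)
  idx <- which(as.vector(mask$data))
  Y <- t(matrix(series$data, nrow = prod(d[1:3]))[idx, , drop = FALSE])
  one_map <- function(seed) {
    R <- residualize(cbind(seed, Y), nuisance)
    rs <- R[, 1]
    RY <- R[, -1, drop = FALSE]
    ss <- stats::sd(rs)
    if (!is.finite(ss) || ss < 1e-12)
      stop("degenerate seed series after residualization", call. = FALSE)
    sv <- apply(RY, 2, stats::sd)
    vals <- rep(0, length(idx))
    ok <- is.finite(sv) & sv >= 1e-12
    vals[ok] <- as.vector(stats::cor(rs, RY[, ok, drop = FALSE]))
    vals
  }
  vals <- (one_map(seed_left) + one_map(seed_right)) / 2
  out <- array(0, d[1:3])
  out[idx] <- vals
  vol_image(out, series$affine)
}

#' Dice-Sorensen overlap coefficient
#'
#' `2|A and B| / (|A| + |B|)`; two empty masks give 0 with a warning.
#'
#' @param a,b [mask_volume]s on the same grid.
#' @return coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  stopifnot_same_grid(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) {
    warning("both masks are empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a$data & b$data) / (na + nb)
}
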