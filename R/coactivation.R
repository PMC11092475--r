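# Partial-correlation machinery shared by the coactivation and RSFC stages.

# Residualize columns of Y (t x k) on [1, nuisance] by QR (rank-deficient
# nuisance sets are handled through the pivoted decomposition).
residualize <- function(Y, nuisance = NULL) {
  Y <- as.matrix(Y)
  X <- cbind(intercept = rep(1, nrow(Y)),
             if (!is.null(nuisance) && NCOL(nuisance) > 0) as.matrix(nuisance))
  Y - qr.fitted(qr(X), Y)
}

#' Partial correlation
#'
#' Pearson correlation between `x` and `y` after both are residualized on
#' the nuisance matrix (plus an intercept). Degenerate (constant after
#' residualization) inputs give 0 with attribute `degenerate = TRUE`.
#'
#' @param x,y numeric vectors of equal length.
#' @param nuisance optional matrix of nuisance regressors (rows = time).
#' @return partial correlation in [-1, 1].
#' @export
partial_correlation <- function(x, y, nuisance = NULL) {
  R <- residualize(cbind(x, y), nuisance)
  sx <- stats::sd(R[, 1]); sy <- stats::sd(R[, 2])
  if (!is.finite(sx) || !is.finite(sy) || sx < 1e-12 || sy < 1e-12)
    return(structure(0, degenerate = TRUE))
  stats::cor(R[, 1], R[, 2])
}

#' Coactivation map of a thalamic search region
#'
#' For every TSR voxel, the Pearson partial correlation between the voxel's
#' task time series and a cortical reference series, controlling for the
#' nuisance matrix (WM, CSF, global GM, local WM, cluster-volume
#' indicators, run intercepts).
#'
#' @param series a [vol_series] or list of per-run `vol_series` (smoothed
#'   task data), concatenated in time.
#' @param tsr a [mask_volume] (or `tsr` object).
#' @param cortex_series numeric reference series (one value per volume).
#' @param nuisance matrix of nuisance regressors, or NULL.
#' @return a `coactivation_map`: list with `values` (r per TSR voxel),
#'   `voxels` (linear indices), `tsr`, and `degenerate` (logical flags).
#' @export
coactivation_map <- function(series, tsr, cortex_series, nuisance = NULL) {
  if (inherits(tsr, "tsr")) tsr <- tsr$mask
  if (inherits(series, "vol_series")) series <- list(series)
  idx <- which(as.vector(tsr$data))
  Y <- do.call(rbind, lapply(series, function(s) {
    d <- dim(s$data)
    t(matrix(s$data, nrow = prod(d[1:3]))[idx, , drop = FALSE])
  }))
  if (nrow(Y) != length(cortex_series))
    stop("cortex series and task series span different volume counts",
         call. = FALSE)
  R <- residualize(cbind(cortex_series, Y), nuisance)
  rc <- R[, 1]
  RY <- R[, -1, drop = FALSE]
  sc <- stats::sd(rc)
  sv <- apply(RY, 2, stats::sd)
  degen <- !is.finite(sv) | sv < 1e-12 | !is.finite(sc) | sc < 1e-12
  vals <- rep(0, length(idx))
  if (sc >= 1e-12) {
    ok <- !degen
    vals[ok] <- as.vector(stats::cor(rc, RY[, ok, drop = FALSE]))
  }
  structure(list(values = vals, voxels = idx, tsr = tsr,
                 degenerate = degen),
            class = "coactivation_map")
}

#' Adaptive coactivation threshold
#'
#' The kept fraction is `numerator / mean(hemisphere TSR sizes)`, capped at
#' 1; within this hemisphere's map the `ceiling(fraction * N)` highest
#' partial correlations survive (ties broken by value then linear voxel
#' index). The numerators (32 for MGN, 20 for LGN) make the survivor count
#' approximately constant across participants regardless of TSR size.
#'
#' @param map a [coactivation_map].
#' @param tsr_sizes numeric vector of the left and right TSR voxel counts.
#' @param numerator threshold numerator (32 for MGN-TSR, 20 for LGN-TSR).
#' @return a [mask_volume] of surviving voxels.
#' @export
adaptive_threshold <- function(map, tsr_sizes, numerator) {
  stopifnot(inherits(map, "coactivation_map"), numerator > 0)
  n <- length(map$voxels)
  if (n == 0L) stop("coactivation map is empty", call. = FALSE)
  fraction <- min(1, numerator / mean(tsr_sizes))
  k <- min(n, ceiling(fraction * n))
  ord <- order(-map$values, map$voxels)
  keep <- map$voxels[ord[seq_len(k)]]
  out <- array(FALSE, dim(map$tsr$data))
  out[keep] <- TRUE
  mask_volume(out, map$tsr$affine)
}

#' Remove cross-modal overlap between thresholded maps
#'
#' Voxels surviving both the AC and the VC thresholded coactivation map of
#' the same TSR are removed from both, improving modality specificity.
#'
#' @param ac_mask,vc_mask [mask_volume]s on the same grid.
#' @return list with disjoint `ac` and `vc` masks.
#' @export
remove_cross_modal_overlap <- function(ac_mask, vc_mask) {
  stopifnot_same_grid(ac_mask, vc_mask)
  both <- ac_mask$data & vc_mask$data
  list(ac = mask_volume(ac_mask$data & !both, ac_mask$affine),
       vc = mask_volume(vc_mask$data & !both, vc_mask$affine))
}

#' Extract the fROI from a thresholded map
#'
#' The largest contiguous cluster (18-connectivity by default); an empty
#' input yields an empty fROI flagged rather than an error.
#'
#' @param thresholded a [mask_volume].
#' @param connectivity cluster contiguity (default 18).
#' @return list with `mask` and logical `empty`.
#' @export
extract_froi <- function(thresholded, connectivity = 18L) {
  comps <- connected_components(thresholded, connectivity)
  if (!length(comps))
    return(list(mask = mask_volume(array(FALSE, dim(thresholded$data)),
                                   thresholded$affine),
                empty = TRUE))
  list(mask = comps[[1]], empty = FALSE)
}

#' Automated fROI quality-control flags
#'
#' Surrogates for manual anatomical review: flags any empty fROI, an LGN
#' centroid inferior or medial to the ipsilateral MGN centroid, left/right
#' size asymmetry of either nucleus beyond `asymmetry_bound`, and any
#' overlap between MGN and LGN fROIs.
#'
#' @param mgn_left,mgn_right,lgn_left,lgn_right [mask_volume] fROIs.
#' @param asymmetry_bound maximum allowed left/right (or right/left) size
#'   ratio (default 3).
#' @return character vector of flag names (empty when all checks pass).
#' @export
qc_flags <- function(mgn_left, mgn_right, lgn_left, lgn_right,
                     asymmetry_bound = 3) {
  rois <- list(mgn_left = mgn_left, mgn_right = mgn_right,
               lgn_left = lgn_left, lgn_right = lgn_right)
  flags <- character(0)
  sizes <- vapply(rois, function(m) sum(m$data), numeric(1))
  for (nm in names(rois)) if (sizes[[nm]] == 0)
    flags <- c(flags, paste0("empty_", nm))
  cent <- lapply(rois, mask_centroid_world)
  for (h in c("left", "right")) {
    m <- cent[[paste0("mgn_", h)]]; l <- cent[[paste0("lgn_", h)]]
    if (anyNA(m) || anyNA(l)) next
    if (l[3] < m[3]) flags <- c(flags, paste0("lgn_inferior_to_mgn_", h))
    if (abs(l[1]) < abs(m[1]))
      flags <- c(flags, paste0("lgn_medial_to_mgn_", h))
  }
  for (nuc in c("mgn", "lgn")) {
    a <- sizes[[paste0(nuc, "_left")]]; b <- sizes[[paste0(nuc, "_right")]]
    if (a > 0 && b > 0 && max(a / b, b / a) > asymmetry_bound)
      flags <- c(flags, paste0("asymmetry_", nuc))
  }
  for (h in c("left", "right")) {
    if (any(rois[[paste0("mgn_", h)]]$data & rois[[paste0("lgn_", h)]]$data))
      flags <- c(flags, paste0("mgn_lgn_overlap_", h))
  }
  flags
}
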