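#' Build auditory and visual cortex search masks
#'
#' Per hemisphere, the auditory cortex (AC) search mask is the union of the
#' BA 41/42-style labels and the visual cortex (VC) mask the union of the
#' BA 17/18-style labels, each dilated once in 3D.
#'
#' @param ba_labels a [label_volume] containing the cortical labels.
#' @param ac_names,vc_names named list with elements `left` and `right`,
#'   each a character vector of label names to union for that hemisphere.
#' @return list of four [mask_volume]s: `ac_left`, `ac_right`, `vc_left`,
#'   `vc_right`.
#' @export
build_cortex_search_masks <- function(ba_labels,
                                      ac_names = list(left = "ac_l",
                                                      right = "ac_r"),
                                      vc_names = list(left = "vc_l",
                                                      right = "vc_r")) {
  get <- function(nms) dilate_mask(label_mask(ba_labels, nms), 1L)
  out <- list(ac_left = get(ac_names$left), ac_right = get(ac_names$right),
              vc_left = get(vc_names$left), vc_right = get(vc_names$right))
  for (nm in names(out)) {
    if (!any(out[[nm]]$data))
      stop("cortex search mask is empty: ", nm, call. = FALSE)
  }
  out
}

# Deterministically pick the k most extreme in-mask voxels of a map.
# `tail = "upper"` takes the largest values, `"lower"` the smallest; ties
# at the cutoff are broken by value and then by linear voxel index.
top_fraction_mask <- function(values, mask, fraction, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  idx <- which(mask$data)
  n <- length(idx)
  k <- ceiling(fraction * n)
  v <- values[idx]
  ord <- if (tail == "upper") order(-v, idx) else order(v, idx)
  keep <- idx[ord[seq_len(min(k, n))]]
  out <- array(FALSE, dim(mask$data))
  out[keep] <- TRUE
  mask_volume(out, mask$affine)
}

#' Select the maximally responsive cortex cluster
#'
#' Thresholds the contrast map to the most extreme `fraction` of in-mask
#' voxels (upper tail for AC, lower tail for VC on the Auditory - Visual
#' contrast), removes connected components smaller than `min_cluster`
#' voxels, and returns the component containing the largest-magnitude
#' surviving contrast value.
#'
#' @param contrast a [vol_image] contrast map.
#' @param search a [mask_volume] search region.
#' @param tail `"upper"` or `"lower"`.
#' @param fraction fraction of in-mask voxels to keep (default 0.10).
#' @param min_cluster minimum component size in voxels (default 10).
#' @param connectivity cluster contiguity (default 18).
#' @return a `cortex_cluster`: list with `mask`, `peak_value`, `size`.
#' @export
select_cortex_cluster <- function(contrast, search, tail = c("upper", "lower"),
                                  fraction = 0.10, min_cluster = 10L,
                                  connectivity = 18L) {
  tail <- match.arg(tail)
  if (!any(search$data)) stop("search mask is empty", call. = FALSE)
  stopifnot_same_grid(contrast, search)
  thr <- top_fraction_mask(contrast$data, search, fraction, tail)
  comps <- connected_components(thr, connectivity)
  comps <- Filter(function(m) sum(m$data) >= min_cluster, comps)
  if (!length(comps))
    stop("no suprathreshold cluster of at least ", min_cluster,
         " voxels in the search mask", call. = FALSE)
  peaks <- vapply(comps, function(m) max(abs(contrast$data[m$data])),
                  numeric(1))
  best <- comps[[which.max(peaks)]]
  structure(list(mask = best, peak_value = max(abs(contrast$data[best$data])),
                 size = sum(best$data)),
            class = "cortex_cluster")
}

# Spatial mean time series of a mask. Linear indexing into the 4D array
# avoids copying the full series for small masks.
mask_mean_series <- function(series, mask) {
  d <- dim(series$data)
  nvox <- prod(d[1:3])
  idx <- which(as.vector(mask$data))
  if (!length(idx)) stop("cannot average an empty mask", call. = FALSE)
  out <- numeric(d[4])
  chunk <- max(1L, floor(5e6 / length(idx)))
  for (t0 in seq(1L, d[4], by = chunk)) {
    tt <- t0:min(t0 + chunk - 1L, d[4])
    block <- series$data[rep(idx, length(tt)) +
                           rep((tt - 1) * nvox, each = length(idx))]
    dim(block) <- c(length(idx), length(tt))
    out[tt] <- colMeans(block)
  }
  out
}

#' Primary anatomical AC and VC ROIs
#'
#' Anatomically defined sensory-cortex ROIs used for resting-state
#' validation, independent of the task. The AC ROI is the transverse
#' temporal parcel dilated once in 3D. The VC ROI is the pericalcarine
#' parcel dilated once, restricted to grey matter, then dilated twice more.
#'
#' @param parcellation a [label_volume].
#' @param ac_label,vc_label per-hemisphere parcel name.
#' @param gm_names grey-matter label names used for the VC restriction.
#' @return a [mask_volume].
#' @export
build_primary_ac_roi <- function(parcellation, ac_label) {
  dilate_mask(label_mask(parcellation, ac_label), 1L)
}

#' @rdname build_primary_ac_roi
#' @export
build_primary_vc_roi <- function(parcellation, vc_label,
                                 gm_names = phantom_gm_names()) {
  gm <- label_mask(parcellation,
                   gm_names[gm_names %in% parcellation$label_table$name])
  step1 <- dilate_mask(label_mask(parcellation, vc_label), 1L)
  step1$data <- step1$data & gm$data
  dilate_mask(step1, 2L)
}

#' Extract hemisphere-averaged cortex time series
#'
#' Averages the task series within each hemisphere's cluster, then takes
#' the unweighted mean of the two hemisphere series.
#'
#' @param series a [vol_series] (smoothed task data).
#' @param cluster_left,cluster_right `cortex_cluster`s (or bare
#'   [mask_volume]s).
#' @return numeric vector, one value per acquired volume.
#' @export
extract_cortex_series <- function(series, cluster_left, cluster_right) {
  as_mask <- function(x) if (inherits(x, "cortex_cluster")) x$mask else x
  l <- mask_mean_series(series, as_mask(cluster_left))
  r <- mask_mean_series(series, as_mask(cluster_right))
  (l + r) / 2
}
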