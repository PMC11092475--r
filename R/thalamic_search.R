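#' Build a thalamic search region (TSR)
#'
#' Starting from one hemisphere's segmented nucleus, the TSR is the nucleus
#' dilated in 3D (3 iterations for MGN, whose segmentation estimates are
#' small; 1 for the larger LGN), with voxels belonging to surrounding
#' structures removed: cortical grey matter, parahippocampal WM and
#' hippocampus undilated, and mediodorsal nucleus, insular WM, choroid
#' plexus, pulvinar, putamen and pallidum each dilated by one voxel. The
#' posterior-most two occupied slices of the resulting TSR are then removed
#' (to stay clear of midbrain), and for the MGN only, voxels superior to
#' the inferior-most pulvinar slice (over both hemispheres) are removed so
#' the search stays in inferior posterior thalamus.
#'
#' @param thalamic_labels [label_volume] with thalamic-nuclei labels
#'   (`mgn_l`, `lgn_l`, `pulvinar_l`, `mediodorsal_l`, and `_r`
#'   counterparts).
#' @param parcellation [label_volume] with the whole-brain parcellation
#'   (`cortical_gm`, `parahippocampal_wm_*`, `hippocampus_*`,
#'   `insular_wm_*`, `choroid_plexus_*`, `putamen_*`, `pallidum_*`; may be
#'   the same object as `thalamic_labels`).
#' @param nucleus `"mgn"` or `"lgn"`.
#' @param hemisphere `"l"` or `"r"`.
#' @return a `tsr`: list with `mask` ([mask_volume]), `nucleus`,
#'   `hemisphere`, and `provenance` (voxels removed per rule).
#' @export
build_tsr <- function(thalamic_labels, parcellation,
                      nucleus = c("mgn", "lgn"), hemisphere = c("l", "r")) {
  nucleus <- match.arg(nucleus)
  hemisphere <- match.arg(hemisphere)
  stopifnot_same_grid(thalamic_labels, parcellation)
  seed_name <- paste0(nucleus, "_", hemisphere)
  seed <- label_mask(thalamic_labels, seed_name)
  if (!any(seed$data))
    stop("nucleus label is empty: ", seed_name, call. = FALSE)
  dil_iter <- if (nucleus == "mgn") 3L else 1L
  tsr <- dilate_mask(seed, dil_iter)
  prov <- list(seed_voxels = sum(seed$data), dilated_voxels = sum(tsr$data))

  both <- function(stem) paste0(stem, c("_l", "_r"))
  has <- function(lv, nms) nms[nms %in% lv$label_table$name]
  excl <- array(FALSE, dim(tsr$data))
  plain <- c("cortical_gm", both("parahippocampal_wm"), both("hippocampus"))
  for (nm in c(has(parcellation, plain), has(thalamic_labels, plain)))
    excl <- excl | label_mask(
      if (nm %in% parcellation$label_table$name) parcellation
      else thalamic_labels, nm)$data
  dil1 <- c(both("mediodorsal"), both("insular_wm"), both("choroid_plexus"),
            both("pulvinar"), both("putamen"), both("pallidum"))
  for (nm in unique(c(has(parcellation, dil1), has(thalamic_labels, dil1)))) {
    src <- if (nm %in% thalamic_labels$label_table$name) thalamic_labels
           else parcellation
    excl <- excl | dilate_mask(label_mask(src, nm), 1L)$data
  }
  removed <- tsr$data & excl
  prov$removed_structures <- sum(removed)
  cur <- tsr$data & !excl

  ori <- axis_orientation(tsr$affine)
  ant_dim <- ori$dim[2]; ant_sign <- ori$sign[2]
  sup_dim <- ori$dim[3]; sup_sign <- ori$sign[3]
  slice_coord <- function(arr, d) {
    idx <- which(arr, arr.ind = TRUE)
    if (!nrow(idx)) integer(0) else idx[, d]
  }
  # posterior-most 2 occupied slices of this TSR
  occ <- sort(unique(slice_coord(cur, ant_dim)))
  if (length(occ)) {
    post2 <- if (ant_sign > 0) utils::head(occ, 2) else utils::tail(occ, 2)
    sl <- slice_coord(cur, ant_dim)
    kill <- which(cur)[sl %in% post2]
    prov$removed_posterior_slices <- length(kill)
    cur[kill] <- FALSE
  } else prov$removed_posterior_slices <- 0L

  if (nucleus == "mgn") {
    pulv <- label_mask(thalamic_labels, both("pulvinar"))
    pz <- slice_coord(pulv$data, sup_dim)
    if (length(pz)) {
      inf_most <- if (sup_sign > 0) min(pz) else max(pz)
      cz <- slice_coord(cur, sup_dim)
      above <- if (sup_sign > 0) cz > inf_most else cz < inf_most
      kill <- which(cur)[above]
      prov$removed_superior_to_pulvinar <- length(kill)
      cur[kill] <- FALSE
    } else prov$removed_superior_to_pulvinar <- 0L
  }
  prov$final_voxels <- sum(cur)
  if (!any(cur))
    stop("TSR construction emptied ", seed_name,
         "; participant fails TSR QC", call. = FALSE)
  structure(list(mask = mask_volume(cur, tsr$affine), nucleus = nucleus,
                 hemisphere = hemisphere, provenance = prov),
            class = "tsr")
}

#' Local white-matter nuisance mask for a TSR
#'
#' WM voxels whose Chebyshev ("any direction") distance to the TSR lies in
#' 1..5 voxels: `(dilate(tsr, 5) \ tsr) & wm`.
#'
#' @param tsr a [mask_volume] (or `tsr` object).
#' @param wm a [mask_volume] of white matter.
#' @return a [mask_volume], disjoint from the TSR.
#' @export
build_local_wm_mask <- function(tsr, wm) {
  if (inherits(tsr, "tsr")) tsr <- tsr$mask
  stopifnot_same_grid(tsr, wm)
  ring <- dilate_mask(tsr, 5L)$data & !tsr$data
  mask_volume(ring & wm$data, tsr$affine)
}

#' Global grey-matter nuisance mask
#'
#' Union of the grey-matter labels, eroded once; the corresponding global
#' signal is extracted from unsmoothed data downstream.
#'
#' @param parcellation a [label_volume].
#' @param gm_names character vector of grey-matter label names.
#' @return a [mask_volume].
#' @export
build_global_gm_mask <- function(parcellation, gm_names = phantom_gm_names()) {
  gm <- label_mask(parcellation, gm_names[gm_names %in%
                                            parcellation$label_table$name])
  out <- erode_mask(gm, 1L)
  if (!any(out$data))
    stop("grey-matter mask is empty after erosion", call. = FALSE)
  out
}
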