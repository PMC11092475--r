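#' 3D binary morphology and components
#'
#' Dilation and erosion use the full 3x3x3 (26-connectivity) structuring
#' element; cluster contiguity defaults to 18-connectivity (faces + edges),
#' the dominant fMRI clustering convention.
#'
#' @name morphology
NULL

# Shift a 3D array by (dx, dy, dz), filling exposed planes with `fill`.
shift3d <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) {
    i <- seq_len(n)
    i[i - s >= 1 & i - s <= n]
  }
  xi <- src(d[1], dx); yi <- src(d[2], dy); zi <- src(d[3], dz)
  if (!length(xi) || !length(yi) || !length(zi)) return(out)
  out[xi, yi, zi] <- a[xi - dx, yi - dy, zi - dz]
  out
}

neighbour_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1,
                 "18" = ord <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  as.matrix(g[keep, ])
}

dilate_once <- function(a) {
  out <- a
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out | shift3d(a, dx, dy, dz, fill = FALSE)
  }
  out
}

erode_once <- function(a) {
  out <- a
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out & shift3d(a, dx, dy, dz, fill = FALSE)
  }
  out
}

#' @rdname morphology
#' @param mask a [mask_volume].
#' @param iterations number of dilation iterations (>= 0); 0 is the identity.
#' @return a `mask_volume`.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  stopifnot(inherits(mask, "mask_volume"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop("iterations must be >= 0", call. = FALSE)
  a <- mask$data
  for (i in seq_len(iterations)) a <- dilate_once(a)
  mask_volume(a, mask$affine)
}

#' Erode a mask
#'
#' Plain 26-neighbourhood erosion, `iterations` times.
#'
#' @inheritParams dilate_mask
#' @export
erode_mask <- function(mask, iterations = 1L) {
  stopifnot(inherits(mask, "mask_volume"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop("iterations must be >= 0", call. = FALSE)
  a <- mask$data
  for (i in seq_len(iterations)) a <- erode_once(a)
  mask_volume(a, mask$affine)
}

#' Iteratively erode a nuisance-compartment mask
#'
#' Applies up to `max_iterations` erosions; before each, checks that the
#' eroded mask would retain at least `min_voxels` voxels and stops when it
#' would not. Used to shave partial-volume voxels from WM and CSF
#' compartments before extracting nuisance time series.
#'
#' @param mask a [mask_volume].
#' @param max_iterations maximum erosions (default 3).
#' @param min_voxels minimum voxels the next erosion must leave (default 2).
#' @return a `mask_volume`.
#' @export
erode_compartment_mask <- function(mask, max_iterations = 3L, min_voxels = 2L) {
  stopifnot(inherits(mask, "mask_volume"))
  a <- mask$data
  for (i in seq_len(max_iterations)) {
    nxt <- erode_once(a)
    if (sum(nxt) < min_voxels) break
    a <- nxt
  }
  mask_volume(a, mask$affine)
}

#' Connected components of a mask
#'
#' @param mask a [mask_volume].
#' @param connectivity 6, 18 or 26 (default 18: faces + edges).
#' @return list of `mask_volume` components, ordered by size descending,
#'   ties broken by smallest linear voxel index. Empty mask gives an empty
#'   list.
#' @export
connected_components <- function(mask, connectivity = 18L) {
  stopifnot(inherits(mask, "mask_volume"))
  d <- dim(mask$data)
  lab <- component_labels(mask$data, connectivity)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ids)) return(list())
  sizes <- tabulate(lab, nbins = max(ids))[ids]
  first_idx <- vapply(ids, function(i) which(lab == i)[1], integer(1))
  ord <- order(-sizes, first_idx)
  lapply(ids[ord], function(i)
    mask_volume(array(lab == i, d), mask$affine))
}

# Integer component labelling by vectorized BFS.
component_labels <- function(a, connectivity = 18L) {
  d <- dim(a)
  lab <- array(0L, d)
  offs <- neighbour_offsets(connectivity)
  next_id <- 0L
  todo <- which(a & lab == 0L)
  while (length(todo)) {
    seed <- todo[1]
    next_id <- next_id + 1L
    lab[seed] <- next_id
    frontier <- arrayInd(seed, d)
    while (nrow(frontier)) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                       drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + d[1] * (cand[, 2] - 1) +
                      d[1] * d[2] * (cand[, 3] - 1))
      lin <- lin[a[lin] & lab[lin] == 0L]
      lab[lin] <- next_id
      frontier <- arrayInd(lin, d)
    }
    todo <- which(a & lab == 0L)
  }
  lab
}

#' Resample a label volume to a target grid (nearest neighbour)
#'
#' Each target voxel centre is mapped to world coordinates and assigned the
#' label of the nearest source voxel; targets falling outside the source
#' field of view get 0.
#'
#' @param labels a [label_volume].
#' @param target a volume object defining the output grid (dims + affine).
#' @return a `label_volume` on the target grid with the label table
#'   preserved.
#' @export
resample_labels_nearest <- function(labels, target) {
  stopifnot(inherits(labels, "label_volume"))
  src_aff <- labels$affine
  if (abs(det(src_aff)) < 1e-12)
    stop("source affine is singular", call. = FALSE)
  d_t <- dim(target$data)[1:3]
  d_s <- dim(labels$data)
  grid <- as.matrix(expand.grid(i = seq_len(d_t[1]) - 1,
                                j = seq_len(d_t[2]) - 1,
                                k = seq_len(d_t[3]) - 1))
  world <- cbind(grid, 1) %*% t(target$affine)
  src_vox <- world %*% t(solve(src_aff))
  idx <- round(src_vox[, 1:3]) + 1  # back to 1-based
  ok <- idx[, 1] >= 1 & idx[, 1] <= d_s[1] &
        idx[, 2] >= 1 & idx[, 2] <= d_s[2] &
        idx[, 3] >= 1 & idx[, 3] <= d_s[3]
  out <- integer(nrow(idx))
  lin <- idx[ok, 1] + d_s[1] * (idx[ok, 2] - 1) + d_s[1] * d_s[2] * (idx[ok, 3] - 1)
  out[ok] <- labels$data[lin]
  label_volume(array(out, d_t), target$affine, labels$label_table)
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing with a kernel specified as full width at
#' half maximum in mm, converted per-axis using the affine voxel sizes.
#' Edges are handled by renormalizing the kernel to the in-volume mass.
#'
#' @param vol a `vol_image` or `vol_series`.
#' @param fwhm_mm full width at half maximum of the Gaussian, in mm.
#' @return smoothed volume of the same class.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 4) {
  if (fwhm_mm <= 0) return(vol)
  vs <- voxel_sizes(vol$affine)
  sigmas <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  kerns <- lapply(sigmas, function(s) {
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k / sum(k)
  })
  smooth3 <- function(a) {
    for (ax in 1:3) {
      n <- dim(a)[ax]
      K <- band_matrix(kerns[[ax]], n)
      a <- apply_along_axis(a, ax, K)
    }
    a
  }
  if (inherits(vol, "vol_series")) {
    out <- vol$data
    for (t in seq_len(dim(out)[4])) out[, , , t] <- smooth3(out[, , , t])
    vol_series(out, vol$affine, vol$tr)
  } else {
    vol_image(smooth3(vol$data), vol$affine)
  }
}

# n x n banded convolution matrix for kernel k (odd length), rows
# renormalized so truncation at the edges preserves local means.
band_matrix <- function(k, n) {
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    ok <- i + o >= 1 & i + o <= n
    K[cbind(i[ok], i[ok] + o)] <- k[o + r + 1L]
  }
  K / rowSums(K)
}

apply_along_axis <- function(a, ax, K) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[ax])
  res <- K %*% m
  ap <- array(res, dim(ap))
  aperm(ap, order(perm))
}
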