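#' Volume containers
#'
#' Lightweight S3 containers for volumetric data on a common voxel grid.
#' A `vol_image` is a 3D scalar array plus a 4x4 voxel-to-world affine (mm);
#' a `vol_series` adds a time axis and a repetition time; `mask_volume` and
#' `label_volume` hold boolean and integer-labelled grids respectively.
#' World coordinates follow the NIfTI convention (+x right, +y anterior,
#' +z superior); the affine maps 0-based voxel indices to mm.
#'
#' @param data numeric 3D array (`vol_image`), numeric 4D array
#'   (`vol_series`), logical 3D array (`mask_volume`) or integer 3D array
#'   (`label_volume`).
#' @param affine 4x4 numeric voxel-to-world matrix; must be finite.
#' @name volumes
NULL

new_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  affine
}

#' @rdname volumes
#' @export
vol_image <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("vol_image requires a 3D array", call. = FALSE)
  structure(list(data = data, affine = new_affine(affine)),
            class = "vol_image")
}

#' @rdname volumes
#' @param tr repetition time in seconds (> 0).
#' @export
vol_series <- function(data, affine = diag(4), tr) {
  data <- as.array(data)
  if (length(dim(data)) != 4L || dim(data)[4] < 1L)
    stop("vol_series requires a 4D array with t >= 1", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a single positive number (seconds)", call. = FALSE)
  structure(list(data = data, affine = new_affine(affine), tr = tr),
            class = "vol_series")
}

#' @rdname volumes
#' @export
mask_volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("mask_volume requires a 3D array", call. = FALSE)
  storage.mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  structure(list(data = data, affine = new_affine(affine)),
            class = "mask_volume")
}

#' @rdname volumes
#' @param label_table data.frame with columns `id` (positive integer) and
#'   `name`; every nonzero value in `data` must appear in `id`.
#' @export
label_volume <- function(data, affine = diag(4), label_table) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("label_volume requires a 3D array", call. = FALSE)
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE))
    stop("labels must be non-negative integers", call. = FALSE)
  label_table <- as.data.frame(label_table)
  if (!all(c("id", "name") %in% names(label_table)))
    stop("label_table needs columns id and name", call. = FALSE)
  present <- setdiff(unique(as.vector(data)), 0L)
  missing <- setdiff(present, label_table$id)
  if (length(missing))
    stop("labels present in data but absent from label_table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(data = data, affine = new_affine(affine),
                 label_table = label_table),
            class = "label_volume")
}

#' @export
print.vol_image <- function(x, ...) {
  cat("<vol_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(voxel_sizes(x$affine), 3), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.vol_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<vol_series> ", paste(d[1:3], collapse = " x "), " voxels x ",
      d[4], " volumes, TR ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat("<mask_volume> ", paste(dim(x$data), collapse = " x "),
      ", ", sum(x$data), " voxels set\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      ", ", nrow(x$label_table), " labels\n", sep = "")
  invisible(x)
}

voxel_sizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' Check that two volumes share a grid
#'
#' @param a,b volume objects with `data` and `affine`.
#' @param tol absolute tolerance on affine entries.
#' @return TRUE invisibly; errors on mismatch.
#' @export
stopifnot_same_grid <- function(a, b, tol = 1e-6) {
  if (!all(dim(a$data)[1:3] == dim(b$data)[1:3]))
    stop("volumes are on different grids (dimensions differ)", call. = FALSE)
  if (max(abs(a$affine - b$affine)) > tol)
    stop("volumes are on different grids (affines differ)", call. = FALSE)
  invisible(TRUE)
}

#' Extract a mask for one labelled structure
#'
#' @param labels a `label_volume`.
#' @param name structure name (or vector of names; the union is returned).
#' @return a `mask_volume`.
#' @export
label_mask <- function(labels, name) {
  ids <- labels$label_table$id[labels$label_table$name %in% name]
  if (length(ids) < length(unique(name)))
    stop("label(s) not found: ",
         paste(setdiff(name, labels$label_table$name), collapse = ", "),
         call. = FALSE)
  mask_volume(array(labels$data %in% ids, dim(labels$data)), labels$affine)
}

# Map anatomical axes to array dimensions for (near-)axis-aligned affines.
# Returns, for each world axis (x=right, y=anterior, z=superior), the array
# dimension it runs along and the sign (+1 if increasing index moves in the
# +world direction).
axis_orientation <- function(affine) {
  R <- affine[1:3, 1:3]
  dims <- apply(abs(R), 1, which.max)
  if (length(unique(dims)) != 3L)
    stop("affine is not axis-aligned enough to infer orientation",
         call. = FALSE)
  signs <- sign(R[cbind(1:3, dims)])
  list(dim = dims, sign = signs)
}

# Centroid of a mask in world coordinates (mm).
mask_centroid_world <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(rep(NA_real_, 3))
  vox <- cbind(idx - 1, 1)  # 0-based voxel coords
  w <- vox %*% t(mask$affine)
  colMeans(w[, 1:3, drop = FALSE])
}
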