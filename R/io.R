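#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file and returns a [vol_image] (3D) or [vol_series] (4D).
#' For 4D inputs the repetition time is taken from the header's pixdim[4]
#' unless overridden.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param tr optional repetition time in seconds overriding the header value.
#' @return a `vol_image` or `vol_series`.
#' @export
read_volume <- function(path, tr = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, call. = FALSE))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!all(is.finite(affine)))
    stop("non-finite affine in ", path, call. = FALSE)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop RNifti bookkeeping
  nd <- length(dim(arr))
  if (nd == 3L) {
    vol_image(arr, affine)
  } else if (nd == 4L) {
    if (is.null(tr)) {
      hdr <- RNifti::niftiHeader(img)
      tr <- hdr$pixdim[5]
      if (!is.finite(tr) || tr <= 0)
        stop("4D file has no usable TR in header; pass tr=", call. = FALSE)
    }
    vol_series(arr, affine, tr = tr)
  } else {
    stop("expected a 3D or 4D NIfTI, got ", nd, "D", call. = FALSE)
  }
}

#' Write a volume to NIfTI
#'
#' Writes a `vol_image`, `vol_series`, `mask_volume` (as 0/1) or
#' `label_volume` to a NIfTI-1 file. For a `label_volume` a JSON sidecar
#' `<path minus extension>.labels.json` mapping id to name is written too.
#'
#' @param vol a volume object.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- vol$data
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- if (inherits(vol, "vol_series"))
    c(voxel_sizes(vol$affine), vol$tr) else voxel_sizes(vol$affine)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  if (inherits(vol, "label_volume")) {
    side <- sub("\\.nii(\\.gz)?$", "", path)
    side <- paste0(side, ".labels.json")
    tab <- as.list(vol$label_table$name)
    names(tab) <- as.character(vol$label_table$id)
    jsonlite::write_json(tab, side, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a label volume with its JSON sidecar
#'
#' @param path NIfTI path; the sidecar `<path minus extension>.labels.json`
#'   must exist.
#' @return a `label_volume`.
#' @export
read_label_volume <- function(path) {
  img <- read_volume(path)
  side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
  if (!file.exists(side))
    stop("label sidecar not found: ", side, call. = FALSE)
  tab <- jsonlite::read_json(side)
  label_volume(round(img$data), img$affine,
               data.frame(id = as.integer(names(tab)),
                          name = unlist(tab, use.names = FALSE),
                          stringsAsFactors = FALSE))
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
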