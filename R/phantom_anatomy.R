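#' Synthetic labeled anatomy for pipeline testing
#'
#' Builds a deterministic, axis-aligned labeled head phantom on an isotropic
#' grid in a +x=right / +y=anterior / +z=superior world frame. Structures
#' are simple boxes positioned to honour the anatomy the localizer relies
#' on: per hemisphere the LGN sits lateral and superior to the MGN, the
#' pulvinar superior and posterior to both, with mediodorsal nucleus,
#' putamen, pallidum, hippocampus, choroid plexus, insular and
#' parahippocampal white matter around them; auditory cortex (a BA 41/42
#' surrogate) on the lateral temporal surface, visual cortex (BA 17/18
#' surrogate) occipitally, a cortical grey-matter shell, interior white
#' matter, and a ventricular CSF block. Labels are pairwise disjoint;
#' `brain` is the in-brain mask.
#'
#' Default geniculus extents give 40-voxel nuclei at the default 48^3 grid,
#' matching typical functionally defined geniculate sizes at 2 mm
#' resolution.
#'
#' @param shape grid dimensions, each >= 32 (default c(48, 48, 48)).
#' @param seed integer seed (geometry is deterministic; kept for interface
#'   symmetry with the stochastic simulators).
#' @param voxel_mm isotropic voxel size in mm (default 2).
#' @param mgn_extent,lgn_extent integer voxel extents (x, y, z) of each
#'   geniculus box.
#' @return a `phantom_anatomy`: list with `labels` ([label_volume]),
#'   `brain` ([mask_volume]) and `shape`.
#' @export
make_phantom_anatomy <- function(shape = c(48, 48, 48), seed = 1,
                                 voxel_mm = 2,
                                 mgn_extent = c(4L, 5L, 2L),
                                 lgn_extent = c(5L, 4L, 2L)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("phantom grid must be at least 32 voxels on each axis",
         call. = FALSE)
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- -voxel_mm * (shape - 1) / 2

  # coordinates below are designed on a 48-unit frame and rescaled
  sc <- function(c48, n) pmin(pmax(round(c48 * n / 48), 1L), n)
  rng3 <- function(x1, x2, y1, y2, z1, z2)
    list(x = sc(x1, shape[1]):sc(x2, shape[1]),
         y = sc(y1, shape[2]):sc(y2, shape[2]),
         z = sc(z1, shape[3]):sc(z2, shape[3]))
  centred <- function(cx, cy, cz, ext) {
    ctr <- c(sc(cx, shape[1]), sc(cy, shape[2]), sc(cz, shape[3]))
    lo <- pmax(ctr - (ext - 1L) %/% 2L, 1L)
    hi <- pmin(lo + ext - 1L, shape)
    list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  }
  mirror <- function(b) { b$x <- sort(shape[1] + 1L - b$x); b }

  left <- list(
    mgn = centred(18.5, 22, 21.5, as.integer(mgn_extent)),
    lgn = centred(15, 22.5, 23.5, as.integer(lgn_extent)),
    pulvinar = rng3(15, 21, 16, 20, 25, 29),
    mediodorsal = rng3(19, 23, 25, 29, 25, 29),
    putamen = rng3(8, 11, 22, 30, 20, 26),
    pallidum = rng3(12, 13, 24, 28, 21, 25),
    hippocampus = rng3(10, 14, 14, 20, 16, 19),
    choroid_plexus = rng3(22, 24, 12, 15, 22, 26),
    insular_wm = rng3(6, 7, 20, 30, 18, 22),
    parahippocampal_wm = rng3(12, 16, 16, 20, 13, 15),
    ac = rng3(3, 7, 18, 30, 24, 30),
    vc = rng3(14, 23, 3, 8, 18, 28))

  hemi_names <- names(left)
  tab <- data.frame(id = integer(0), name = character(0),
                    stringsAsFactors = FALSE)
  lab <- array(0L, shape)
  next_id <- 0L
  paint <- function(box, name) {
    next_id <<- next_id + 1L
    tab <<- rbind(tab, data.frame(id = next_id, name = name,
                                  stringsAsFactors = FALSE))
    sub <- lab[box$x, box$y, box$z]
    sub[sub == 0L] <- next_id            # earlier labels take precedence
    lab[box$x, box$y, box$z] <<- sub
    invisible(NULL)
  }
  for (nm in hemi_names) paint(left[[nm]], paste0(nm, "_l"))
  for (nm in hemi_names) paint(mirror(left[[nm]]), paste0(nm, "_r"))

  paint(rng3(23, 26, 31, 38, 24, 30), "csf")

  # cortical GM shell: outer box minus interior, skipping labelled voxels
  outer_box <- rng3(4, 45, 4, 45, 4, 45)
  inner_box <- rng3(8, 41, 8, 41, 8, 41)
  shell <- array(FALSE, shape)
  shell[outer_box$x, outer_box$y, outer_box$z] <- TRUE
  shell[inner_box$x, inner_box$y, inner_box$z] <- FALSE
  next_id <- next_id + 1L
  tab <- rbind(tab, data.frame(id = next_id, name = "cortical_gm",
                               stringsAsFactors = FALSE))
  lab[shell & lab == 0L] <- next_id

  interior <- array(FALSE, shape)
  interior[inner_box$x, inner_box$y, inner_box$z] <- TRUE
  next_id <- next_id + 1L
  tab <- rbind(tab, data.frame(id = next_id, name = "wm",
                               stringsAsFactors = FALSE))
  lab[interior & lab == 0L] <- next_id

  brain <- array(FALSE, shape)
  bb <- rng3(3, 46, 3, 46, 3, 46)
  brain[bb$x, bb$y, bb$z] <- TRUE

  structure(list(labels = label_volume(lab, affine, tab),
                 brain = mask_volume(brain, affine),
                 shape = shape, voxel_mm = voxel_mm, seed = seed),
            class = "phantom_anatomy")
}

#' @export
print.phantom_anatomy <- function(x, ...) {
  cat("<phantom_anatomy> ", paste(x$shape, collapse = " x "), " grid, ",
      nrow(x$labels$label_table), " labels\n", sep = "")
  invisible(x)
}

# Names of grey-matter labels in the phantom parcellation.
phantom_gm_names <- function() {
  c("cortical_gm", "ac_l", "ac_r", "vc_l", "vc_r")
}
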