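# Brute-force oracles and shared fixtures. Oracles are deliberately naive
# (triple loops, lm-based residualization) and independent of the package's
# vectorized implementations.

bf_dilate_once <- function(a) {
  d <- dim(a)
  out <- array(FALSE, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!a[x, y, z]) next
    xs <- max(1, x - 1):min(d[1], x + 1)
    ys <- max(1, y - 1):min(d[2], y + 1)
    zs <- max(1, z - 1):min(d[3], z + 1)
    out[xs, ys, zs] <- TRUE
  }
  out
}

bf_erode_once <- function(a) {
  d <- dim(a)
  out <- array(FALSE, d)
  for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
    out[x, y, z] <- all(a[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1)])
  }
  out
}

# Partial correlation by explicit lm residualization.
bf_partial_cor <- function(x, y, Z = NULL) {
  if (is.null(Z)) {
    rx <- stats::resid(stats::lm(x ~ 1))
    ry <- stats::resid(stats::lm(y ~ 1))
  } else {
    rx <- stats::resid(stats::lm(x ~ Z))
    ry <- stats::resid(stats::lm(y ~ Z))
  }
  stats::cor(rx, ry)
}

random_mask <- function(shape, p = 0.2, seed = 1) {
  set.seed(seed)
  mask_volume(array(stats::runif(prod(shape)) < p, shape))
}

# Phantom datasets and pipeline runs reused across test files.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

small_anatomy <- function() cached("anat32", make_phantom_anatomy(c(32, 32, 32)))

default_anatomy <- function() cached("anat48", make_phantom_anatomy())

default_task_phantom <- function() cached("task48", {
  phantom_dataset(seed = 101, n_task_runs = 4, n_rest_runs = 0)
})

default_localize <- function() cached("froi48", {
  ds <- default_task_phantom()
  localize_froi(ds$task$runs, ds$task$schedules, ds$task$motion,
                ds$anatomy$labels, ds$anatomy$labels, ds$anatomy$brain)
})

phantom_roi_set <- function(anatomy) {
  lapply(c(mgn_left = "mgn_l", mgn_right = "mgn_r",
           lgn_left = "lgn_l", lgn_right = "lgn_r",
           ac_left = "ac_l", ac_right = "ac_r",
           vc_left = "vc_l", vc_right = "vc_r"),
         function(nm) label_mask(anatomy$labels, nm))
}
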