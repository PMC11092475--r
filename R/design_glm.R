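#' Build the sparse-acquisition design matrix
#'
#' One block of 19 named columns per run — intercept, auditory and visual
#' condition indicators (0/1 over the acquired volumes of each trial's
#' condition, unconvolved: sparse sampling at the response plateau precludes
#' an HRF model), 6 motion parameters and their squares, WM and CSF nuisance
#' series, and indicators for the second and third volume of each
#' acquisition cluster (absorbing T1-relaxation non-steady-state effects) —
#' assembled block-diagonally so each run's columns occupy only its rows.
#'
#' @param schedules list of per-run [build_run_schedule] results.
#' @param motion list of per-run motion tables (data.frame or matrix with 6
#'   columns, one row per acquired volume).
#' @param wm,csf lists of per-run nuisance series (numeric, one value per
#'   acquired volume).
#' @param centre_nuisance mean-centre WM/CSF within each run (default TRUE).
#' @return a `design_matrix`: list with `matrix`, `column_names`,
#'   `run_blocks` (per-run row index vectors) and `n_runs`.
#' @export
build_design_matrix <- function(schedules, motion, wm, csf,
                                centre_nuisance = TRUE) {
  n_runs <- length(schedules)
  stopifnot(n_runs >= 1, length(motion) == n_runs,
            length(wm) == n_runs, length(csf) == n_runs)
  per_run <- vector("list", n_runs)
  n_per_run <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    sch <- schedules[[r]]
    k <- ncol(sch$acquisition_times)
    n_vol <- length(sch$acquisition_times)
    mp <- as.matrix(motion[[r]])
    if (nrow(mp) != n_vol || ncol(mp) != 6L)
      stop("run ", r, ": motion table must be ", n_vol, " x 6", call. = FALSE)
    if (length(wm[[r]]) != n_vol || length(csf[[r]]) != n_vol)
      stop("run ", r, ": WM/CSF series length must match ", n_vol,
           " volumes", call. = FALSE)
    cond <- rep(sch$trials$condition, each = k)
    vic <- rep(seq_len(k), times = nrow(sch$trials))
    wmv <- as.numeric(wm[[r]]); csfv <- as.numeric(csf[[r]])
    if (centre_nuisance) {
      wmv <- wmv - mean(wmv); csfv <- csfv - mean(csfv)
    }
    X <- cbind(intercept = 1,
               auditory = as.numeric(cond == "auditory"),
               visual = as.numeric(cond == "visual"),
               mp,
               mp^2,
               wm = wmv,
               csf = csfv,
               cluster_vol2 = as.numeric(vic == 2L),
               cluster_vol3 = as.numeric(vic == 3L))
    colnames(X) <- paste0("run", r, "_",
                          c("intercept", "auditory", "visual",
                            paste0("mp", 1:6), paste0("mp", 1:6, "_sq"),
                            "wm", "csf", "cluster_vol2", "cluster_vol3"))
    per_run[[r]] <- X
    n_per_run[r] <- n_vol
  }
  total <- sum(n_per_run)
  p <- vapply(per_run, ncol, integer(1))
  M <- matrix(0, total, sum(p))
  cn <- character(sum(p))
  row0 <- 0L; col0 <- 0L
  run_blocks <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ri <- row0 + seq_len(n_per_run[r])
    ci <- col0 + seq_len(p[r])
    M[ri, ci] <- per_run[[r]]
    cn[ci] <- colnames(per_run[[r]])
    run_blocks[[r]] <- ri
    row0 <- row0 + n_per_run[r]; col0 <- col0 + p[r]
  }
  colnames(M) <- cn
  structure(list(matrix = M, column_names = cn, run_blocks = run_blocks,
                 n_runs = n_runs),
            class = "design_matrix")
}

#' Fit the voxelwise GLM
#'
#' Ordinary least squares per voxel within a mask.
#'
#' @param series a [vol_series] (or list of per-run `vol_series`, which are
#'   concatenated in time to match the design's run blocks).
#' @param design a [build_design_matrix] result.
#' @param mask a [mask_volume] restricting the fit.
#' @return a `beta_maps`: coefficients (regressors x in-mask voxels),
#'   residual variance, mask, and grid info.
#' @export
fit_glm <- function(series, design, mask) {
  if (inherits(series, "vol_series")) series <- list(series)
  Y <- do.call(rbind, lapply(series, function(s) {
    d <- dim(s$data)
    m <- matrix(s$data, nrow = prod(d[1:3]))
    t(m[as.vector(mask$data), , drop = FALSE])
  }))
  X <- design$matrix
  if (nrow(Y) != nrow(X))
    stop("series has ", nrow(Y), " volumes but design has ", nrow(X),
         " rows", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- design$column_names[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / max(1, nrow(X) - ncol(X))
  structure(list(coefficients = B, residual_variance = sigma2,
                 column_names = design$column_names, mask = mask,
                 n_runs = design$n_runs),
            class = "beta_maps")
}

#' Extract one beta map as a volume
#'
#' @param betas a [fit_glm] result.
#' @param name regressor column name.
#' @return a [vol_image]; voxels outside the fit mask are 0.
#' @export
beta_map <- function(betas, name) {
  i <- match(name, betas$column_names)
  if (is.na(i)) stop("no such regressor: ", name, call. = FALSE)
  out <- array(0, dim(betas$mask$data))
  out[betas$mask$data] <- betas$coefficients[i, ]
  vol_image(out, betas$mask$affine)
}

#' Auditory minus visual contrast
#'
#' Per-voxel auditory-beta minus visual-beta, averaged across runs.
#'
#' @param betas a [fit_glm] result.
#' @return a [vol_image] contrast map (0 outside the fit mask).
#' @export
contrast_auditory_minus_visual <- function(betas) {
  vals <- 0
  for (r in seq_len(betas$n_runs)) {
    ia <- match(paste0("run", r, "_auditory"), betas$column_names)
    iv <- match(paste0("run", r, "_visual"), betas$column_names)
    if (is.na(ia) || is.na(iv))
      stop("run ", r, " is missing auditory/visual columns", call. = FALSE)
    vals <- vals + (betas$coefficients[ia, ] - betas$coefficients[iv, ])
  }
  vals <- vals / betas$n_runs
  out <- array(0, dim(betas$mask$data))
  out[betas$mask$data] <- vals
  vol_image(out, betas$mask$affine)
}
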