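make_design_fixture <- function(n_runs = 1, seed = 5, tr = 0.85) {
  p <- timing_params(tr)
  schedules <- lapply(seq_len(n_runs), function(r)
    build_run_schedule(p, seed = seed + r))
  set.seed(seed)
  motion <- lapply(seq_len(n_runs), function(r)
    simulate_motion_and_eyes(51, tr, seed = seed + r)$motion)
  wm <- lapply(seq_len(n_runs), function(r) rnorm(51))
  csf <- lapply(seq_len(n_runs), function(r) rnorm(51))
  list(schedules = schedules, motion = motion, wm = wm, csf = csf,
       design = build_design_matrix(schedules, motion, wm, csf))
}

test_that("one run gives a 51 x 19 design with the documented column sums", {
  fx <- make_design_fixture()
  X <- fx$design$matrix
  expect_equal(dim(X), c(51L, 19L))
  expect_equal(sum(X[, "run1_auditory"]), 24)   # 8 trials x 3 volumes
  expect_equal(sum(X[, "run1_visual"]), 24)
  expect_equal(sum(X[, "run1_cluster_vol2"]), 17)  # one per trial incl. fixation
  expect_equal(sum(X[, "run1_cluster_vol3"]), 17)
  expect_equal(sum(X[, "run1_intercept"]), 51)
  # condition indicators never overlap and leave fixation as baseline
  expect_equal(max(X[, "run1_auditory"] + X[, "run1_visual"]), 1)
  # WM/CSF are mean-centred per run
  expect_lt(abs(sum(X[, "run1_wm"])), 1e-9)
})

test_that("multi-run designs are block diagonal", {
  fx <- make_design_fixture(n_runs = 3)
  X <- fx$design$matrix
  expect_equal(dim(X), c(153L, 57L))
  expect_equal(length(fx$design$run_blocks), 3)
  # run 2's columns are zero outside run 2's rows
  r2cols <- grepl("^run2_", colnames(X))
  expect_true(all(X[-fx$design$run_blocks[[2]], r2cols] == 0))
  expect_true(any(X[fx$design$run_blocks[[2]], r2cols] != 0))
  expect_error(build_design_matrix(fx$schedules, fx$motion[1:2],
                                   fx$wm, fx$csf))
  bad_motion <- fx$motion; bad_motion[[1]] <- bad_motion[[1]][1:10, ]
  expect_error(build_design_matrix(fx$schedules, bad_motion, fx$wm, fx$csf),
               "51 x 6")
})

test_that("rank-deficient designs are rejected with the offending columns", {
  fx <- make_design_fixture()
  des <- fx$design
  des$matrix <- cbind(des$matrix, dup = des$matrix[, "run1_auditory"])
  des$column_names <- c(des$column_names, "run1_auditory_dup")
  arr <- array(rnorm(4 * 4 * 4 * 51), c(4, 4, 4, 51))
  series <- vol_series(arr, diag(4), tr = 0.85)
  mask <- mask_volume(array(TRUE, c(4, 4, 4)))
  expect_error(fit_glm(series, des, mask), "rank deficient")
  expect_error(fit_glm(series, des, mask), "run1_auditory")
})

test_that("all-zero voxels get zero betas and residuals are orthogonal", {
  fx <- make_design_fixture()
  arr <- array(rnorm(3 * 3 * 3 * 51), c(3, 3, 3, 51))
  arr[1, 1, 1, ] <- 0
  series <- vol_series(arr, diag(4), tr = 0.85)
  mask <- mask_volume(array(TRUE, c(3, 3, 3)))
  betas <- fit_glm(series, fx$design, mask)
  expect_equal(unname(betas$coefficients[, 1]), rep(0, 19))
  # residuals orthogonal to every design column
  Y <- t(matrix(arr, nrow = 27))
  res <- Y - fx$design$matrix %*% betas$coefficients
  dots <- crossprod(fx$design$matrix, res)
  expect_lt(max(abs(dots)) / max(abs(Y)), 1e-8)
})

test_that("a constant added to one run moves only that run's intercept", {
  fx <- make_design_fixture(n_runs = 2)
  arr <- array(rnorm(3 * 3 * 3 * 102), c(3, 3, 3, 102))
  mask <- mask_volume(array(TRUE, c(3, 3, 3)))
  s1 <- vol_series(arr[, , , 1:51, drop = FALSE], diag(4), 0.85)
  s2 <- vol_series(arr[, , , 52:102, drop = FALSE], diag(4), 0.85)
  b0 <- fit_glm(list(s1, s2), fx$design, mask)
  s2_shift <- vol_series(s2$data + 5, diag(4), 0.85)
  b1 <- fit_glm(list(s1, s2_shift), fx$design, mask)
  delta <- b1$coefficients - b0$coefficients
  i2 <- match("run2_intercept", fx$design$column_names)
  expect_equal(unname(delta[i2, ]), rep(5, 27), tolerance = 1e-8)
  expect_lt(max(abs(delta[-i2, ])), 1e-8)
})

test_that("cluster-volume regressors absorb T1 decay bias", {
  an <- small_anatomy()
  sch <- build_run_schedule(timing_params(0.85), seed = 13)
  sim <- simulate_task_run(an, sch, task_effect_spec(noise_sd = 0), seed = 13)
  me <- simulate_motion_and_eyes(51, 0.85, seed = 13)
  set.seed(17)
  wm <- list(rnorm(51)); csf <- list(rnorm(51))
  full <- build_design_matrix(list(sch), list(me$motion), wm, csf)
  mgn <- label_mask(an$labels, "mgn_l")
  b_full <- fit_glm(sim$series, full, mgn)
  ia <- match("run1_auditory", full$column_names)
  expect_lt(max(abs(b_full$coefficients[ia, ] - 20)), 1e-6)

  # dropping the cluster-volume columns biases the condition betas
  drop <- full
  keep <- !grepl("cluster_vol", full$column_names)
  drop$matrix <- full$matrix[, keep]
  drop$column_names <- full$column_names[keep]
  b_drop <- fit_glm(sim$series, drop, mgn)
  ia2 <- match("run1_auditory", drop$column_names)
  expect_gt(max(abs(b_drop$coefficients[ia2, ] - 20)), 0.1)
})

test_that("the auditory-visual contrast has the planted signs", {
  an <- small_anatomy()
  sch <- build_run_schedule(timing_params(0.85), seed = 19)
  sim <- simulate_task_run(an, sch, task_effect_spec(noise_sd = 0), seed = 19)
  me <- simulate_motion_and_eyes(51, 0.85, seed = 19)
  set.seed(23)
  des <- build_design_matrix(list(sch), list(me$motion),
                             list(rnorm(51)), list(rnorm(51)))
  betas <- fit_glm(sim$series, des, an$brain)
  ctr <- contrast_auditory_minus_visual(betas)
  expect_true(all(ctr$data[label_mask(an$labels, "mgn_l")$data] > 0))
  expect_true(all(ctr$data[label_mask(an$labels, "lgn_l")$data] < 0))
  # equal planted amplitudes cancel
  spec_eq <- task_effect_spec(
    auditory_amplitudes = c(mgn_l = 15), visual_amplitudes = c(mgn_l = 15),
    noise_sd = 0)
  sim_eq <- simulate_task_run(an, sch, spec_eq, seed = 19)
  b_eq <- fit_glm(sim_eq$series, des, label_mask(an$labels, "mgn_l"))
  c_eq <- contrast_auditory_minus_visual(b_eq)
  expect_lt(max(abs(c_eq$data)), 1e-6)
})
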