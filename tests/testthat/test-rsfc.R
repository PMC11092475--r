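test_that("mode-1000 normalization rescales by the histogram mode", {
  d <- c(8, 8, 8)
  brain <- mask_volume(array(TRUE, d))
  const <- vol_series(array(500, c(d, 3)), diag(4), tr = 1)
  out <- mode1000_normalize(const, brain)
  expect_true(all(out$data == 1000))
  # scale invariance: scaling the input leaves the output unchanged
  set.seed(5)
  arr <- array(rexp(prod(d) * 4, rate = 1 / 800), c(d, 4))
  s <- vol_series(arr, diag(4), tr = 1)
  n1 <- mode1000_normalize(s, brain)
  n2 <- mode1000_normalize(vol_series(arr * 3.7, diag(4), 1), brain)
  expect_equal(n1$data, n2$data, tolerance = 1e-9)
  # bimodal fixture: the dominant mode wins
  bi <- array(0, c(d, 1))
  bi[, , , 1] <- c(rep(200, 100), rep(800, 412))
  mode_est <- estimate_brain_mode(vol_series(bi, diag(4), 1), brain)
  expect_equal(mode_est, 800, tolerance = 800 / 100)  # within one bin width
  neg <- vol_series(array(-5, c(d, 2)), diag(4), 1)
  expect_error(mode1000_normalize(neg, brain), "not positive")
})

test_that("detrending removes linear trends and centres the mean", {
  expect_equal(detrend_center(3 * seq_len(50) + 7), rep(0, 50),
               tolerance = 1e-10)
  expect_equal(detrend_center(rep(4.2, 30)), rep(0, 30), tolerance = 1e-12)
  set.seed(8)
  m <- matrix(rnorm(200), 50)
  dm <- detrend_center(m)
  tt <- seq_len(50)
  expect_lt(max(abs(colSums(dm))), 1e-9)
  expect_lt(max(abs(crossprod(tt - mean(tt), dm))), 1e-8)
  arr <- array(rnorm(4 * 4 * 4 * 20), c(4, 4, 4, 20))
  ds <- detrend_center(vol_series(arr, diag(4), 1))
  expect_lt(max(abs(apply(ds$data, 1:3, sum))), 1e-9)
})

test_that("eye-closure censoring follows the 3 s and 30 s rules", {
  tr <- 0.85
  cfg <- censor_config()
  # a 2 s closure is below the 3 s rule: nothing censored
  keep <- eye_closure_censor(data.frame(onset = 10, offset = 12), tr, 100, cfg)
  expect_true(all(keep))
  # a 4 s closure censors exactly the overlapping volumes
  keep <- eye_closure_censor(data.frame(onset = 10, offset = 14), tr, 100, cfg)
  vol_start <- (seq_len(100) - 1) * tr
  overlap <- vol_start + tr > 10 & vol_start < 14
  expect_equal(!keep, overlap)
  # two 4 s closures 20 s apart censor the gap too (20 < 30)
  cl <- data.frame(onset = c(10, 34), offset = c(14, 38))
  keep2 <- eye_closure_censor(cl, tr, 100, cfg)
  expect_equal(!keep2, vol_start + tr > 10 & vol_start < 38)
  # a sub-3 s closure does not arm the between-closure rule
  cl3 <- data.frame(onset = c(10, 34), offset = c(12, 38))
  keep3 <- eye_closure_censor(cl3, tr, 100, cfg)
  expect_equal(!keep3, vol_start + tr > 34 & vol_start < 38)
  expect_error(eye_closure_censor(data.frame(onset = 5, offset = 3), tr, 10,
                                  cfg), "malformed")
})

test_that("retention rules prune segments, runs, and participants", {
  tr <- 1
  cfg <- censor_config()
  # a 7 s island between censored stretches is discarded (7 < 8)
  keep <- rep(FALSE, 120); keep[10:16] <- TRUE; keep[30:119] <- TRUE
  out <- apply_retention_rules(list(keep), tr, cfg)
  expect_true(all(!out$masks[[1]][10:16]))
  expect_true(all(out$masks[[1]][30:119]))
  expect_equal(out$retained_seconds, 90)
  expect_true(out$run_kept)
  # a run retaining 80 s is dropped (80 < 90)
  keep80 <- rep(FALSE, 200); keep80[1:80] <- TRUE
  out80 <- apply_retention_rules(list(keep80), tr, cfg)
  expect_false(out80$run_kept)
  # two 140 s runs: runs kept but participant dropped (280 < 300)
  keep140 <- rep(TRUE, 140)
  out2 <- apply_retention_rules(list(keep140, keep140), tr, cfg)
  expect_true(all(out2$run_kept))
  expect_false(out2$participant_kept)
  # two 160 s runs pass every rule
  out3 <- apply_retention_rules(list(rep(TRUE, 160), rep(TRUE, 160)), tr, cfg)
  expect_true(out3$participant_kept)
  # one run alone fails the 2-run rule even with plenty of data
  out4 <- apply_retention_rules(list(rep(TRUE, 400)), tr, cfg)
  expect_false(out4$participant_kept)
})

test_that("band-pass filtering discards the documented edge volumes", {
  expect_equal(edge_discard_volumes(0.85), 26L)
  expect_equal(edge_discard_volumes(0.80), 28L)
  tr <- 0.85
  n <- 600
  tt <- (seq_len(n) - 1) * tr
  # in-band sinusoid (0.03 Hz) survives within 5%
  x <- sin(2 * pi * 0.03 * tt)
  bp <- bandpass_with_interpolation(x, NULL, tr)
  expect_equal(length(bp$data), n - 2 * 26)
  expect_gt(max(abs(bp$data)), 0.95)
  # out-of-band sinusoid (0.2 Hz) is attenuated below 10%
  y <- sin(2 * pi * 0.2 * tt)
  bpy <- bandpass_with_interpolation(y, NULL, tr)
  expect_lt(max(abs(bpy$data)), 0.10)
  # censored points are interpolated before filtering, dropped after
  keep <- rep(TRUE, n); keep[100:110] <- FALSE
  bpc <- bandpass_with_interpolation(x, keep, tr)
  expect_equal(length(bpc$data), n - 2 * 26 - 11)
  expect_false(any(bpc$retained_index %in% 100:110))
  expect_error(bandpass_with_interpolation(x, rep(FALSE, n), tr),
               "fewer than 2")
})

test_that("the RSFC nuisance matrix has 28 columns built in order", {
  tr <- 0.85
  n <- 200
  me <- simulate_motion_and_eyes(n, tr, seed = 3)
  set.seed(4)
  wm <- rnorm(n); csf <- rnorm(n)
  nuis <- build_rsfc_nuisance(me$motion, wm, csf, tr)
  expect_equal(ncol(nuis), 28)
  expect_equal(nrow(nuis), n)
  # constant motion column: filtered to zero, derivative zero
  mp0 <- me$motion; mp0[, 1] <- 5
  n0 <- build_rsfc_nuisance(mp0, wm, csf, tr)
  expect_lt(max(abs(n0[, "mp1_d"])), 1e-6)
  # squares are taken after filtering, not before
  mpf <- thalamoloc:::butter_bandpass(as.matrix(me$motion), tr)
  expect_equal(nuis[, "mp1_f_sq"], mpf[, 1]^2, tolerance = 1e-10,
               ignore_attr = TRUE)
  filtered_square <- thalamoloc:::butter_bandpass(as.matrix(me$motion)^2, tr)
  expect_gt(max(abs(nuis[, "mp1_f_sq"] - filtered_square[, 1])), 1e-4)
  # derivatives are backward differences with leading zero
  expect_equal(nuis[, "wm_d"], c(0, diff(wm)), ignore_attr = TRUE)
  expect_error(build_rsfc_nuisance(me$motion[, 1:5], wm, csf, tr),
               "6 columns")
})

test_that("ROI-pair estimates average four oracle partial correlations", {
  set.seed(9)
  n <- 80
  Z <- matrix(rnorm(n * 3), n)
  a <- rnorm(n); b <- 0.5 * a + rnorm(n)
  est <- roi_pair_connectivity(a, a, b, b, Z)
  expect_equal(unname(est$pairwise), rep(bf_partial_cor(a, b, Z), 4),
               tolerance = 1e-10)
  expect_equal(est$estimate, bf_partial_cor(a, b, Z), tolerance = 1e-10)
  sl <- rnorm(n); sr <- rnorm(n); tl <- rnorm(n); tr_ <- rnorm(n)
  est2 <- roi_pair_connectivity(sl, sr, tl, tr_, Z)
  oracle <- mean(c(bf_partial_cor(sl, tl, Z), bf_partial_cor(sl, tr_, Z),
                   bf_partial_cor(sr, tl, Z), bf_partial_cor(sr, tr_, Z)))
  expect_equal(est2$estimate, oracle, tolerance = 1e-10)
  expect_error(roi_pair_connectivity(rep(1, n), sr, tl, tr_, Z),
               "degenerate")
  # invariance to affine rescaling of series and nuisance
  est3 <- roi_pair_connectivity(2 * sl + 3, 5 * sr - 1, 0.1 * tl, tr_,
                                Z %*% diag(c(2, 0.5, 7)))
  expect_equal(est3$estimate, est2$estimate, tolerance = 1e-10)
})

test_that("selectivity tests compute one-tailed paired t with BH correction", {
  # identical paired columns: t = 0, one-tailed p = 0.5
  eq <- data.frame(mgn_ac = c(.3, .4, .5), mgn_vc = c(.3, .4, .5),
                   lgn_ac = c(.1, .2, .3), lgn_vc = c(.1, .2, .3))
  res <- selectivity_tests(eq)
  expect_equal(res$t[res$contrast == "mgn_ac_gt_mgn_vc"], 0)
  expect_equal(res$p[res$contrast == "mgn_ac_gt_mgn_vc"], 0.5)
  # planted mean difference 0.3, sd 0.1, n = 20: all four p < 0.001
  set.seed(12)
  base <- rnorm(20, 0.1, 0.05)
  tbl <- data.frame(mgn_ac = base + rnorm(20, 0.3, 0.1),
                    mgn_vc = base + rnorm(20, 0, 0.05),
                    lgn_ac = base + rnorm(20, 0, 0.05),
                    lgn_vc = base + rnorm(20, 0.3, 0.1))
  res2 <- selectivity_tests(tbl)
  expect_true(all(res2$p < 0.001))
  expect_true(all(res2$significant))
  # agreement with stats::t.test on non-degenerate data
  tt <- t.test(tbl$mgn_ac, tbl$mgn_vc, paired = TRUE,
               alternative = "greater")
  expect_equal(res2$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res2$p[1], tt$p.value, tolerance = 1e-12)
  expect_error(selectivity_tests(tbl[1, ]), "at least 2")
})

test_that("BH adjustment reproduces the hand-computed step-up decisions", {
  # step-up by hand for p = (.01,.02,.03,.04): adjusted all 0.04, all reject
  tbl <- data.frame(mgn_ac = 1:4, mgn_vc = 1:4, lgn_ac = 1:4, lgn_vc = 1:4)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.04, 0.3, 0.9), "BH"),
               c(0.04, 0.08, 0.4, 0.9))
})

test_that("seed connectivity maps average hemisphere maps voxelwise", {
  set.seed(14)
  d <- c(5, 1, 1); n <- 60
  seed_l <- rnorm(n); seed_r <- rnorm(n)
  arr <- array(rnorm(prod(d) * n), c(d, n))
  arr[1, 1, 1, ] <- seed_l              # seed copied into a voxel
  s <- vol_series(arr, diag(4), tr = 1)
  mask <- mask_volume(array(TRUE, d))
  m_l <- seed_connectivity_map(s, mask, seed_l, seed_l)
  expect_equal(m_l$data[1, 1, 1], 1, tolerance = 1e-12)
  # hemisphere averaging: map = (r_left + r_right) / 2 per voxel
  Z <- matrix(rnorm(n * 2), n)
  m2 <- seed_connectivity_map(s, mask, seed_l, seed_r, Z)
  Y <- t(matrix(arr, nrow = prod(d)))
  for (v in 1:5) {
    oracle <- (bf_partial_cor(seed_l, Y[, v], Z) +
                 bf_partial_cor(seed_r, Y[, v], Z)) / 2
    expect_equal(m2$data[v, 1, 1], oracle, tolerance = 1e-10)
  }
  expect_error(seed_connectivity_map(s, mask, rep(1, n), seed_r),
               "degenerate")
})

test_that("Dice coefficients follow the overlap formula", {
  d <- c(6, 6, 6)
  a <- mask_volume(array(FALSE, d)); a$data[1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- mask_volume(array(FALSE, d)); b$data[11:20] <- TRUE
  expect_equal(dice(a, b), 0)
  c5 <- mask_volume(array(FALSE, d)); c5$data[6:15] <- TRUE
  expect_equal(dice(a, c5), 0.5)   # |a|=|b|=10, overlap 5
  e <- mask_volume(array(FALSE, d))
  expect_warning(z <- dice(e, e), "empty")
  expect_equal(z, 0)
  wrong <- mask_volume(array(FALSE, c(5, 5, 5)))
  expect_error(dice(a, wrong), "different grids")
})
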