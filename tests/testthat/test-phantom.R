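test_that("phantom anatomy honours geniculate and pulvinar geometry", {
  an <- default_anatomy()
  tab <- an$labels$label_table
  needed <- c("mgn_l", "mgn_r", "lgn_l", "lgn_r", "pulvinar_l", "pulvinar_r",
              "mediodorsal_l", "mediodorsal_r", "putamen_l", "pallidum_l",
              "hippocampus_l", "choroid_plexus_l", "insular_wm_l",
              "parahippocampal_wm_l", "ac_l", "ac_r", "vc_l", "vc_r",
              "cortical_gm", "wm", "csf")
  expect_true(all(needed %in% tab$name))
  # labels are disjoint by construction of a single integer volume; every
  # labelled voxel is in-brain
  expect_true(all(an$brain$data[an$labels$data > 0]))

  for (h in c("l", "r")) {
    m <- thalamoloc:::mask_centroid_world(label_mask(an$labels, paste0("mgn_", h)))
    l <- thalamoloc:::mask_centroid_world(label_mask(an$labels, paste0("lgn_", h)))
    p <- thalamoloc:::mask_centroid_world(label_mask(an$labels, paste0("pulvinar_", h)))
    expect_gt(abs(l[1]), abs(m[1]))  # LGN lateral to MGN
    expect_gt(l[3], m[3])            # LGN superior to MGN
    expect_gt(p[3], max(l[3], m[3])) # pulvinar superior to both
    expect_lt(p[2], min(l[2], m[2])) # pulvinar posterior to both
  }
  expect_equal(sum(label_mask(an$labels, "mgn_l")$data), 40)
  expect_equal(sum(label_mask(an$labels, "lgn_l")$data), 40)

  expect_identical(make_phantom_anatomy(c(34, 34, 34), seed = 2)$labels$data,
                   make_phantom_anatomy(c(34, 34, 34), seed = 2)$labels$data)
  expect_error(make_phantom_anatomy(c(24, 24, 24)), "at least 32")
})

test_that("noise-free task runs vary only through T1 decay", {
  an <- small_anatomy()
  sch <- build_run_schedule(timing_params(0.85), seed = 3)
  spec <- task_effect_spec(auditory_amplitudes = c(),
                           visual_amplitudes = c(), noise_sd = 0)
  sim <- simulate_task_run(an, sch, spec, seed = 3)
  gm_idx <- which(an$labels$data == an$labels$label_table$id[
    an$labels$label_table$name == "cortical_gm"])[1]
  vox <- sim$series$data[gm_idx + prod(an$shape) * (0:50)]
  expect_equal(unique(round(vox, 9)),
               1000 * c(1, 0.97, 0.95))
  expect_identical(simulate_task_run(an, sch, spec, seed = 3)$series$data,
                   sim$series$data)
})

test_that("planted task amplitudes are recovered exactly without noise", {
  an <- small_anatomy()
  sch <- build_run_schedule(timing_params(0.85), seed = 7)
  sim <- simulate_task_run(an, sch, task_effect_spec(noise_sd = 0), seed = 7)
  me <- simulate_motion_and_eyes(51, 0.85, seed = 7)
  set.seed(11)
  des <- build_design_matrix(list(sch), list(me$motion),
                             list(rnorm(51)), list(rnorm(51)))
  betas <- fit_glm(sim$series, des, an$brain)
  aud <- beta_map(betas, "run1_auditory")
  vis <- beta_map(betas, "run1_visual")
  for (nm in c("ac_l", "ac_r"))
    expect_lt(max(abs(aud$data[label_mask(an$labels, nm)$data] - 30)), 1e-6)
  for (nm in c("mgn_l", "mgn_r"))
    expect_lt(max(abs(aud$data[label_mask(an$labels, nm)$data] - 20)), 1e-6)
  for (nm in c("lgn_l", "lgn_r"))
    expect_lt(max(abs(vis$data[label_mask(an$labels, nm)$data] - 20)), 1e-6)
})

test_that("rest runs plant the requested latent correlation structure", {
  spec <- rest_connectivity_spec(r_mgn_ac = 0.5, r_lgn_vc = 0.3,
                                 r_cross = 0.1)
  rng <- thalamoloc:::rng_stream(11, "rest")
  sig <- thalamoloc:::rest_latent_signals(rng, spec, 0.85, 600)
  expect_equal(cor(sig$mgn, sig$ac), 0.5, tolerance = 1e-10)
  expect_equal(cor(sig$lgn, sig$vc), 0.3, tolerance = 1e-10)
  expect_equal(cor(sig$mgn, sig$vc), 0.1, tolerance = 1e-10)
  expect_equal(cor(sig$lgn, sig$ac), 0.1, tolerance = 1e-10)

  an <- small_anatomy()
  sim1 <- simulate_rest_run(an, rest_connectivity_spec(), 0.85, 40, seed = 4)
  sim2 <- simulate_rest_run(an, rest_connectivity_spec(), 0.85, 40, seed = 4)
  expect_identical(sim1$series$data, sim2$series$data)
  expect_error(rest_connectivity_spec(r_mgn_ac = 1.2), "< 1")
  expect_error(simulate_rest_run(an, rest_connectivity_spec(), 0.85, 1),
               ">= 2")
})

test_that("motion traces and eye logs respect their options", {
  still <- simulate_motion_and_eyes(50, 0.85, seed = 1,
                                    translation_step_mm = 0,
                                    rotation_step_rad = 0)
  expect_true(all(as.matrix(still$motion) == 0))
  expect_equal(dim(still$motion), c(50L, 6L))

  given <- data.frame(onset = c(10, 60), offset = c(12, 64))
  me <- simulate_motion_and_eyes(200, 0.85, seed = 2, closures = given)
  expect_equal(me$eye_closures, given)
  expect_identical(simulate_motion_and_eyes(200, 0.85, seed = 2)$motion,
                   simulate_motion_and_eyes(200, 0.85, seed = 2)$motion)
})

test_that("cohort generator emits consistent participant series", {
  coh <- simulate_rest_cohort(3, n_volumes = 120, seed = 8)
  expect_length(coh, 3)
  for (p in coh) {
    expect_equal(dim(p$roi), c(120L, 8L))
    expect_length(p$wm, 120)
    expect_equal(dim(p$motion), c(120L, 6L))
  }
  coh2 <- simulate_rest_cohort(3, n_volumes = 120, seed = 8)
  expect_equal(coh, coh2)
})
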