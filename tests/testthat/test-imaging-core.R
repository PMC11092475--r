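test_that("NIfTI volumes round-trip with data, affine and TR intact", {
  arr <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-5, -6, -7)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol_image(arr, aff), f)
  back <- read_volume(f)
  expect_s3_class(back, "vol_image")
  expect_equal(back$data, arr, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$affine, aff, ignore_attr = TRUE)

  # 51 frames: one phantom task run, 17 trials x 3 cluster volumes
  arr4 <- array(rnorm(5 * 5 * 5 * 51), c(5, 5, 5, 51))
  f4 <- tempfile(fileext = ".nii.gz")
  write_volume(vol_series(arr4, aff, tr = 0.85), f4)
  back4 <- read_volume(f4)
  expect_s3_class(back4, "vol_series")
  expect_equal(dim(back4$data)[4], 51)
  expect_equal(back4$tr, 0.85, tolerance = 1e-6)
})

test_that("non-NIfTI and missing files are rejected", {
  txt <- tempfile(fileext = ".nii")
  writeLines("not a nifti", txt)
  suppressWarnings(expect_error(read_volume(txt)))
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("dilation follows the 26-neighbourhood brute-force oracle", {
  m <- mask_volume(array(FALSE, c(9, 9, 9)))
  expect_equal(sum(dilate_mask(m, 5)$data), 0)
  m$data[5, 5, 5] <- TRUE
  expect_equal(sum(dilate_mask(m, 0)$data), 1)
  expect_equal(sum(dilate_mask(m, 1)$data), 27)
  expect_equal(sum(dilate_mask(m, 2)$data), 125)
  rm1 <- random_mask(c(8, 9, 7), p = 0.15, seed = 4)
  expect_equal(dilate_mask(rm1, 1)$data, bf_dilate_once(rm1$data))
  # extensivity: dilation never removes voxels
  expect_true(all(dilate_mask(rm1, 2)$data[rm1$data]))
})

test_that("compartment erosion stops before dropping below two voxels", {
  a <- array(FALSE, c(13, 13, 13)); a[3:11, 3:11, 3:11] <- TRUE
  out <- erode_compartment_mask(mask_volume(a))
  expect_equal(sum(out$data), 27)  # 9^3 -> 7^3 -> 5^3 -> 3^3
  oracle <- bf_erode_once(bf_erode_once(bf_erode_once(a)))
  expect_equal(out$data, oracle)

  b <- array(FALSE, c(7, 7, 7)); b[3:5, 3:5, 3:5] <- TRUE
  out3 <- erode_compartment_mask(mask_volume(b))
  expect_equal(out3$data, b)  # first erosion would leave 1 < 2 voxels
  expect_equal(sum(erode_compartment_mask(
    mask_volume(array(FALSE, c(5, 5, 5))))$data), 0)

  rm1 <- dilate_mask(random_mask(c(10, 10, 10), p = 0.1, seed = 9), 1)
  expect_equal(erode_mask(rm1, 1)$data, bf_erode_once(rm1$data))
  out <- erode_compartment_mask(rm1)
  expect_true(all(rm1$data[out$data]))           # output subset of input
  expect_true(sum(out$data) >= 2 || identical(out$data, rm1$data))
})

test_that("connected components partition the mask in size order", {
  a <- array(FALSE, c(12, 12, 12))
  a[2:3, 2:3, 2:4] <- TRUE       # 12 voxels
  a[8:9, 8, 8] <- TRUE; a[8, 9, 8] <- TRUE
  a[8, 8, 9] <- TRUE; a[9, 9, 8] <- TRUE  # 5 voxels, 18-connected
  comps <- connected_components(mask_volume(a))
  expect_length(comps, 2)
  expect_equal(sum(comps[[1]]$data), 12)
  expect_equal(sum(comps[[2]]$data), 5)

  single <- mask_volume(array(FALSE, c(4, 4, 4))); single$data[2, 2, 2] <- TRUE
  expect_length(connected_components(single), 1)
  expect_length(connected_components(mask_volume(array(FALSE, c(4, 4, 4)))), 0)

  rm1 <- random_mask(c(10, 11, 9), p = 0.25, seed = 7)
  comps <- connected_components(rm1)
  un <- Reduce(`|`, lapply(comps, `[[`, "data"))
  expect_equal(un, rm1$data)                       # union = mask
  expect_equal(sum(vapply(comps, function(m) sum(m$data), numeric(1))),
               sum(rm1$data))                      # pairwise disjoint
  # corner-only contact is not 18-connected
  c2 <- array(FALSE, c(4, 4, 4)); c2[1, 1, 1] <- TRUE; c2[2, 2, 2] <- TRUE
  expect_length(connected_components(mask_volume(c2)), 2)
  expect_length(connected_components(mask_volume(c2), connectivity = 26), 1)
})

test_that("nearest-neighbour label resampling maps grids through world space", {
  tab <- data.frame(id = 1:2, name = c("a", "b"))
  lab <- array(0L, c(8, 8, 8)); lab[1:4, , ] <- 1L; lab[5:8, , ] <- 2L
  lv <- label_volume(lab, diag(4), tab)
  same <- resample_labels_nearest(lv, vol_image(array(0, c(8, 8, 8)), diag(4)))
  expect_equal(same$data, lv$data)
  expect_equal(resample_labels_nearest(same,
    vol_image(array(0, c(8, 8, 8)), diag(4)))$data, same$data)  # idempotent

  # 1 mm block-constant labels onto a 2 mm grid: blocks survive
  aff1 <- diag(4)
  lab1 <- array(0L, c(8, 8, 8)); lab1[1:4, , ] <- 1L; lab1[5:8, , ] <- 2L
  src <- label_volume(lab1, aff1, tab)
  aff2 <- diag(c(2, 2, 2, 1))
  tgt <- vol_image(array(0, c(4, 4, 4)), aff2)
  out <- resample_labels_nearest(src, tgt)
  expect_equal(unique(as.vector(out$data[1:2, , ])), 1L)
  expect_equal(unique(as.vector(out$data[3:4, , ])), 2L)
  expect_equal(out$label_table, tab)

  # label fully outside the target field of view disappears
  aff_far <- diag(4); aff_far[1, 4] <- 100
  far <- vol_image(array(0, c(4, 4, 4)), aff_far)
  expect_equal(sum(resample_labels_nearest(src, far)$data), 0)
})

test_that("label volumes validate their label table", {
  expect_error(label_volume(array(3L, c(2, 2, 2)), diag(4),
                            data.frame(id = 1, name = "a")),
               "absent from label_table")
  lm <- label_mask(label_volume(array(1L, c(2, 2, 2)), diag(4),
                                data.frame(id = 1, name = "a")), "a")
  expect_equal(sum(lm$data), 8)
})
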