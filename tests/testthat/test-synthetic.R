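test_that("phantom anatomy partitions GM into the requested contiguous labels", {
  anat <- make_phantom_anatomy(c(20, 20, 10), n_rois = 8, seed = 1)
  labs <- anat$parcellation$labels
  expect_identical(sort(unique(as.vector(labs))), c(0L, 1:8))
  # labels live exactly on GM
  expect_true(all((labs > 0) == anat$tissue_masks$gm))
  # each parcel is one connected component under 6-connectivity
  for (k in 1:8) {
    comp <- mefc:::label_components(labs == k, scheme = 6)
    expect_equal(max(comp), 1L)
  }
  # tissue compartments are disjoint and inside the brain
  tm <- anat$tissue_masks
  expect_false(any(tm$gm & tm$wm) || any(tm$gm & tm$csf) || any(tm$wm & tm$csf))
  expect_true(all((tm$gm | tm$wm | tm$csf) == tm$brain))
})

test_that("anatomy generation is deterministic and T2* stays in range", {
  a1 <- make_phantom_anatomy(c(20, 20, 10), n_rois = 8, seed = 1)
  a2 <- make_phantom_anatomy(c(20, 20, 10), n_rois = 8, seed = 1)
  expect_identical(a1, a2)
  a3 <- make_phantom_anatomy(c(20, 20, 10), n_rois = 8, seed = 2)
  expect_false(identical(a1$ground_truth$t2s_map, a3$ground_truth$t2s_map))
  t2_gm <- a1$ground_truth$t2s_map[a1$tissue_masks$gm]
  expect_true(all(t2_gm >= 15 & t2_gm <= 60))
  expect_true(all(a1$ground_truth$t2s_map[a1$tissue_masks$brain] > 0))
})

test_that("a grid too small to host the parcels is rejected", {
  expect_error(make_phantom_anatomy(c(8, 8, 4), n_rois = 5000, seed = 1),
               "too small")
  expect_error(make_phantom_anatomy(c(4, 4, 2), n_rois = 2, seed = 1), ">=")
})

test_that("simulated sessions have one array per echo and obey the decay model", {
  anat <- tiny_anatomy()
  ses <- simulate_session(anat, mbme_acquisition(n_volumes = 40), seed = 2)
  expect_length(ses$me$data, 3)
  dims <- unique(lapply(ses$me$data, dim))
  expect_length(dims, 1)
  expect_identical(dims[[1]][4], 40L)
  expect_identical(dim(ses$motion), c(40L, 6L))

  # noiseless, nuisance-free: mean echo ratio is exp(-(TE2-TE1)/T2*)
  ses0 <- simulate_session(anat, mbme_acquisition(n_volumes = 40), seed = 2,
                           bold_amplitude = 0, noise_sd = 0,
                           drift_on = FALSE, physio_on = FALSE)
  m1 <- apply(ses0$me$data[[1]], 1:3, mean)
  m2 <- apply(ses0$me$data[[2]], 1:3, mean)
  brain <- anat$tissue_masks$brain
  expect_lt(max(abs(m2[brain] / m1[brain] -
                      exp(-(30 - 11) / anat$ground_truth$t2s_map[brain]))), 1e-6)
})

test_that("session generation is seed-deterministic and rejects bad correlation targets", {
  anat <- tiny_anatomy()
  acq <- mbme_acquisition(n_volumes = 30)
  s1 <- simulate_session(anat, acq, seed = 5)
  s2 <- simulate_session(anat, acq, seed = 5)
  expect_identical(s1, s2)
  bad <- matrix(c(1, 2, 2, 1), 2)  # corr 2: not PSD
  anat2 <- make_phantom_anatomy(c(12, 12, 6), n_rois = 2, seed = 1)
  expect_error(simulate_session(anat2, acq, network_corr = bad),
               "positive semi-definite")
  expect_error(simulate_session(anat2, acq, network_corr = matrix(c(1, .2, .3, 1), 2)),
               "symmetric")
})

test_that("planted latent correlation is recovered empirically at 400 volumes", {
  C <- matrix(c(1, 0.7, 0.7, 1), 2)
  anat <- make_phantom_anatomy(c(12, 12, 6), n_rois = 2, seed = 1)
  ses <- simulate_session(anat, mbme_acquisition(n_volumes = 400),
                          network_corr = C, seed = 3, noise_sd = 0,
                          drift_on = FALSE, physio_on = FALSE,
                          bold_amplitude = 0.05)
  expect_lt(abs(cor(ses$latents)[1, 2] - 0.7), 0.1)
  # and in the mean BOLD-effect time courses of the two regions
  b <- combine_echoes(ses$me, fit_t2star(ses$me))
  p <- anat$parcellation
  roi_ts <- sapply(1:2, function(k) {
    rowMeans(mefc:::series_matrix(b, mask = p$labels == k & b$mask))
  })
  expect_lt(abs(cor(roi_ts)[1, 2] - 0.7), 0.1)
})

test_that("study assembly matches the two-visit design", {
  d <- study_design(29, 18)
  expect_equal(length(unique(d$session_id)), 47)
  d0 <- study_design(5, 0)
  expect_equal(length(unique(d0$session_id)), 5)
  expect_true(all(table(d0$subject) == 2))  # MB + MBME rows only
  expect_error(study_design(3, 4), "exceeds")

  st <- make_study(n_subjects = 3, n_repeat = 2, scale = 0.05, seed = 4,
                   shape = c(12, 12, 6), n_rois = 4)
  expect_length(st$sessions, 5)
  expect_named(st$sessions$sub01_tp1, c("subject", "timepoint", "MB", "MBME"),
               ignore.order = TRUE)
  expect_equal(st$sessions$sub01_tp1$MB$me$te_ms, 30)
  expect_equal(st$sessions$sub01_tp1$MBME$me$te_ms, c(11, 30, 49))
  st2 <- make_study(n_subjects = 3, n_repeat = 2, scale = 0.05, seed = 4,
                    shape = c(12, 12, 6), n_rois = 4)
  expect_identical(st, st2)
})

test_that("session_stability = 1 reproduces timepoint-1 latents exactly", {
  st <- make_study(n_subjects = 2, n_repeat = 1, scale = 0.05, seed = 9,
                   shape = c(12, 12, 6), n_rois = 4, session_stability = 1)
  expect_equal(st$sessions$sub01_tp1$MBME$latents,
               st$sessions$sub01_tp2$MBME$latents, tolerance = 1e-12)
  expect_equal(st$sessions$sub01_tp1$MB$latents,
               st$sessions$sub01_tp2$MB$latents, tolerance = 1e-12)
})

test_that("the FCD fixture realises its constructed expectations", {
  blocks <- list(rbind(c(2, 2, 1), c(3, 2, 1), c(2, 3, 1), c(3, 3, 1)))
  tc <- make_fcd_testcase(c(6, 6, 1), blocks, n_volumes = 200, seed = 1)
  expect_equal(unique(tc$expected_lfcd[blocks[[1]]]), 4L)
  expect_equal(unique(tc$expected_gfcd[blocks[[1]]]), 3L)
  bg <- tc$expected_lfcd
  bg[blocks[[1]]] <- NA
  expect_true(all(bg == 1L, na.rm = TRUE))
  expect_error(
    make_fcd_testcase(c(6, 6, 1), list(rbind(c(1, 1, 1)), rbind(c(1, 1, 1)))),
    "overlap")
})

test_that("a spatially split block yields component-wise lFCD but block-wide gFCD", {
  blocks <- list(rbind(c(1, 1, 1), c(2, 1, 1), c(5, 5, 1)))  # 2-voxel + 1-voxel parts
  tc <- make_fcd_testcase(c(6, 6, 1), blocks, n_volumes = 200, seed = 2)
  expect_equal(tc$expected_lfcd[1, 1, 1], 2L)
  expect_equal(tc$expected_lfcd[5, 5, 1], 1L)
  expect_equal(tc$expected_gfcd[5, 5, 1], 2L)  # correlated with both remote voxels
})
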