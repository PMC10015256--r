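make_decay_series <- function(s0, t2s, te = c(11, 30, 49), shape = c(3, 3, 2),
                              n_t = 5) {
  data <- lapply(te, function(x) array(s0 * exp(-x / t2s), c(shape, n_t)))
  multi_echo_series(data, te_ms = te, tr_ms = 900)
}

test_that("log-linear fit inverts a noiseless mono-exponential exactly", {
  me <- make_decay_series(100, 40)
  fit <- fit_t2star(me)
  expect_lt(max(abs(fit$t2s_map - 40)), 1e-6)
  expect_lt(max(abs(fit$s0_map - 100)), 1e-6)
  expect_true(all(fit$valid_mask))
  # per-volume fitting agrees on stationary data
  fit_pv <- fit_t2star(me, use_mean_over_time = FALSE)
  expect_equal(fit_pv$t2s_map, fit$t2s_map, tolerance = 1e-8)
})

test_that("non-decaying and degenerate voxels hit the documented clamps", {
  me <- make_decay_series(100, 40)
  for (e in seq_along(me$data)) {
    me$data[[e]][1, 1, 1, ] <- 50   # flat across TE: zero slope
    me$data[[e]][2, 1, 1, ] <- -1   # no positive samples at any echo
  }
  fit <- fit_t2star(me)
  expect_equal(fit$t2s_map[1, 1, 1], 300)           # zero slope -> upper clamp
  expect_equal(fit$t2s_map[2, 1, 1], 300)           # < 2 positive samples
  expect_false(fit$valid_mask[2, 1, 1])
  expect_true(fit$valid_mask[1, 1, 1])
  expect_error(fit_t2star(multi_echo_series(list(me$data[[1]]), 30, 650)),
               "single-echo")
})

test_that("T2* is recovered from noisy phantoms to within 2 ms median error", {
  anat <- tiny_anatomy()
  # per-voxel SNR ~ 100 at the middle echo
  gt <- anat$ground_truth
  gm <- anat$tissue_masks$gm
  mid_sig <- median(gt$s0_map[gm] * exp(-30 / gt$t2s_map[gm]))
  ses <- simulate_session(anat, mbme_acquisition(n_volumes = 100), seed = 1,
                          noise_sd = mid_sig / 100, bold_amplitude = 0,
                          drift_on = FALSE, physio_on = FALSE)
  fit <- fit_t2star(ses$me)
  err <- abs(fit$t2s_map[gm] - gt$t2s_map[gm])
  expect_lt(median(err), 2)
})

test_that("T2*-weighted combination uses the normalised TE-weighted formula", {
  # w_i = TE_i exp(-TE_i / 40), normalised: frozen by direct evaluation
  w_raw <- c(11, 30, 49) * exp(-c(11, 30, 49) / 40)
  w_ref <- w_raw / sum(w_raw)
  expect_equal(round(w_ref, 4), c(0.2263, 0.3838, 0.3899))

  me <- make_decay_series(100, 40)
  fit <- fit_t2star(me)
  W <- echo_weights(me$te_ms, fit$t2s_map)
  for (e in 1:3) expect_equal(unique(round(as.vector(W[[e]]), 10)),
                              round(w_ref[e], 10))
  tot <- Reduce(`+`, W)
  expect_lt(max(abs(tot - 1)), 1e-12)

  b <- combine_echoes(me, fit)
  expect_equal(b$data[1, 1, 1, 1], sum(w_ref * 100 * exp(-c(11, 30, 49) / 40)),
               tolerance = 1e-8)
  expect_identical(dim(b$data)[4], dim(me$data[[1]])[4])
  expect_identical(b$mask, me$mask)
  expect_length(b$df_ledger, 0)
})

test_that("summation combines by plain voxelwise sum and passes single echoes through", {
  me <- make_decay_series(100, 40)
  b <- combine_echoes(me, scheme = "summation")
  expect_equal(b$data[2, 2, 1, 3], sum(100 * exp(-c(11, 30, 49) / 40)))
  one <- multi_echo_series(list(me$data[[2]]), te_ms = 30, tr_ms = 650)
  b1 <- combine_echoes(one, scheme = "summation")
  expect_identical(b1$data, me$data[[2]])
  # alias scheme equals the weighted scheme
  fit <- fit_t2star(me)
  expect_equal(combine_echoes(me, fit, "normalized_t2star")$data,
               combine_echoes(me, fit, "t2star_weighted")$data)
})

test_that("combination neither mutates the echoes nor perturbs a T2* refit", {
  anat <- tiny_anatomy()
  ses <- simulate_session(anat, mbme_acquisition(n_volumes = 20), seed = 1,
                          bold_amplitude = 0, noise_sd = 0,
                          drift_on = FALSE, physio_on = FALSE)
  fit1 <- fit_t2star(ses$me)
  before <- ses$me$data
  b <- combine_echoes(ses$me, fit1)
  expect_identical(ses$me$data, before)
  fit2 <- fit_t2star(ses$me)
  brain <- anat$tissue_masks$brain
  expect_lt(max(abs(fit2$t2s_map[brain] - fit1$t2s_map[brain])), 1e-6)
  expect_identical(dim(b$data)[4], 20L)
})

test_that("tsnr follows the mean-over-sample-SD definition with sqrt(NTP) scaling", {
  x <- rep(c(99, 101), 10)  # n = 20
  arr <- array(0, c(2, 1, 1, 20))
  arr[1, 1, 1, ] <- x
  arr[2, 1, 1, ] <- 7  # constant: zero SD
  b <- bold_series(arr, tr_ms = 900)
  m <- tsnr(b)
  expect_equal(m[1, 1, 1], 100 / sqrt(20 / 19), tolerance = 1e-10)
  expect_equal(round(m[1, 1, 1], 5), 97.46794)
  expect_true(is.na(m[2, 1, 1]))
  b400 <- bold_series(array(rnorm(400) + 100, c(1, 1, 1, 400)), 900)
  expect_equal(tsnr(b400, scale_by_sqrt_ntp = TRUE), 20 * tsnr(b400))
  expect_error(tsnr(bold_series(array(1, c(1, 1, 1, 2)), 900)), ">= 3")
})

test_that("T2*-weighted combination does not lose tSNR relative to the middle echo", {
  for (s in 1:5) {
    anat <- make_phantom_anatomy(c(12, 12, 6), n_rois = 4, seed = s)
    ses <- simulate_session(anat, mbme_acquisition(n_volumes = 80),
                            seed = s + 10, bold_amplitude = 0.03)
    comb <- combine_echoes(ses$me, fit_t2star(ses$me))
    mid <- bold_series(ses$me$data[[2]], tr_ms = 900, mask = ses$me$mask,
                       affine = ses$me$affine)
    gm <- anat$tissue_masks$gm
    expect_gte(mean(tsnr(comb)[gm], na.rm = TRUE),
               mean(tsnr(mid)[gm], na.rm = TRUE))
  }
})
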