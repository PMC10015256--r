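const_bold <- function(n_t, tr_ms = 900, shape = c(4, 4, 2), value = 100) {
  bold_series(array(value, c(shape, n_t)), tr_ms = tr_ms)
}

test_that("initial discard drops ceil(seconds / TR) volumes", {
  expect_equal(dim(discard_initial(const_bold(400, 900))$data)[4], 388L)
  expect_equal(dim(discard_initial(const_bold(554, 650))$data)[4], 538L)
  expect_equal(dim(discard_initial(const_bold(40, 1000))$data)[4], 30L)
  expect_error(discard_initial(const_bold(15, 900)), "too short")
})

test_that("nuisance designs count df as regressors plus detrend order", {
  mo12 <- matrix(rnorm(100 * 12), 100)
  tiss <- matrix(rnorm(100 * 2), 100)
  d <- build_design(nuisance_set(motion = mo12, tissue_signals = tiss,
                                 detrend_order = 3), 100)
  expect_equal(d$df_loss, 17L)
  expect_equal(ncol(d$X), 18L)  # + constant, excluded from the count

  mo6 <- mo12[, 1:6]
  expect_equal(build_design(nuisance_set(motion = mo6, tissue_signals = tiss,
                                         detrend_order = 3), 100)$df_loss, 11L)
  expect_equal(build_design(nuisance_set(detrend_order = 0), 100)$df_loss, 0L)
  expect_equal(ncol(motion_derivatives(mo6)), 12L)
  expect_warning(build_design(nuisance_set(motion = cbind(mo6, mo6[, 1]),
                                           detrend_order = 0), 100),
                 "rank deficient")
})

test_that("nuisance regression removes exactly the spanned signal", {
  withr::with_seed(1, {
    n_t <- 60
    arr <- array(rnorm(4 * 4 * 2 * n_t), c(4, 4, 2, n_t))
    b <- bold_series(arr, tr_ms = 900)
    own <- b$data[1, 1, 1, ]
    des <- list(X = cbind(1, own), df_loss = 1L)
    out <- regress_nuisance(b, des)
    expect_lt(var(out$data[1, 1, 1, ]), 1e-20)          # self-regression
    expect_equal(mean(out$data[1, 1, 1, ]), mean(own))  # mean restored
    expect_equal(df_total(out), 1L)

    # orthogonal regressor leaves a voxel unchanged up to mean restoration
    y <- b$data[2, 1, 1, ]
    ortho <- residuals(lm(rnorm(n_t) ~ y))  # orthogonal to y and the constant
    out2 <- regress_nuisance(b, list(X = cbind(1, ortho), df_loss = 1L))
    expect_lt(max(abs(out2$data[2, 1, 1, ] - y)), 1e-10)
  })
})

test_that("third-order detrending annihilates cubic drift", {
  withr::with_seed(2, {
    n_t <- 80
    x <- seq(-1, 1, length.out = n_t)
    drift <- 5 * x^3
    arr <- array(rnorm(8 * n_t), c(2, 2, 2, n_t))
    for (i in 1:2) for (j in 1:2) for (k in 1:2) {
      arr[i, j, k, ] <- arr[i, j, k, ] + drift
    }
    b <- bold_series(arr, tr_ms = 900)
    des <- build_design(nuisance_set(detrend_order = 3), n_t)
    out <- regress_nuisance(b, des)
    for (i in 1:2) {
      r <- out$data[i, 1, 1, ]
      # residual projection onto the drift direction is numerically zero
      expect_lt(abs(sum((r - mean(r)) * drift)) / sqrt(sum(drift^2)), 1e-8)
      expect_lt(abs(cor(r, x^3)), 1e-10)
    }
  })
})

test_that("the ideal bandpass keeps the pass band and kills the stop band", {
  n <- 388
  tt <- (0:(n - 1)) * 0.9
  stopb <- sin(2 * pi * 0.2 * tt)
  passb <- sin(2 * pi * 0.05 * tt)
  arr <- array(0, c(3, 1, 1, n))
  arr[1, 1, 1, ] <- stopb
  arr[2, 1, 1, ] <- passb
  arr[3, 1, 1, ] <- 42
  bp <- bandpass(bold_series(arr, tr_ms = 900))
  expect_lt(sum(bp$data[1, 1, 1, ]^2) / sum(stopb^2), 0.01)
  expect_gt(sum(bp$data[2, 1, 1, ]^2) / sum(passb^2), 0.99)
  expect_equal(bp$data[3, 1, 1, ], rep(42, n))  # DC preserved as the mean
  expect_error(bandpass(bold_series(arr, tr_ms = 900), f_hi = 0.6), "Nyquist")
})

test_that("Gaussian smoothing preserves constants in-mask and fwhm 0 is the identity", {
  withr::with_seed(3, {
    shape <- c(8, 8, 4)
    mask <- array(FALSE, shape)
    mask[2:7, 2:7, 2:3] <- TRUE
    arr <- array(rnorm(prod(shape) * 4), c(shape, 4))
    b <- bold_series(arr, tr_ms = 900, mask = mask)
    expect_identical(smooth_gaussian(b, 0)$data, b$data)

    const <- b
    const$data[] <- 0
    const$data[, , , 1][mask] <- 5
    const$data[, , , 2][mask] <- 5
    const$data[, , , 3][mask] <- 5
    const$data[, , , 4][mask] <- 5
    sm <- smooth_gaussian(const, 4)
    expect_lt(max(abs(sm$data[, , , 1][mask] - 5)), 1e-10)
  })
})

test_that("voxels outside the mask never influence in-mask results", {
  withr::with_seed(4, {
    shape <- c(8, 8, 4)
    mask <- array(FALSE, shape)
    mask[3:6, 3:6, 2:3] <- TRUE
    arr <- array(rnorm(prod(shape) * 30), c(shape, 30))
    b1 <- bold_series(arr, tr_ms = 900, mask = mask)
    arr2 <- arr
    arr2[rep(!mask, 30)] <- 1e6 * rnorm(sum(!mask) * 30)  # corrupt outside
    b2 <- bold_series(array(arr2, dim(arr)), tr_ms = 900, mask = mask)
    s1 <- smooth_gaussian(b1, 4)
    s2 <- smooth_gaussian(b2, 4)
    expect_equal(s1$data[, , , 5][mask], s2$data[, , , 5][mask], tolerance = 1e-10)
    f1 <- bandpass(b1)
    f2 <- bandpass(b2)
    expect_equal(f1$data[, , , 5][mask], f2$data[, , , 5][mask], tolerance = 1e-10)
  })
})

test_that("regression and bandpass are idempotent on a second pass", {
  withr::with_seed(5, {
    n_t <- 64
    arr <- array(rnorm(4 * 4 * 2 * n_t), c(4, 4, 2, n_t))
    b <- bold_series(arr, tr_ms = 900)
    des <- build_design(nuisance_set(motion = matrix(rnorm(n_t * 6), n_t),
                                     detrend_order = 3), n_t)
    r1 <- regress_nuisance(b, des)
    r2 <- regress_nuisance(r1, des)
    expect_lt(max(abs(r2$data - r1$data)) / max(abs(r1$data)), 1e-6)
    p1 <- bandpass(b)
    p2 <- bandpass(p1)
    expect_lt(max(abs(p2$data - p1$data)) / max(abs(p1$data)), 1e-6)
  })
})

test_that("the standard chain reports the printed df arithmetic", {
  anat <- tiny_anatomy()
  ses <- simulate_session(anat, mbme_acquisition(n_volumes = 60), seed = 1)
  b <- combine_echoes(ses$me, fit_t2star(ses$me))
  den <- standard_denoise(b, motion = ses$motion, wm = anat$tissue_masks$wm,
                          csf = anat$tissue_masks$csf)
  expect_equal(df_total(den), 17L)
  expect_equal(dim(den$data)[4], 60L - 12L)
  den6 <- standard_denoise(combine_echoes(ses$me, fit_t2star(ses$me)),
                           motion = ses$motion, wm = anat$tissue_masks$wm,
                           csf = anat$tissue_masks$csf, motion_params = 6)
  expect_equal(df_total(den6), 11L)
})
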