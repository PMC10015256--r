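#' Voxelwise T2*/S0 estimation by log-linear fit
#'
#' Per voxel, ordinary least squares of log(signal) on echo time: the slope is
#' -1/T2* and the intercept log(S0). By default the fit uses the temporal mean
#' signal at each echo; with `use_mean_over_time = FALSE` the fit is done per
#' volume and the fitted coefficients averaged over volumes. T2* is clamped to
#' `[t2s_min, t2s_max]`; non-decaying voxels (slope >= 0) hit the upper clamp.
#' Voxels with fewer than two positive samples are marked invalid and assigned
#' `t2s_max`.
#'
#' @param me A [multi_echo_series()] with >= 2 echoes.
#' @param use_mean_over_time Fit on temporal means (default) or per volume.
#' @param t2s_min,t2s_max Clamp range in ms.
#' @return A `t2star_fit`: list with `t2s_map` (ms), `s0_map`, `valid_mask`,
#'   and the clamp range.
#' @export
fit_t2star <- function(me, use_mean_over_time = TRUE,
                       t2s_min = 2, t2s_max = 300) {
  if (length(me$data) < 2) {
    abort_mefc(paste("single-echo series: T2* cannot be fit;",
                     "use combine_echoes(scheme = 'summation') to pass through"))
  }
  shape <- dim(me$data[[1]])[1:3]
  te <- me$te_ms
  n_e <- length(te)
  vox <- which(me$mask)
  n_v <- length(vox)
  n_t <- dim(me$data[[1]])[4]

  # signal matrix: echoes x voxels (one slice per volume, or the mean)
  fit_one <- function(S) {
    # S: n_e x n_v positive-signal OLS of log(S) on TE
    pos <- S > 0
    npos <- colSums(pos)
    slope <- rep(NA_real_, n_v)
    inter <- rep(NA_real_, n_v)
    full <- npos == n_e
    if (any(full)) {
      y <- log(S[, full, drop = FALSE])
      tec <- te - mean(te)
      slope[full] <- colSums(tec * y) / sum(tec^2)
      inter[full] <- colMeans(y) - slope[full] * mean(te)
    }
    part <- which(!full & npos >= 2)
    for (j in part) {
      p <- pos[, j]
      y <- log(S[p, j])
      tej <- te[p]
      b <- cov(tej, y) / var(tej)
      slope[j] <- b
      inter[j] <- mean(y) - b * mean(tej)
    }
    list(slope = slope, inter = inter, valid = npos >= 2)
  }

  if (use_mean_over_time) {
    S <- vapply(me$data, function(a) {
      rowMeans(matrix(a, prod(shape), n_t))[vox]
    }, numeric(n_v))
    f <- fit_one(t(S))
    slope <- f$slope; inter <- f$inter; valid <- f$valid
  } else {
    slope <- inter <- rep(0, n_v)
    nvalid <- rep(0L, n_v)
    valid <- rep(FALSE, n_v)
    for (k in seq_len(n_t)) {
      S <- vapply(me$data, function(a) {
        matrix(a, prod(shape), n_t)[vox, k]
      }, numeric(n_v))
      f <- fit_one(t(S))
      ok <- f$valid & is.finite(f$slope)
      slope[ok] <- slope[ok] + f$slope[ok]
      inter[ok] <- inter[ok] + f$inter[ok]
      nvalid[ok] <- nvalid[ok] + 1L
      valid <- valid | ok
    }
    slope <- ifelse(nvalid > 0, slope / pmax(nvalid, 1), NA_real_)
    inter <- ifelse(nvalid > 0, inter / pmax(nvalid, 1), NA_real_)
  }

  t2s <- rep(t2s_max, n_v)
  decaying <- valid & is.finite(slope) & slope < 0
  t2s[decaying] <- pmin(pmax(-1 / slope[decaying], t2s_min), t2s_max)
  s0 <- rep(0, n_v)
  okv <- valid & is.finite(inter)
  s0[okv] <- exp(inter[okv])

  t2s_map <- array(NA_real_, shape); t2s_map[vox] <- t2s
  s0_map <- array(NA_real_, shape); s0_map[vox] <- s0
  valid_mask <- array(FALSE, shape); valid_mask[vox] <- valid
  structure(list(t2s_map = t2s_map, s0_map = s0_map, valid_mask = valid_mask,
                 t2s_min = t2s_min, t2s_max = t2s_max),
            class = "t2star_fit")
}

#' @export
print.t2star_fit <- function(x, ...) {
  v <- x$t2s_map[x$valid_mask]
  cat(sprintf("<t2star_fit> %d valid voxels, T2* median %.1f ms (clamp [%g, %g])\n",
              sum(x$valid_mask), stats::median(v), x$t2s_min, x$t2s_max))
  invisible(x)
}

#' Combine multi-echo data into a single BOLD series
#'
#' `t2star_weighted` combines echoes with per-voxel weights
#' \eqn{w_i = TE_i e^{-TE_i / T2^*}} normalised to sum to one across echoes.
#' `summation` is the plain voxelwise sum. `normalized_t2star` is an alias of
#' `t2star_weighted` (under the sum-to-one normalisation used here the two
#' are identical).
#'
#' @param me A [multi_echo_series()].
#' @param fit A `t2star_fit` matching `me` (required for the weighted
#'   schemes; ignored by `summation`).
#' @param scheme One of "t2star_weighted", "summation", "normalized_t2star".
#' @return A [bold_series()] inheriting TR, mask and affine; empty df ledger.
#' @export
combine_echoes <- function(me, fit = NULL,
                           scheme = c("t2star_weighted", "summation",
                                      "normalized_t2star")) {
  scheme <- match.arg(scheme)
  shape <- dim(me$data[[1]])[1:3]
  n_t <- dim(me$data[[1]])[4]
  n_e <- length(me$data)

  if (scheme == "summation") {
    out <- me$data[[1]]
    if (n_e > 1) for (e in 2:n_e) out <- out + me$data[[e]]
  } else {
    if (is.null(fit)) abort_mefc("scheme '%s' needs a t2star_fit", scheme)
    if (!identical(dim(fit$t2s_map), dim(me$data[[1]])[1:3])) {
      abort_mefc("t2star_fit shape does not match the series")
    }
    W <- echo_weights(me$te_ms, fit$t2s_map)
    out <- array(0, dim(me$data[[1]]))
    flat <- function(a) matrix(a, prod(shape), n_t)
    acc <- matrix(0, prod(shape), n_t)
    for (e in seq_len(n_e)) {
      acc <- acc + as.vector(W[[e]]) * flat(me$data[[e]])
    }
    out <- array(acc, dim(me$data[[1]]))
  }
  bold_series(out, tr_ms = me$tr_ms, mask = me$mask, affine = me$affine,
              df_ledger = list())
}

#' Per-echo T2*-weighted combination weights, normalised to sum to one
#'
#' @param te_ms Echo times (ms).
#' @param t2s_map T2* map (ms); NA outside the fitted region gives equal
#'   weights there.
#' @return List of weight arrays, one per echo, summing to 1 voxelwise.
#' @export
echo_weights <- function(te_ms, t2s_map) {
  t2s <- t2s_map
  t2s[!is.finite(t2s) | t2s <= 0] <- NA
  raw <- lapply(te_ms, function(te) te * exp(-te / t2s))
  tot <- Reduce(`+`, raw)
  lapply(raw, function(w) {
    out <- w / tot
    out[!is.finite(out)] <- 1 / length(te_ms)
    out
  })
}

#' Temporal signal-to-noise ratio
#'
#' Voxelwise mean over sample standard deviation (denominator N-1) of the
#' time series. With `scale_by_sqrt_ntp` the map is multiplied by
#' \eqn{\sqrt{N_{TP}}} to put acquisitions with different volume counts on a
#' common footing. Voxels with zero temporal SD are set to `NA` and excluded
#' from summaries.
#'
#' @param b A [bold_series()] with >= 3 time points.
#' @param scale_by_sqrt_ntp Apply the time-point scaling.
#' @return A 3D map (NA outside the mask and at zero-SD voxels).
#' @export
tsnr <- function(b, scale_by_sqrt_ntp = FALSE) {
  n_t <- dim(b$data)[4]
  if (n_t < 3) abort_mefc("tsnr needs >= 3 time points")
  Y <- series_matrix(b)
  mu <- colMeans(Y)
  s <- apply(Y, 2, sd)
  val <- ifelse(s > 0, mu / s, NA_real_)
  if (scale_by_sqrt_ntp) val <- val * sqrt(n_t)
  out <- array(NA_real_, dim(b$data)[1:3])
  out[which(b$mask)] <- val
  out
}
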