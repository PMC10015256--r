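#' Element-wise paired test with an optional session covariate
#'
#' Per element, the paired differences `d = b - a` are regressed on an
#' intercept plus the mean-centred covariate; the intercept's t statistic
#' (df = n - 2) tests the covariate-adjusted mean difference. Without a
#' covariate this reduces exactly to the classical paired t-test (df = n - 1).
#' Elements with zero-variance differences and a nonzero mean are flagged:
#' t = +/-Inf, p = 0.
#'
#' @param cond_a,cond_b Numeric matrices (sessions x elements) or vectors,
#'   aligned by session.
#' @param covariate Optional per-session numeric vector (e.g. scan number).
#' @return List with vectors `t`, `p` (two-sided), `estimate` (adjusted mean
#'   difference), scalar `df`, and logical `zero_variance`.
#' @export
paired_test <- function(cond_a, cond_b, covariate = NULL) {
  a <- as.matrix(cond_a); b <- as.matrix(cond_b)
  if (!identical(dim(a), dim(b))) abort_mefc("conditions must be aligned by session")
  n <- nrow(a)
  if (n < 3) abort_mefc("need >= 3 sessions")
  d <- b - a
  X <- if (is.null(covariate)) {
    matrix(1, n, 1)
  } else {
    if (length(covariate) != n) abort_mefc("covariate length must equal sessions")
    cbind(1, covariate - mean(covariate))
  }
  k <- ncol(X)
  df <- n - k
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, d)
  resid <- d - X %*% beta
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtXi[1, 1])
  est <- beta[1, ]
  zv <- se == 0 | !is.finite(se)
  tval <- ifelse(zv, ifelse(est == 0, 0, sign(est) * Inf), est / ifelse(se == 0, 1, se))
  pval <- ifelse(zv, ifelse(est == 0, 1, 0), 2 * pt(-abs(tval), df))
  if (any(zv & est != 0)) {
    message(sprintf("%d element(s) had zero-variance nonzero differences (t = Inf, p = 0)",
                    sum(zv & est != 0)))
  }
  list(t = tval, p = pval, estimate = est, df = df, zero_variance = zv)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up procedure at level `q` over the supplied p-values (for symmetric
#' matrices pass the strictly-lower-triangle elements only). NA p-values are
#' never rejected.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Logical vector: TRUE where rejected.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_mefc("p-values must lie in [0, 1]")
  out <- p.adjust(p, method = "BH") <= q
  out[is.na(out)] <- FALSE
  out
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates white Gaussian volumes, smooths them to the requested FWHM,
#' standardises within the mask, thresholds two-sided at `voxel_p`, and
#' records the largest in-mask suprathreshold cluster (26-connectivity) per
#' iteration. The returned minimum cluster size is the ceiling of the
#' `1 - alpha` quantile of that null distribution (at least 1). This is a
#' transparent Gaussian-smoothness stand-in for ACF-based cluster simulation
#' and is not numerically equivalent to it.
#'
#' @param map_shape Length-3 grid.
#' @param mask 3D logical mask (non-empty).
#' @param smoothness_fwhm_mm Assumed smoothness (mm); 0 for none.
#' @param voxel_p Two-sided voxel-level threshold (default 0.001).
#' @param alpha Cluster-level false-positive rate (default 0.05).
#' @param n_iter Monte-Carlo iterations (>= 100, default 1000).
#' @param seed Integer seed.
#' @param voxel_mm Voxel size (mm) used to convert the FWHM.
#' @return Integer minimum cluster size (in voxels).
#' @export
cluster_threshold_mc <- function(map_shape, mask, smoothness_fwhm_mm,
                                 voxel_p = 0.001, alpha = 0.05,
                                 n_iter = 1000, seed = 1,
                                 voxel_mm = c(3, 3, 3)) {
  mask <- as_mask(mask)
  if (!any(mask)) abort_mefc("mask is empty")
  if (n_iter < 100) abort_mefc("n_iter must be >= 100")
  sigma <- smoothness_fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  zthr <- qnorm(1 - voxel_p / 2)
  maxes <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      vol <- array(rnorm(prod(map_shape)), map_shape)
      if (smoothness_fwhm_mm > 0) vol <- smooth3d(vol, sigma)
      v <- vol[mask]
      vol[mask] <- (v - mean(v)) / sd(v)
      supra <- array(FALSE, map_shape)
      supra[mask] <- abs(vol[mask]) >= zthr
      if (!any(supra)) return(0L)
      comp <- label_components(supra, scheme = 26)
      max(tabulate(comp[comp > 0]))
    }, 1L)
  })
  max(1L, as.integer(ceiling(quantile(maxes, 1 - alpha, type = 1, names = FALSE))))
}
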