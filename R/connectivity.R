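#' Seed-based correlation map
#'
#' The mean time series over the seed's in-mask voxels is Pearson-correlated
#' with every in-mask voxel. Zero-variance voxels get r = 0 and are counted
#' in the `zero_variance` attribute. The effective df is
#' `n_timepoints - 2 - total df loss` from the series' ledger.
#'
#' @param b A [bold_series()].
#' @param p A [parcellation()] aligned with `b`.
#' @param seed_label Integer label of the seed region.
#' @return A `connectivity_map`: list with `r_map` (3D, NA outside mask),
#'   `seed_label`, `n_timepoints`, `df_effective`, `mask`.
#' @export
seed_map <- function(b, p, seed_label) {
  seed_vox <- p$labels == seed_label & b$mask
  if (!any(seed_vox)) abort_mefc("seed label %s has no in-mask voxels", seed_label)
  n_t <- dim(b$data)[4]
  seed_ts <- rowMeans(series_matrix(b, mask = seed_vox))
  Y <- series_matrix(b)
  Z <- standardize_cols(Y)
  zv <- attr(Z, "zero_variance")
  s <- sd(seed_ts)
  r <- if (s == 0) rep(0, ncol(Z)) else {
    zs <- (seed_ts - mean(seed_ts)) / s
    as.vector(crossprod(Z, zs)) / (n_t - 1)
  }
  r[zv] <- 0
  r <- pmin(pmax(r, -1), 1)
  r_map <- array(NA_real_, dim(b$data)[1:3])
  r_map[which(b$mask)] <- r
  structure(list(r_map = r_map, seed_label = seed_label, n_timepoints = n_t,
                 df_effective = as.integer(n_t - 2 - df_total(b)),
                 mask = b$mask, zero_variance = sum(zv)),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> seed %s, %d time points, df %d, r in [%.2f, %.2f]\n",
              x$seed_label, x$n_timepoints, x$df_effective,
              min(x$r_map, na.rm = TRUE), max(x$r_map, na.rm = TRUE)))
  invisible(x)
}

#' ROI-by-ROI correlation matrix
#'
#' Mean time series per selected ROI, Pearson-correlated pairwise. ROIs are
#' ordered with the subcortical block first, then cortical, each in ascending
#' label order. Empty ROIs abort with their names listed.
#'
#' @param b A [bold_series()].
#' @param p A [parcellation()].
#' @param roi_classes Classes to include (default subcortical + cortical).
#' @return A `connectivity_matrix`: list with `r` (symmetric, unit diagonal),
#'   `roi_labels`, `roi_names`, `n_timepoints`.
#' @export
roi_matrix <- function(b, p, roi_classes = c("subcortical", "cortical")) {
  tab <- p$table[p$table$class %in% roi_classes, , drop = FALSE]
  ord <- order(match(tab$class, c("subcortical", "cortical", "seed")), tab$label)
  tab <- tab[ord, , drop = FALSE]
  if (nrow(tab) < 2) abort_mefc("need at least two ROIs")
  empty <- character(0)
  TS <- matrix(0, dim(b$data)[4], nrow(tab))
  for (i in seq_len(nrow(tab))) {
    m <- p$labels == tab$label[i] & b$mask
    if (!any(m)) {
      empty <- c(empty, sprintf("%d (%s)", tab$label[i], tab$name[i]))
      next
    }
    TS[, i] <- rowMeans(series_matrix(b, mask = m))
  }
  if (length(empty)) {
    abort_mefc("ROI(s) with no in-mask voxels: %s", paste(empty, collapse = ", "))
  }
  R <- cor(TS)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R <- pmin(pmax(R, -1), 1)
  dimnames(R) <- list(tab$name, tab$name)
  structure(list(r = R, roi_labels = tab$label, roi_names = tab$name,
                 n_timepoints = dim(b$data)[4]),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d ROIs, %d time points\n",
              nrow(x$r), ncol(x$r), x$n_timepoints))
  invisible(x)
}

#' Threshold and binarize a correlation map or matrix
#'
#' Inclusive rule: 1 where `r >= r_thr`, else 0. For matrices the diagonal is
#' excluded (set to 0).
#'
#' @param x A `connectivity_map`, `connectivity_matrix`, or plain array.
#' @param r_thr Threshold in (-1, 1].
#' @return Binary object of the same spatial shape (maps: NA outside mask
#'   set to 0).
#' @export
threshold_binarize <- function(x, r_thr) {
  if (r_thr <= -1 || r_thr > 1) abort_mefc("r_thr must lie in (-1, 1]")
  UseMethod("threshold_binarize")
}

#' @export
threshold_binarize.connectivity_map <- function(x, r_thr) {
  out <- ifelse(!is.na(x$r_map) & x$r_map >= r_thr, 1L, 0L)
  dim(out) <- dim(x$r_map)
  out
}

#' @export
threshold_binarize.connectivity_matrix <- function(x, r_thr) {
  out <- ifelse(x$r >= r_thr, 1L, 0L)
  diag(out) <- 0L
  dimnames(out) <- dimnames(x$r)
  out
}

#' @export
threshold_binarize.default <- function(x, r_thr) {
  out <- ifelse(!is.na(x) & x >= r_thr, 1L, 0L)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  if (is.matrix(x) && nrow(x) == ncol(x)) diag(out) <- 0L
  out
}
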