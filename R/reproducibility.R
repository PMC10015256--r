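#' Dice coefficient of two binary maps
#'
#' \deqn{DC = 2 |A \cap B| / (|A| + |B|)}
#' DC ranges 0-1 with 1 meaning perfect overlap. When both maps are empty the
#' coefficient is undefined and `NA` is returned (reported distinctly, not
#' coerced to 0).
#'
#' @param a,b Binary (logical or 0/1) arrays of identical shape.
#' @return Scalar in \[0, 1\], or NA if both inputs are empty.
#' @export
dice_maps <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort_mefc("maps must share one shape")
  a <- as_mask(a); b <- as_mask(b)
  va <- sum(a); vb <- sum(b)
  if (va + vb == 0) return(NA_real_)
  2 * sum(a & b) / (va + vb)
}

#' Dice coefficient of two binarized symmetric matrices
#'
#' Because correlation matrices are symmetric, only the strictly lower
#' triangle enters the calculation. Both-empty lower triangles give `NA`.
#'
#' @param a,b Binary square matrices of the same dimension.
#' @return Scalar in \[0, 1\], or NA.
#' @export
dice_matrices <- function(a, b) {
  if (!identical(dim(a), dim(b)) || nrow(a) != ncol(a)) {
    abort_mefc("inputs must be square matrices of the same dimension")
  }
  lt <- lower.tri(a, diag = FALSE)
  dice_maps(array(a[lt] != 0), array(b[lt] != 0))
}

#' Voxelwise test-retest reproducibility of FCD maps
#'
#' \deqn{REP = 1 - |FCD_{T1} - FCD_{T2}| / (FCD_{T1} + FCD_{T2})}
#' For non-negative inputs REP ranges 0-1; two equal values give REP = 1,
#' which is also the convention applied at 0/0. The region mean summarises
#' REP over a mask (typically grey matter).
#'
#' @param m1,m2 `fcd_map`s of the same variant and shape.
#' @param region_mask 3D logical mask for the summary mean.
#' @return A `repro_result`: list with `rep_map`, `region_mean_rep`,
#'   `variant`, `r_thr`.
#' @export
rep_fcd <- function(m1, m2, region_mask = m1$mask) {
  if (!identical(m1$variant, m2$variant)) {
    abort_mefc("FCD variant mismatch: %s vs %s", m1$variant, m2$variant)
  }
  if (!identical(dim(m1$counts), dim(m2$counts))) abort_mefc("map shape mismatch")
  a <- m1$counts; b <- m2$counts
  if (any(a[m1$mask] < 0, na.rm = TRUE) || any(b[m2$mask] < 0, na.rm = TRUE)) {
    abort_mefc("REP is defined for non-negative counts")
  }
  tot <- a + b
  rep_map <- 1 - abs(a - b) / ifelse(tot == 0, 1, tot)
  rep_map[tot == 0 & !is.na(tot)] <- 1  # 0/0: two equal values
  region_mask <- as_mask(region_mask) & m1$mask & m2$mask
  if (!any(region_mask)) abort_mefc("region mask is empty")
  structure(list(rep_map = rep_map, region_mean_rep = mean(rep_map[region_mask]),
                 variant = m1$variant, r_thr = m1$r_thr),
            class = "repro_result")
}

#' @export
print.repro_result <- function(x, ...) {
  cat(sprintf("<repro_result> %s FCD at r >= %g: region mean REP %.3f\n",
              x$variant, x$r_thr, x$region_mean_rep))
  invisible(x)
}

#' Per-seed Dice report across a threshold grid
#'
#' Convenience wrapper: thresholds two sessions' connectivity maps at each
#' requested r and tabulates Dice coefficients.
#'
#' @param maps1,maps2 Named lists of `connectivity_map`s (same names =
#'   seeds), one per session.
#' @param r_thrs Thresholds (default 0.3 with the 0.4/0.5/0.6 grid available).
#' @return Tibble with columns seed, r_thr, dice.
#' @export
dice_report <- function(maps1, maps2, r_thrs = c(0.3, 0.4, 0.5, 0.6)) {
  stopifnot(identical(names(maps1), names(maps2)))
  rows <- list()
  for (nm in names(maps1)) {
    for (rt in r_thrs) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        seed = nm, r_thr = rt,
        dice = dice_maps(threshold_binarize(maps1[[nm]], rt),
                         threshold_binarize(maps2[[nm]], rt))
      )
    }
  }
  do.call(rbind, rows)
}
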