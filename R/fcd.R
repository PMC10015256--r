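#' Local functional connectivity density
#'
#' For every in-mask voxel v, a cluster is grown from v by breadth-first
#' search over the chosen neighbour scheme, admitting an in-mask voxel u iff
#' the Pearson correlation of u's series with v's series is at least `r_thr`
#' (correlation is always against v, never chained). The lFCD value at v is
#' the cluster size, including v itself when `self_inclusive`. Correlations
#' are computed against the index voxel on the fly; no full voxel-by-voxel
#' matrix is formed.
#'
#' @param b A [bold_series()] with >= 3 time points and a non-empty mask.
#' @param r_thr Correlation threshold (inclusive, default 0.6).
#' @param neighbor_scheme 6, 18 or 26 (default 26, corner-touching).
#' @param self_inclusive Count the index voxel (default TRUE, so the minimum
#'   in-mask value is 1).
#' @return An `fcd_map`: list with `counts` (3D integer, NA outside mask),
#'   `variant`, `r_thr`, `neighbor_scheme`, `self_inclusive`, `mask`.
#' @export
lfcd <- function(b, r_thr = 0.6, neighbor_scheme = 26, self_inclusive = TRUE) {
  n_t <- dim(b$data)[4]
  if (n_t < 3) abort_mefc("lfcd needs >= 3 time points")
  if (!any(b$mask)) abort_mefc("mask is empty")
  shape <- dim(b$data)[1:3]
  coords <- mask_coords(b$mask)
  nbrs <- neighbor_list(coords, shape, neighbor_scheme)
  Z <- standardize_cols(series_matrix(b))
  n_v <- ncol(Z)
  counts <- integer(n_v)
  visited <- integer(n_v)  # stamp per index voxel, avoids re-zeroing
  for (v in seq_len(n_v)) {
    r <- as.vector(crossprod(Z, Z[, v])) / (n_t - 1)
    admit <- r >= r_thr
    admit[v] <- TRUE  # the index voxel anchors its own cluster
    queue <- v
    visited[v] <- v
    size <- 1L
    while (length(queue)) {
      w <- queue[[1]]
      queue <- queue[-1]
      for (u in nbrs[[w]]) {
        if (visited[u] != v && admit[u]) {
          visited[u] <- v
          size <- size + 1L
          queue <- c(queue, u)
        }
      }
    }
    counts[v] <- if (self_inclusive) size else size - 1L
  }
  out <- array(NA_integer_, shape)
  out[which(b$mask)] <- counts
  structure(list(counts = out, variant = "local", r_thr = r_thr,
                 neighbor_scheme = neighbor_scheme,
                 self_inclusive = self_inclusive, mask = b$mask),
            class = "fcd_map")
}

#' Global functional connectivity density
#'
#' For every in-mask voxel v, the number of in-mask voxels u (u != v unless
#' `include_self`) whose series correlates with v's at `r >= r_thr`.
#' Computed blockwise to bound memory.
#'
#' @param b A [bold_series()].
#' @param r_thr Correlation threshold (inclusive, default 0.6).
#' @param include_self Count the voxel itself (default FALSE).
#' @return An `fcd_map` with `variant = "global"`.
#' @export
gfcd <- function(b, r_thr = 0.6, include_self = FALSE) {
  n_t <- dim(b$data)[4]
  if (n_t < 3) abort_mefc("gfcd needs >= 3 time points")
  if (!any(b$mask)) abort_mefc("mask is empty")
  Z <- standardize_cols(series_matrix(b))
  zv <- attr(Z, "zero_variance")
  n_v <- ncol(Z)
  counts <- integer(n_v)
  block <- 512L
  for (start in seq(1L, n_v, by = block)) {
    jj <- start:min(start + block - 1L, n_v)
    R <- crossprod(Z, Z[, jj, drop = FALSE]) / (n_t - 1)
    # pin the self-correlation to exactly 1 (0 for zero-variance voxels)
    R[cbind(jj, seq_along(jj))] <- ifelse(zv[jj], 0, 1)
    counts[jj] <- as.integer(colSums(R >= r_thr))
    if (!include_self) {
      counts[jj] <- counts[jj] - as.integer(!zv[jj] & 1 >= r_thr)
    }
  }
  out <- array(NA_integer_, dim(b$data)[1:3])
  out[which(b$mask)] <- counts
  structure(list(counts = out, variant = "global", r_thr = r_thr,
                 neighbor_scheme = NA, self_inclusive = include_self,
                 mask = b$mask),
            class = "fcd_map")
}

#' @export
print.fcd_map <- function(x, ...) {
  v <- x$counts[x$mask]
  cat(sprintf("<fcd_map> %s FCD at r >= %g: mean %.2f, max %d over %d voxels\n",
              x$variant, x$r_thr, mean(v), max(v), length(v)))
  invisible(x)
}

#' Mean FCD over a region
#'
#' @param m An `fcd_map`.
#' @param region_mask 3D logical mask; must lie within the map's mask.
#' @return Scalar arithmetic mean of the counts over the region.
#' @export
summarize_fcd <- function(m, region_mask) {
  region_mask <- as_mask(region_mask)
  if (!any(region_mask)) abort_mefc("region mask is empty")
  if (any(region_mask & !m$mask)) {
    abort_mefc("region mask extends outside the FCD map's mask")
  }
  mean(m$counts[region_mask])
}
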