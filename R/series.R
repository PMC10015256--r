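#' Multi-echo BOLD series
#'
#' Container for a multi-echo acquisition: one 4D array (x, y, z, t) per echo,
#' all the same shape, with echo times, TR, a brain mask and a voxel-to-world
#' affine.
#'
#' @param data List of 4D numeric arrays, one per echo.
#' @param te_ms Echo times in ms, strictly increasing; one per array.
#' @param tr_ms Repetition time in ms.
#' @param mask 3D logical/0-1 brain mask matching the spatial dims.
#' @param affine 4x4 voxel-to-world transform (RAS+, mm). Defaults to 3 mm
#'   isotropic centred on the volume.
#' @return A `multi_echo_series` object.
#' @export
multi_echo_series <- function(data, te_ms, tr_ms, mask = NULL, affine = NULL) {
  if (!is.list(data)) data <- list(data)
  if (length(data) != length(te_ms)) {
    abort_mefc("need one data array per echo time (%d arrays, %d TEs)",
               length(data), length(te_ms))
  }
  if (is.unsorted(te_ms, strictly = TRUE)) abort_mefc("te_ms must be strictly increasing")
  dims <- lapply(data, dim)
  if (any(vapply(dims, length, 1L) != 4L)) abort_mefc("each echo must be a 4D array")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    abort_mefc("all echo arrays must share one shape")
  }
  shape <- dims[[1]][1:3]
  if (is.null(mask)) mask <- array(TRUE, shape)
  mask <- as_mask(mask)
  if (!identical(dim(mask), as.integer(shape))) abort_mefc("mask shape mismatch")
  if (is.null(affine)) affine <- default_affine(shape = shape)
  structure(
    list(data = data, te_ms = te_ms, tr_ms = tr_ms, mask = mask, affine = affine),
    class = "multi_echo_series"
  )
}

#' @export
print.multi_echo_series <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("<multi_echo_series> %d echoes (TE %s ms), %dx%dx%d x %d vols, TR %g ms\n",
              length(x$data), paste(x$te_ms, collapse = "/"), d[1], d[2], d[3], d[4],
              x$tr_ms))
  invisible(x)
}

#' Single (combined) BOLD series with a degrees-of-freedom ledger
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr_ms Repetition time in ms.
#' @param mask 3D brain mask.
#' @param affine 4x4 voxel-to-world transform.
#' @param df_ledger List of `list(stage =, regressors_removed =)` records of
#'   degrees of freedom spent by preprocessing stages.
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, tr_ms, mask = NULL, affine = NULL,
                        df_ledger = list()) {
  if (length(dim(data)) != 4L) abort_mefc("data must be 4D (x,y,z,t)")
  shape <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, shape)
  mask <- as_mask(mask)
  if (!identical(dim(mask), as.integer(shape))) abort_mefc("mask shape mismatch")
  if (is.null(affine)) affine <- default_affine(shape = shape)
  structure(
    list(data = data, tr_ms = tr_ms, mask = mask, affine = affine,
         df_ledger = df_ledger),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d x %d vols, TR %g ms, df loss %d\n",
              d[1], d[2], d[3], d[4], x$tr_ms, df_total(x)))
  invisible(x)
}

#' Total degrees of freedom spent so far
#'
#' Sums the `regressors_removed` entries of a series' ledger. Entries whose
#' stage is marked informational (e.g. bandpass bin counts) are excluded.
#'
#' @param b A `bold_series`.
#' @return Integer total df loss.
#' @export
df_total <- function(b) {
  if (length(b$df_ledger) == 0) return(0L)
  counted <- vapply(b$df_ledger, function(e) {
    if (isTRUE(e$informational)) 0L else as.integer(e$regressors_removed)
  }, 1L)
  sum(counted)
}

#' Append a stage to the df ledger
#' @noRd
ledger_append <- function(b, stage, regressors_removed, informational = FALSE) {
  b$df_ledger[[length(b$df_ledger) + 1L]] <-
    list(stage = stage, regressors_removed = as.integer(regressors_removed),
         informational = informational)
  b
}

#' In-mask voxel time series as a t x V matrix
#' @noRd
series_matrix <- function(b, mask = b$mask) {
  d <- dim(b$data)
  flat <- matrix(b$data, prod(d[1:3]), d[4])
  t(flat[which(mask), , drop = FALSE])
}

#' Write a t x V matrix back into the 4D array at in-mask voxels
#' @noRd
series_unmatrix <- function(b, Y, mask = b$mask) {
  d <- dim(b$data)
  flat <- matrix(b$data, prod(d[1:3]), d[4])
  flat[which(mask), ] <- t(Y)
  array(flat, d)
}
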