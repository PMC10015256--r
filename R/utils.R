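`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a formatted message
#' @noRd
abort_mefc <- function(...) stop(sprintf(...), call. = FALSE)

#' Coerce an array to a logical mask, preserving dim
#' @noRd
as_mask <- function(x) {
  m <- x != 0 & !is.na(x)
  dim(m) <- dim(x)
  m
}

#' Default RAS+ affine for a given voxel size (mm), origin at volume centre
#' @noRd
default_affine <- function(voxel_mm = c(3, 3, 3), shape = NULL) {
  aff <- diag(c(voxel_mm, 1))
  if (!is.null(shape)) aff[1:3, 4] <- -voxel_mm * (shape - 1) / 2
  aff
}

#' Voxel edge lengths (mm) from an affine
#' @noRd
voxel_sizes <- function(affine) {
  if (is.null(affine)) return(c(3, 3, 3))
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Neighbourhood offsets for 6/18/26-connectivity
#' @noRd
neighbor_offsets <- function(scheme = 26) {
  if (!scheme %in% c(6, 18, 26)) {
    abort_mefc("neighbor scheme must be one of 6, 18, 26 (got %s)", scheme)
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(scheme),
    "6"  = d == 1,
    "18" = d >= 1 & d <= 2,
    "26" = d >= 1
  )
  unname(g[keep, , drop = FALSE])
}

#' Linear voxel indices (1-based) of TRUE entries, as n x 3 coordinates
#' @noRd
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

#' For each row of coords, the in-mask neighbour row indices under a scheme.
#' Returns a list parallel to coords rows.
#' @noRd
neighbor_list <- function(coords, shape, scheme = 26) {
  offs <- neighbor_offsets(scheme)
  lookup <- array(0L, dim = shape)
  lookup[coords] <- seq_len(nrow(coords))
  lapply(seq_len(nrow(coords)), function(i) {
    nb <- sweep(offs, 2, coords[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    idx <- lookup[nb[ok, , drop = FALSE]]
    idx[idx > 0L]
  })
}

#' Label connected components of a 3D logical array.
#'
#' Breadth-first flood fill over the chosen neighbour scheme. Returns an
#' integer array of the same shape: 0 outside, component id inside.
#' @noRd
label_components <- function(mask, scheme = 26) {
  shape <- dim(mask)
  coords <- mask_coords(mask)
  lab <- array(0L, dim = shape)
  if (nrow(coords) == 0) return(lab)
  nbrs <- neighbor_list(coords, shape, scheme)
  comp <- integer(nrow(coords))
  cur <- 0L
  for (i in seq_len(nrow(coords))) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (u in nbrs[[v]]) {
        if (comp[u] == 0L) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  lab[coords] <- comp
  lab
}

#' Columnwise standardisation to zero mean / unit sample SD.
#' Zero-variance columns are set to all zeros (flagged via attribute).
#' @noRd
standardize_cols <- function(Y) {
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  s <- sqrt(colSums(Yc^2) / (nrow(Y) - 1))
  zv <- s == 0 | !is.finite(s)
  s[zv] <- 1
  Z <- sweep(Yc, 2, s, `/`)
  Z[, zv] <- 0
  attr(Z, "zero_variance") <- zv
  Z
}

#' Binary erosion of a 3D mask (6-connectivity); falls back to the input if
#' erosion would empty it.
#' @noRd
erode_mask <- function(mask) {
  shape <- dim(mask)
  out <- mask
  offs <- neighbor_offsets(6)
  coords <- mask_coords(mask)
  for (i in seq_len(nrow(coords))) {
    nb <- sweep(offs, 2, coords[i, ], `+`)
    inside <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    if (any(!inside) || any(!mask[nb[inside, , drop = FALSE]])) {
      out[coords[i, 1], coords[i, 2], coords[i, 3]] <- FALSE
    }
  }
  if (!any(out)) mask else out
}
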