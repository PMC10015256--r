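#' Discard initial non-equilibrium volumes
#'
#' Drops the first `ceil(seconds * 1000 / tr_ms)` volumes so that at least
#' `seconds` of data are removed (TR 900 ms drops 12 of 400; TR 650 ms drops
#' 16 of 554; TR 1000 ms drops exactly 10).
#'
#' @param b A [bold_series()].
#' @param seconds Duration to discard (default 10 s).
#' @return The trimmed [bold_series()]; the ledger records the stage
#'   (informational, no regressor df).
#' @export
discard_initial <- function(b, seconds = 10) {
  n_drop <- as.integer(ceiling(seconds * 1000 / b$tr_ms))
  n_t <- dim(b$data)[4]
  if (n_t - n_drop < 10) {
    abort_mefc("series too short: %d volumes minus %d discarded leaves < 10",
               n_t, n_drop)
  }
  b$data <- b$data[, , , (n_drop + 1):n_t, drop = FALSE]
  b <- ledger_append(b, sprintf("discard_initial(%gs: %d vols)", seconds, n_drop),
                     0L, informational = TRUE)
  b
}

#' Legendre polynomial basis over a scan
#'
#' Columns are Legendre polynomials of orders 0..`order` evaluated on
#' `[-1, 1]` across the time points.
#'
#' @param n_t Number of time points.
#' @param order Highest order (>= 0).
#' @return An `n_t x (order + 1)` matrix.
#' @export
legendre_basis <- function(n_t, order) {
  if (order < 0) abort_mefc("detrend order must be >= 0")
  x <- if (n_t > 1) seq(-1, 1, length.out = n_t) else 0
  P <- matrix(0, n_t, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      # (k) P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  colnames(P) <- sprintf("legendre%d", 0:order)
  P
}

#' Bundle nuisance regressors
#'
#' @param motion t x 6 or t x 12 table (rigid-body parameters, optionally +
#'   temporal derivatives), or NULL.
#' @param tissue_signals t x k table of tissue means (WM, CSF), or NULL.
#' @param components t x m table of externally computed component time
#'   courses (e.g. from ICA-based denoising), or NULL.
#' @param detrend_order Polynomial detrend order (>= 0).
#' @return A `nuisance_set` list.
#' @export
nuisance_set <- function(motion = NULL, tissue_signals = NULL,
                         components = NULL, detrend_order = 3) {
  if (detrend_order < 0) abort_mefc("detrend_order must be >= 0")
  structure(list(motion = motion, tissue_signals = tissue_signals,
                 components = components, detrend_order = detrend_order),
            class = "nuisance_set")
}

#' Append temporal derivatives to a 6-parameter motion table
#'
#' Backward differences with a leading zero row, giving the 12-parameter
#' motion model.
#'
#' @param motion t x 6 table.
#' @return t x 12 matrix.
#' @export
motion_derivatives <- function(motion) {
  m <- as.matrix(motion)
  if (is.null(colnames(m))) colnames(m) <- sprintf("motion%d", seq_len(ncol(m)))
  d <- rbind(0, diff(m))
  colnames(d) <- paste0(colnames(m), "_deriv")
  cbind(m, d)
}

#' Build the nuisance design matrix and count degrees of freedom
#'
#' Columns are Legendre polynomials of orders 0..detrend_order, then motion,
#' tissue and component regressors. The df loss counts motion + tissue +
#' components + detrend_order; the constant term is excluded from the count,
#' so the standard configuration (12 motion + WM + CSF + 3rd-order detrend)
#' reports a loss of 17.
#'
#' @param n A [nuisance_set()].
#' @param n_t Series length; all tables must have `n_t` rows.
#' @return List with `X` (design matrix) and `df_loss` (integer).
#' @export
build_design <- function(n, n_t) {
  parts <- list(legendre_basis(n_t, n$detrend_order))
  df_loss <- n$detrend_order
  for (nm in c("motion", "tissue_signals", "components")) {
    tab <- n[[nm]]
    if (is.null(tab)) next
    m <- as.matrix(tab)
    if (nrow(m) != n_t) {
      abort_mefc("%s table has %d rows; series has %d time points", nm, nrow(m), n_t)
    }
    if (is.null(colnames(m))) colnames(m) <- sprintf("%s%d", nm, seq_len(ncol(m)))
    parts[[length(parts) + 1]] <- m
    df_loss <- df_loss + ncol(m)
  }
  X <- do.call(cbind, parts)
  if (qr(X)$rank < ncol(X)) {
    warning("nuisance design is rank deficient; regression will use a pseudo-inverse",
            call. = FALSE)
  }
  list(X = X, df_loss = as.integer(df_loss))
}

#' Regress nuisance signals out of a series
#'
#' Voxelwise OLS residuals with the voxel mean restored. Rank-deficient
#' designs are handled through the Moore-Penrose pseudo-inverse. The df
#' ledger is appended with the design's `df_loss`.
#'
#' @param b A [bold_series()].
#' @param design Result of [build_design()] (or a plain matrix, in which case
#'   its column count minus any intercept is recorded).
#' @return The residualised [bold_series()].
#' @export
regress_nuisance <- function(b, design) {
  if (is.matrix(design)) design <- list(X = design, df_loss = ncol(design))
  X <- design$X
  n_t <- dim(b$data)[4]
  if (nrow(X) != n_t) abort_mefc("design has %d rows; series has %d time points",
                                 nrow(X), n_t)
  Y <- series_matrix(b)
  mu <- colMeans(Y)
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-10
  U <- sv$u[, keep, drop = FALSE]
  resid <- Y - U %*% crossprod(U, Y)
  Y_out <- sweep(resid, 2, mu, `+`)
  b$data <- series_unmatrix(b, Y_out)
  ledger_append(b, "nuisance_regression", design$df_loss)
}

#' Ideal bandpass filter
#'
#' Zero-phase frequency-domain mask retaining Fourier bins with frequency
#' strictly inside `(f_lo, f_hi)`; the voxel mean (DC) is restored after
#' filtering. The ledger records the number of removed bins as an
#' informational entry.
#'
#' @param b A [bold_series()].
#' @param f_lo,f_hi Band edges in Hz; `f_hi` must be below the Nyquist
#'   frequency `1 / (2 TR)`.
#' @return Filtered [bold_series()].
#' @export
bandpass <- function(b, f_lo = 0.01, f_hi = 0.1) {
  dt <- b$tr_ms / 1000
  nyq <- 1 / (2 * dt)
  if (f_lo >= f_hi) abort_mefc("f_lo must be below f_hi")
  if (f_hi >= nyq) abort_mefc("f_hi (%g Hz) must be below Nyquist (%g Hz)", f_hi, nyq)
  n_t <- dim(b$data)[4]
  freq <- (seq_len(n_t) - 1) / (n_t * dt)
  freq <- pmin(freq, 1 / dt - freq)  # mirrored axis
  keep <- freq > f_lo & freq < f_hi
  Y <- series_matrix(b)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  F <- mvfft(Yc)
  F[!keep, ] <- 0
  Yf <- Re(mvfft(F, inverse = TRUE)) / n_t
  b$data <- series_unmatrix(b, sweep(Yf, 2, mu, `+`))
  ledger_append(b, sprintf("bandpass(%g-%g Hz)", f_lo, f_hi),
                sum(!keep), informational = TRUE)
}

#' Mask-renormalised Gaussian smoothing
#'
#' Per-volume 3D Gaussian smoothing with
#' \eqn{\sigma_{axis} = FWHM / (2\sqrt{2\ln 2}) / voxel_{axis}} (a 4 mm FWHM
#' on 3 mm voxels gives sigma ~ 0.566 voxels). Smoothing is restricted to the
#' mask with kernel renormalisation over in-mask support, so constants are
#' preserved and out-of-mask voxels never leak in.
#'
#' @param b A [bold_series()].
#' @param fwhm_mm Full width at half maximum in mm; 0 is the identity.
#' @return Smoothed [bold_series()].
#' @export
smooth_gaussian <- function(b, fwhm_mm = 4) {
  if (fwhm_mm < 0) abort_mefc("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(b)
  vox <- voxel_sizes(b$affine)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  n_t <- dim(b$data)[4]
  m <- b$mask * 1
  den <- smooth3d(m, sigma)
  out <- b$data
  for (k in seq_len(n_t)) {
    vol <- b$data[, , , k] * m
    num <- smooth3d(vol, sigma)
    sm <- num / den
    sm[!b$mask] <- b$data[, , , k][!b$mask]
    out[, , , k] <- sm
  }
  b$data <- out
  b
}

#' Separable 3D Gaussian convolution (truncated at 4 sigma)
#' @noRd
smooth3d <- function(vol, sigma) {
  d <- dim(vol)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    half <- max(1L, ceiling(4 * sigma[ax]))
    kern <- stats::dnorm(-half:half, sd = sigma[ax])
    kern <- kern / sum(kern)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- kern[ok]
    }
    vol <- apply_along(vol, ax, K)
  }
  vol
}

#' Multiply axis `ax` of a 3D array by matrix K (K %*% slices)
#' @noRd
apply_along <- function(vol, ax, K) {
  d <- dim(vol)
  perm <- c(ax, setdiff(1:3, ax))
  v <- aperm(vol, perm)
  m <- matrix(v, d[ax], prod(d[-ax]))
  m <- K %*% m
  v <- array(m, d[perm])
  aperm(v, order(perm))
}

#' Mean tissue time courses from eroded masks
#'
#' WM and CSF nuisance signals, extracted (by convention) before smoothing
#' from masks eroded by one voxel (6-connectivity; falls back to the raw mask
#' if erosion empties it).
#'
#' @param b A [bold_series()].
#' @param wm,csf 3D logical masks.
#' @param erode Erode the masks first (default TRUE).
#' @return A t x 2 matrix with columns `wm`, `csf`.
#' @export
tissue_signals <- function(b, wm, csf, erode = TRUE) {
  get_mean <- function(m) {
    m <- as_mask(m) & b$mask
    if (erode) m <- erode_mask(m)
    m <- m & b$mask
    if (!any(m)) abort_mefc("tissue mask empty after intersection with the brain mask")
    rowMeans(series_matrix(b, mask = m))
  }
  cbind(wm = get_mean(wm), csf = get_mean(csf))
}

#' Run the standard denoising chain
#'
#' discard -> smooth -> (detrend + nuisance regression, one design) ->
#' bandpass, with tissue signals extracted before smoothing. Motion tables
#' are trimmed to match the discarded series and optionally expanded to 12
#' parameters.
#'
#' @param b A combined [bold_series()] (pre-discard).
#' @param motion Motion table aligned with the un-discarded series, or NULL.
#' @param wm,csf Tissue masks, or NULL to skip tissue regressors.
#' @param components Component time courses aligned with the un-discarded
#'   series (rows trimmed with the discard), or NULL.
#' @param motion_params 6 or 12 (12 adds temporal derivatives).
#' @param detrend_order Polynomial order (default 3).
#' @param discard_seconds Initial discard (default 10 s).
#' @param fwhm_mm Smoothing kernel (default 4 mm).
#' @param f_lo,f_hi Band edges in Hz.
#' @return The denoised [bold_series()] with a complete df ledger.
#' @export
standard_denoise <- function(b, motion = NULL, wm = NULL, csf = NULL,
                             components = NULL, motion_params = 12,
                             detrend_order = 3, discard_seconds = 10,
                             fwhm_mm = 4, f_lo = 0.01, f_hi = 0.1) {
  if (!motion_params %in% c(6, 12)) abort_mefc("motion_params must be 6 or 12")
  n_t0 <- dim(b$data)[4]
  b <- discard_initial(b, discard_seconds)
  n_t <- dim(b$data)[4]
  trim <- function(tab) {
    if (is.null(tab)) return(NULL)
    m <- as.matrix(tab)
    if (nrow(m) == n_t0) m <- m[(n_t0 - n_t + 1):n_t0, , drop = FALSE]
    if (nrow(m) != n_t) abort_mefc("regressor table rows match neither the raw nor trimmed series")
    m
  }
  motion <- trim(motion)
  components <- trim(components)
  if (!is.null(motion) && motion_params == 12 && ncol(motion) == 6) {
    motion <- motion_derivatives(motion)
  }
  tiss <- if (!is.null(wm) && !is.null(csf)) tissue_signals(b, wm, csf) else NULL
  b <- smooth_gaussian(b, fwhm_mm)
  des <- build_design(nuisance_set(motion = motion, tissue_signals = tiss,
                                   components = components,
                                   detrend_order = detrend_order), n_t)
  b <- regress_nuisance(b, des)
  bandpass(b, f_lo, f_hi)
}
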