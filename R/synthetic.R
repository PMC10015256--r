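#' Seeded multi-echo BOLD phantom generator
#'
#' These functions build a self-contained emulation of a two-session
#' multiband (MB) / multiband multi-echo (MBME) resting-state study: a
#' brain-like anatomy with GM/WM/CSF compartments and a contiguous GM
#' parcellation, per-voxel T2*/S0 ground truth with a short-T2* dropout
#' region, latent network signals with a controllable between-session
#' stability, and mono-exponential multi-echo signal formation
#' \eqn{S_v(t, TE) = S0_v \exp(-TE \cdot R2^*_v(t)) (1 + d_v(t) + p(t)) + \epsilon}
#' where BOLD fluctuations enter through \eqn{R2^*_v(t)} (so their amplitude
#' is TE-dependent) and drift/physiological nuisance enter multiplicatively.
#'
#' @name synthetic
NULL

#' Build a phantom anatomy: tissue masks, GM parcellation and ground truth
#'
#' The brain is an ellipsoid filling ~90% of the grid: an outer CSF shell, a
#' GM shell and a WM core. GM is partitioned into `n_rois` contiguous labels
#' by seeded multi-source region growing. A short-T2* "dropout" cap is
#' planted at the inferior GM edge.
#'
#' @param shape Grid size, length-3 integer vector, each >= c(8, 8, 4).
#' @param n_rois Number of GM parcels (>= 2, <= number of GM voxels).
#' @param seed Integer RNG seed; outputs are bit-identical for a fixed seed.
#' @param n_subcortical How many of the labels (taken from the innermost GM
#'   parcels) are classed "subcortical"; the rest are "cortical".
#' @param t2s_gm,t2s_wm,t2s_csf,t2s_dropout T2* ranges (ms) drawn uniformly
#'   per voxel within each compartment.
#' @param s0_range Equilibrium-signal range (arbitrary units).
#' @param noise_sd Thermal noise SD in signal units (default gives per-echo
#'   tSNR of roughly 50-100 at the default S0).
#' @param session_stability Correlation in \[0, 1\] of latent network signals
#'   between timepoint 1 and timepoint 2.
#' @param physio_freqs_hz Nuisance oscillation frequencies (Hz).
#' @return A list with elements `parcellation` (a [parcellation()]),
#'   `tissue_masks` (list of logical arrays `brain`, `gm`, `wm`, `csf`), and
#'   `ground_truth` (t2s_map, s0_map, network_loadings, gm_index, brain_index,
#'   drift_coeffs, noise_sd, session_stability, physio_freqs_hz,
#'   dropout_mask).
#' @export
make_phantom_anatomy <- function(shape = c(20, 20, 10), n_rois = 8, seed = 1,
                                 n_subcortical = 0,
                                 t2s_gm = c(30, 60), t2s_wm = c(40, 55),
                                 t2s_csf = c(80, 150), t2s_dropout = c(15, 25),
                                 s0_range = c(900, 1100), noise_sd = 7,
                                 session_stability = 0.8,
                                 physio_freqs_hz = c(0.25, 1.0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < c(8, 8, 4))) {
    abort_mefc("shape must be length 3 with each dim >= (8, 8, 4)")
  }
  if (n_rois < 2) abort_mefc("n_rois must be >= 2")
  withr::with_seed(seed, {
    ctr <- (shape + 1) / 2
    semi <- 0.45 * shape
    g <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                               z = seq_len(shape[3])))
    r <- sqrt(((g[, 1] - ctr[1]) / semi[1])^2 + ((g[, 2] - ctr[2]) / semi[2])^2 +
                ((g[, 3] - ctr[3]) / semi[3])^2)
    brain <- array(r <= 1, shape)
    csf <- array(r <= 1 & r > 0.88, shape)
    wm <- array(r <= 0.55, shape)
    gm <- array(r <= 0.88 & r > 0.55, shape)

    gm_index <- mask_coords(gm)
    n_gm <- nrow(gm_index)
    if (n_gm < n_rois) {
      abort_mefc("shape too small: %d GM voxels cannot host %d contiguous ROIs",
                 n_gm, n_rois)
    }

    # multi-source region growing: contiguous, non-overlapping GM parcels
    centers <- sample.int(n_gm, n_rois)
    nbrs <- neighbor_list(gm_index, shape, scheme = 6)
    lab <- integer(n_gm)
    queues <- lapply(centers, function(i) i)
    lab[centers] <- seq_len(n_rois)
    while (any(lengths(queues) > 0)) {
      for (k in seq_len(n_rois)) {
        q <- queues[[k]]
        if (!length(q)) next
        v <- q[[1]]
        queues[[k]] <- q[-1]
        for (u in nbrs[[v]]) {
          if (lab[u] == 0L) {
            lab[u] <- k
            queues[[k]] <- c(queues[[k]], u)
          }
        }
      }
    }
    # mop up voxels unreachable under 6-connectivity (rare disconnected spurs)
    if (any(lab == 0L)) {
      nbrs26 <- neighbor_list(gm_index, shape, scheme = 26)
      for (pass in 1:10) {
        todo <- which(lab == 0L)
        if (!length(todo)) break
        for (v in todo) {
          nl <- lab[nbrs26[[v]]]
          nl <- nl[nl > 0L]
          if (length(nl)) lab[v] <- nl[[1]]
        }
      }
      if (any(lab == 0L)) {
        far <- which(lab == 0L)
        for (v in far) {
          d2 <- rowSums((gm_index[centers, , drop = FALSE] -
                           matrix(gm_index[v, ], n_rois, 3, byrow = TRUE))^2)
          lab[v] <- which.min(d2)
        }
      }
    }
    labels <- array(0L, shape)
    labels[gm_index] <- lab

    # subcortical = innermost parcels by mean ellipsoidal radius
    roi_r <- vapply(seq_len(n_rois), function(k) {
      mean(r[which(gm)[lab == k]])
    }, 1.0)
    cls <- rep("cortical", n_rois)
    if (n_subcortical > 0) {
      cls[order(roi_r)[seq_len(min(n_subcortical, n_rois))]] <- "subcortical"
    }
    tab <- tibble::tibble(label = seq_len(n_rois),
                          name = sprintf("roi%03d", seq_len(n_rois)),
                          class = cls)
    affine <- default_affine(c(3, 3, 3), shape)
    parc <- parcellation(labels, tab, affine)

    # ground truth maps
    t2s <- array(0, shape)
    t2s[gm] <- runif(sum(gm), t2s_gm[1], t2s_gm[2])
    t2s[wm] <- runif(sum(wm), t2s_wm[1], t2s_wm[2])
    t2s[csf] <- runif(sum(csf), t2s_csf[1], t2s_csf[2])
    # inferior-edge dropout cap (short T2*)
    gm_z <- gm_index[, 3]
    dropout <- array(FALSE, shape)
    cap <- gm_index[gm_z <= stats::quantile(gm_z, 0.15), , drop = FALSE]
    dropout[cap] <- TRUE
    t2s[dropout] <- runif(sum(dropout), t2s_dropout[1], t2s_dropout[2])
    s0 <- array(0, shape)
    s0[brain] <- runif(sum(brain), s0_range[1], s0_range[2])

    brain_index <- mask_coords(brain)
    loadings <- matrix(0, n_gm, n_rois)
    loadings[cbind(seq_len(n_gm), lab)] <- 1
    drift_coeffs <- cbind(rnorm(nrow(brain_index), 0, 0.01),
                          rnorm(nrow(brain_index), 0, 0.005))

    list(
      parcellation = parc,
      tissue_masks = list(brain = brain, gm = gm, wm = wm, csf = csf),
      ground_truth = list(
        t2s_map = t2s, s0_map = s0,
        network_loadings = loadings, gm_index = gm_index,
        brain_index = brain_index, drift_coeffs = drift_coeffs,
        noise_sd = noise_sd, session_stability = session_stability,
        physio_freqs_hz = physio_freqs_hz, dropout_mask = dropout
      )
    )
  })
}

#' Latent network time courses with a target cross-correlation
#'
#' White Gaussian draws are mixed to the requested correlation, temporally
#' smoothed with a small Gaussian kernel (identical filter on every channel,
#' which preserves cross-correlation) to give BOLD-like slow structure, and
#' re-standardised columnwise.
#'
#' @param n_t Number of time points.
#' @param C Target K x K correlation matrix (symmetric, unit diagonal, PSD).
#' @param seed Integer seed; pass `NULL` to use the current RNG state.
#' @param smooth_sd Temporal kernel SD in samples.
#' @return An n_t x K matrix, columns zero mean / unit SD.
#' @export
generate_latents <- function(n_t, C, seed = NULL, smooth_sd = 1.5) {
  check_corr_psd(C)
  K <- nrow(C)
  run <- function() {
    Z <- matrix(rnorm(n_t * K), n_t, K)
    e <- eigen(C, symmetric = TRUE)
    M <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), K) %*% t(e$vectors)
    X <- Z %*% M
    if (smooth_sd > 0) {
      half <- max(1L, ceiling(4 * smooth_sd))
      kern <- stats::dnorm(-half:half, sd = smooth_sd)
      X <- apply(X, 2, smooth_1d, kern = kern)
    }
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    X
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Edge-renormalised 1D convolution
#' @noRd
smooth_1d <- function(x, kern) {
  n <- length(x)
  half <- (length(kern) - 1) / 2
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- stats::filter(xp, kern, sides = 2)[(half + 1):(half + n)]
  den <- stats::filter(wp, kern, sides = 2)[(half + 1):(half + n)]
  as.numeric(num / den)
}

#' @noRd
check_corr_psd <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) abort_mefc("network_corr must be square")
  if (max(abs(C - t(C))) > 1e-8) abort_mefc("network_corr must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-8) abort_mefc("network_corr must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort_mefc("network_corr is not positive semi-definite (min eigenvalue %.3g)",
               min(ev))
  }
  invisible(TRUE)
}

#' Simulate one multi-echo session from a phantom anatomy
#'
#' Signal model per brain voxel v:
#' \deqn{S_v(t, TE) = S0_v e^{-TE \cdot R2^*_v(t)} (1 + d_v(t) + p(t)) + \epsilon_v(t)}
#' with \eqn{R2^*_v(t) = 1/T2^*_v + (A / T2^*_v)\sum_k L_{vk} n_k(t)} for GM
#' voxels (A = `bold_amplitude`, a fractional R2* modulation), polynomial
#' drift d, sinusoidal physiological nuisance p, and white Gaussian noise.
#' Background (non-brain) voxels contain noise only.
#'
#' @param anatomy Result of [make_phantom_anatomy()].
#' @param acq An [acquisition_spec()].
#' @param network_corr Target latent-network correlation matrix (defaults to
#'   identity of size = number of parcels).
#' @param bold_amplitude Fractional R2* effect size of the latent networks.
#' @param seed Integer seed.
#' @param latents Optional pre-computed latent matrix (n_volumes x K); used by
#'   [make_study()] to impose between-session stability.
#' @param drift_on,physio_on Toggle nuisance components.
#' @param noise_sd Override the anatomy's thermal noise SD.
#' @param physio_amplitude Fractional amplitude of each physio sinusoid.
#' @return List with `me` (a [multi_echo_series()]), `motion` (tibble, 3
#'   translations mm + 3 rotations deg), and `latents` (the latent matrix
#'   actually used).
#' @export
simulate_session <- function(anatomy, acq, network_corr = NULL,
                             bold_amplitude = 0.02, seed = 1, latents = NULL,
                             drift_on = TRUE, physio_on = TRUE,
                             noise_sd = NULL, physio_amplitude = 0.005) {
  gt <- anatomy$ground_truth
  K <- ncol(gt$network_loadings)
  if (is.null(network_corr)) network_corr <- diag(K)
  check_corr_psd(network_corr)
  if (ncol(network_corr) != K) {
    abort_mefc("network_corr dimension %d != number of networks %d",
               ncol(network_corr), K)
  }
  noise_sd <- noise_sd %||% gt$noise_sd
  n_t <- acq$n_volumes
  shape <- dim(gt$t2s_map)

  withr::with_seed(seed, {
    if (is.null(latents)) latents <- generate_latents(n_t, network_corr, seed = NULL)
    if (nrow(latents) != n_t) abort_mefc("latents must have %d rows", n_t)

    bidx <- gt$brain_index
    n_b <- nrow(bidx)
    t2s_b <- gt$t2s_map[bidx]
    s0_b <- gt$s0_map[bidx]
    # R2*(t): baseline + TE-dependent BOLD term at GM voxels
    R2 <- matrix(1 / t2s_b, n_b, n_t)
    gm_in_brain <- match(
      paste(gt$gm_index[, 1], gt$gm_index[, 2], gt$gm_index[, 3]),
      paste(bidx[, 1], bidx[, 2], bidx[, 3])
    )
    if (bold_amplitude != 0) {
      bold <- gt$network_loadings %*% t(latents)  # n_gm x n_t
      R2[gm_in_brain, ] <- R2[gm_in_brain, ] +
        (bold_amplitude / t2s_b[gm_in_brain]) * bold
    }
    # multiplicative nuisance: per-voxel polynomial drift + shared physio
    tt <- seq(0, by = acq$tr_ms / 1000, length.out = n_t)
    x <- if (n_t > 1) seq(-1, 1, length.out = n_t) else 0
    mult <- matrix(1, n_b, n_t)
    if (drift_on) {
      mult <- mult + gt$drift_coeffs[, 1] %o% x +
        gt$drift_coeffs[, 2] %o% (0.5 * (3 * x^2 - 1))
    }
    if (physio_on && length(gt$physio_freqs_hz)) {
      p <- rep(0, n_t)
      for (f in gt$physio_freqs_hz) {
        p <- p + physio_amplitude * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
      }
      mult <- mult + matrix(p, n_b, n_t, byrow = TRUE)
    }

    data <- vector("list", length(acq$te_ms))
    flat_idx <- bidx[, 1] + (bidx[, 2] - 1) * shape[1] +
      (bidx[, 3] - 1) * shape[1] * shape[2]
    for (e in seq_along(acq$te_ms)) {
      te <- acq$te_ms[e]
      sig <- s0_b * exp(-te * R2) * mult
      vol <- matrix(rnorm(prod(shape) * n_t, 0, noise_sd), prod(shape), n_t)
      vol[flat_idx, ] <- vol[flat_idx, ] + sig
      data[[e]] <- array(vol, c(shape, n_t))
    }

    brain <- array(FALSE, shape)
    brain[bidx] <- TRUE
    me <- multi_echo_series(data, te_ms = acq$te_ms, tr_ms = acq$tr_ms,
                            mask = brain,
                            affine = default_affine(acq$voxel_mm, shape))

    # smooth low-amplitude random-walk motion traces (never applied to images)
    mo <- vapply(1:6, function(j) {
      step <- if (j <= 3) 0.005 else 0.003
      w <- cumsum(rnorm(n_t, 0, step))
      smooth_1d(w, stats::dnorm(-8:8, sd = 2))
    }, numeric(n_t))
    motion <- tibble::as_tibble(as.data.frame(mo))
    names(motion) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                       "rot_x_deg", "rot_y_deg", "rot_z_deg")

    list(me = me, motion = motion, latents = latents)
  })
}

#' Generate a full synthetic two-visit MB/MBME study
#'
#' Every subject gets a timepoint-1 session; the first `n_repeat` subjects get
#' a timepoint-2 session reusing the same anatomy with latent network signals
#' redrawn at the anatomy's `session_stability` (timepoint-2 latents are
#' `s * tp1 + sqrt(1 - s^2) * fresh`, so stability 1 reproduces them exactly).
#' Each session carries both an MB-like acquisition (TR 650 ms, TE 30 ms) and
#' an MBME-like acquisition (TR 900 ms, TE 11/30/49 ms).
#'
#' @param n_subjects,n_repeat Study size; `n_repeat <= n_subjects`.
#' @param scale Factor applied to the full-study volume counts (554 MB / 400
#'   MBME), floored at 20 volumes; grid size is set by `shape`.
#' @param seed Integer seed for the whole study.
#' @param shape,n_rois,n_subcortical Passed to [make_phantom_anatomy()].
#' @param session_stability Between-session latent correlation in \[0, 1\].
#' @param network_corr Latent correlation structure (default identity).
#' @param bold_amplitude_mb,bold_amplitude_mbme Fractional R2* effect per
#'   acquisition condition.
#' @param ... Further arguments to [make_phantom_anatomy()].
#' @return A `synthetic_study`: list with `design` (tibble from
#'   [study_design()]), `anatomy` (per subject), `sessions` (per session_id:
#'   list with `MB` and `MBME`, each holding `me`, `motion`, `latents`), and
#'   `params`.
#' @export
make_study <- function(n_subjects = 29, n_repeat = 18, scale = 1, seed = 1,
                       shape = c(20, 20, 10), n_rois = 8, n_subcortical = 2,
                       session_stability = 0.8, network_corr = NULL,
                       bold_amplitude_mb = 0.02, bold_amplitude_mbme = 0.02,
                       ...) {
  design <- study_design(n_subjects, n_repeat)
  n_mb <- max(20L, as.integer(round(554 * scale)))
  n_mbme <- max(20L, as.integer(round(400 * scale)))
  acqs <- list(MB = mb_acquisition(n_volumes = n_mb),
               MBME = mbme_acquisition(n_volumes = n_mbme))
  amp <- c(MB = bold_amplitude_mb, MBME = bold_amplitude_mbme)

  anatomy <- list()
  sessions <- list()
  subjects <- unique(design$subject)
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    sub_seed <- (seed + 7919L * si) %% 2147483647L
    anat <- make_phantom_anatomy(shape = shape, n_rois = n_rois, seed = sub_seed,
                                 n_subcortical = n_subcortical,
                                 session_stability = session_stability, ...)
    anatomy[[sub]] <- anat
    K <- ncol(anat$ground_truth$network_loadings)
    C <- network_corr %||% diag(K)
    tps <- sort(unique(design$timepoint[design$subject == sub]))
    lat1 <- list()
    for (tp in tps) {
      sid <- sprintf("%s_tp%d", sub, tp)
      ses <- list(subject = sub, timepoint = tp)
      for (a in c("MB", "MBME")) {
        acq <- acqs[[a]]
        lseed <- (sub_seed + 13L * tp + if (a == "MB") 1L else 2L) %% 2147483647L
        if (tp == 1L) {
          lat <- generate_latents(acq$n_volumes, C, seed = lseed)
          lat1[[a]] <- lat
        } else {
          s <- session_stability
          fresh <- generate_latents(acq$n_volumes, C, seed = lseed)
          lat <- s * lat1[[a]] + sqrt(1 - s^2) * fresh
        }
        ses[[a]] <- simulate_session(anat, acq, network_corr = C,
                                     bold_amplitude = amp[[a]],
                                     seed = (lseed + 101L) %% 2147483647L,
                                     latents = lat)
      }
      sessions[[sid]] <- ses
    }
  }
  structure(list(design = design, anatomy = anatomy, sessions = sessions,
                 params = list(scale = scale, seed = seed,
                               session_stability = session_stability,
                               n_volumes = c(MB = n_mb, MBME = n_mbme))),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d subjects, %d sessions (%d MB + %d MBME acquisitions)\n",
              length(x$anatomy), length(x$sessions),
              sum(x$design$acquisition == "MB"),
              sum(x$design$acquisition == "MBME")))
  invisible(x)
}

#' Construct an exactly-known fixture for FCD algorithms
#'
#' Plants disjoint blocks of voxels that share one time series (plus tiny
#' jitter) in a field of independent noise, and returns the lFCD/gFCD maps
#' that follow by construction: within-block correlations exceed the
#' threshold, everything else falls below it. The construction is verified
#' against the full correlation matrix; if any background/cross-block pair
#' reaches the threshold for the drawn seed, the draw is repeated with a
#' deterministically advanced seed.
#'
#' @param shape Length-3 grid; the mask is the full grid.
#' @param blocks List of n x 3 integer matrices of voxel coordinates;
#'   pairwise disjoint.
#' @param n_volumes Time points (>= 30 recommended).
#' @param seed Integer seed.
#' @param r_thr Threshold the expectations are built for (default 0.6).
#' @param neighbor_scheme Connectivity for the expected lFCD (default 26).
#' @return List: `bold` (a [bold_series()]), `expected_lfcd`,
#'   `expected_gfcd` (integer arrays; lFCD self-inclusive, gFCD
#'   self-exclusive), and `r_thr`.
#' @export
make_fcd_testcase <- function(shape, blocks, n_volumes = 200, seed = 1,
                              r_thr = 0.6, neighbor_scheme = 26) {
  shape <- as.integer(shape)
  n_vox <- prod(shape)
  lin <- function(co) co[, 1] + (co[, 2] - 1) * shape[1] +
    (co[, 3] - 1) * shape[1] * shape[2]
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "integer"
    b
  })
  all_lin <- unlist(lapply(blocks, lin))
  if (anyDuplicated(all_lin)) abort_mefc("blocks overlap: they must be pairwise disjoint")

  for (attempt in 0:19) {
    use_seed <- (seed + 1000L * attempt) %% 2147483647L
    Y <- withr::with_seed(use_seed, {
      Y <- matrix(rnorm(n_volumes * n_vox), n_volumes, n_vox)
      for (b in blocks) {
        shared <- rnorm(n_volumes)
        for (j in lin(b)) Y[, j] <- shared + rnorm(n_volumes, 0, 1e-3)
      }
      Y
    })
    R <- cor(Y)
    inblock <- matrix(FALSE, n_vox, n_vox)
    for (b in blocks) {
      jj <- lin(b)
      inblock[jj, jj] <- TRUE
    }
    diag(inblock) <- TRUE
    ok_in <- all(R[inblock] >= r_thr + 0.02)
    ok_out <- all(abs(R[!inblock]) < r_thr - 0.02)
    if (ok_in && ok_out) {
      lfcd <- array(1L, shape)
      gfcd <- array(0L, shape)
      for (b in blocks) {
        sz <- nrow(b)
        bm <- array(FALSE, shape)
        bm[b] <- TRUE
        comp <- label_components(bm, scheme = neighbor_scheme)
        csize <- tabulate(comp[comp > 0])
        lfcd[b] <- csize[comp[b]]
        gfcd[b] <- sz - 1L
      }
      bold <- bold_series(array(t(Y), c(shape, n_volumes)), tr_ms = 900)
      return(list(bold = bold, expected_lfcd = lfcd, expected_gfcd = gfcd,
                  r_thr = r_thr, seed_used = use_seed))
    }
  }
  abort_mefc("could not realise the fixture below threshold after 20 seeds")
}
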