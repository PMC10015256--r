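#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain in one validated structure:
#' the acquisition block (TR, TEs, discard), the denoising block (pipeline
#' flavour, motion model, detrend order, band edges, smoothing), the analysis
#' block (seed labels, threshold grids, FCD conventions, FDR level, cluster
#' alpha and iterations) and the RNG seeds of the stochastic stages.
#'
#' @param tr_ms,te_ms Acquisition timing (ms).
#' @param discard_seconds Initial discard (s).
#' @param pipeline "standard" or "component_injected" (the latter expects
#'   component regressors at run time).
#' @param motion_params 6 or 12.
#' @param detrend_order Polynomial order.
#' @param f_lo,f_hi Band edges (Hz).
#' @param fwhm_mm Smoothing kernel.
#' @param combine_scheme Echo combination scheme.
#' @param seed_labels Integer labels used for seed maps.
#' @param r_thr_grid Dice threshold grid.
#' @param fcd_r_thr FCD correlation threshold.
#' @param fcd_neighbor_scheme 6/18/26.
#' @param fdr_q FDR level.
#' @param cluster_alpha,cluster_n_iter,cluster_voxel_p Cluster MC settings.
#' @param seed RNG seed for stochastic stages.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(tr_ms = 900, te_ms = c(11, 30, 49),
                            discard_seconds = 10,
                            pipeline = c("standard", "component_injected"),
                            motion_params = 12, detrend_order = 3,
                            f_lo = 0.01, f_hi = 0.1, fwhm_mm = 4,
                            combine_scheme = "t2star_weighted",
                            seed_labels = integer(0),
                            r_thr_grid = c(0.3, 0.4, 0.5, 0.6),
                            fcd_r_thr = 0.6, fcd_neighbor_scheme = 26,
                            fdr_q = 0.05, cluster_alpha = 0.05,
                            cluster_n_iter = 1000, cluster_voxel_p = 0.001,
                            seed = 1) {
  cfg <- list(
    acquisition = list(tr_ms = tr_ms, te_ms = te_ms,
                       discard_seconds = discard_seconds),
    denoising = list(pipeline = match.arg(pipeline),
                     motion_params = motion_params,
                     detrend_order = detrend_order, f_lo = f_lo, f_hi = f_hi,
                     fwhm_mm = fwhm_mm, combine_scheme = combine_scheme),
    analysis = list(seed_labels = seed_labels, r_thr_grid = r_thr_grid,
                    fcd_r_thr = fcd_r_thr,
                    fcd_neighbor_scheme = fcd_neighbor_scheme, fdr_q = fdr_q,
                    cluster_alpha = cluster_alpha,
                    cluster_n_iter = cluster_n_iter,
                    cluster_voxel_p = cluster_voxel_p),
    seeds = list(seed = seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its legal range and the band edges against
#' the acquisition's Nyquist frequency, before any computation runs.
#'
#' @param cfg A `pipeline_config` (or plain list with the same blocks).
#' @return `cfg`, invisibly, or an error.
#' @export
validate_config <- function(cfg) {
  a <- cfg$acquisition; d <- cfg$denoising; an <- cfg$analysis
  if (a$tr_ms <= 0) abort_mefc("config: tr_ms must be positive")
  if (any(a$te_ms <= 0) || is.unsorted(a$te_ms, strictly = TRUE)) {
    abort_mefc("config: te_ms must be positive and strictly increasing")
  }
  nyq <- 1 / (2 * a$tr_ms / 1000)
  if (d$f_lo >= d$f_hi) abort_mefc("config: f_lo must be below f_hi")
  if (d$f_hi >= nyq) {
    abort_mefc("config: f_hi (%g Hz) is not below Nyquist (%g Hz) for TR %g ms",
               d$f_hi, nyq, a$tr_ms)
  }
  if (!d$motion_params %in% c(6, 12)) abort_mefc("config: motion_params must be 6 or 12")
  if (d$detrend_order < 0) abort_mefc("config: detrend_order must be >= 0")
  if (d$fwhm_mm < 0) abort_mefc("config: fwhm_mm must be >= 0")
  if (an$fcd_r_thr <= -1 || an$fcd_r_thr > 1) abort_mefc("config: fcd_r_thr out of range")
  if (any(an$r_thr_grid <= -1 | an$r_thr_grid > 1)) abort_mefc("config: r_thr_grid out of range")
  if (!an$fcd_neighbor_scheme %in% c(6, 18, 26)) abort_mefc("config: bad neighbor scheme")
  if (an$fdr_q <= 0 || an$fdr_q >= 1) abort_mefc("config: fdr_q must lie in (0, 1)")
  if (an$cluster_alpha <= 0 || an$cluster_alpha > 1) abort_mefc("config: cluster_alpha out of range")
  invisible(cfg)
}

#' Run the full session pipeline and write a result bundle
#'
#' Executes discard -> combine -> tSNR -> smooth -> detrend/nuisance
#' regression -> bandpass -> seed maps / ROI matrix / lFCD / gFCD on one
#' session's inputs, writing every intermediate plus a machine-readable
#' manifest (stage list, config hash, df ledger, seeds). Re-running with an
#' identical config and inputs reproduces the outputs bit-identically.
#'
#' @param config A [pipeline_config()].
#' @param me A [multi_echo_series()] (single-echo series are combined by
#'   pass-through summation).
#' @param out_dir Output directory (created if needed).
#' @param motion Optional motion table aligned with the raw series.
#' @param parcellation Optional [parcellation()] for seed maps / ROI matrix.
#' @param wm,csf Optional tissue masks for nuisance regression.
#' @param gm Optional grey-matter mask for FCD summaries.
#' @param components Optional component time courses (component_injected
#'   pipeline).
#' @param run_fcd Compute lFCD/gFCD maps (default TRUE).
#' @return The manifest list, invisibly; all outputs land in `out_dir`.
#' @export
run_pipeline <- function(config, me, out_dir, motion = NULL,
                         parcellation = NULL, wm = NULL, csf = NULL,
                         gm = NULL, components = NULL, run_fcd = TRUE) {
  validate_config(config)
  if (config$denoising$pipeline == "component_injected" && is.null(components)) {
    abort_mefc("component_injected pipeline requires component time courses")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)
  fail <- function(stage, e) {
    abort_mefc("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  # combine
  b <- run_stage("combine", {
    if (length(me$data) >= 2 &&
        config$denoising$combine_scheme != "summation") {
      fit <- fit_t2star(me)
      write_volume(fit$t2s_map, file.path(out_dir, "t2star.nii.gz"), me$affine)
      write_volume(fit$s0_map, file.path(out_dir, "s0.nii.gz"), me$affine)
      combine_echoes(me, fit, scheme = config$denoising$combine_scheme)
    } else {
      combine_echoes(me, scheme = "summation")
    }
  })
  note("combine")

  b <- run_stage("discard", discard_initial(b, config$acquisition$discard_seconds))
  note("discard")
  n_t0 <- dim(me$data[[1]])[4]
  n_t <- dim(b$data)[4]

  ts_map <- run_stage("tsnr", tsnr(b, scale_by_sqrt_ntp = TRUE))
  write_volume(ts_map, file.path(out_dir, "tsnr_sqrtntp.nii.gz"), b$affine)
  note("tsnr")

  trim <- function(tab) {
    if (is.null(tab)) return(NULL)
    m <- as.matrix(tab)
    if (nrow(m) == n_t0) m[(n_t0 - n_t + 1):n_t0, , drop = FALSE] else m
  }
  tiss <- if (!is.null(wm) && !is.null(csf)) {
    run_stage("tissue_signals", tissue_signals(b, wm, csf))
  }
  b <- run_stage("smooth", smooth_gaussian(b, config$denoising$fwhm_mm))
  note("smooth")

  mo <- trim(motion)
  if (!is.null(mo) && config$denoising$motion_params == 12 && ncol(mo) == 6) {
    mo <- motion_derivatives(mo)
  }
  des <- run_stage("design", build_design(
    nuisance_set(motion = mo, tissue_signals = tiss,
                 components = trim(components),
                 detrend_order = config$denoising$detrend_order), n_t))
  b <- run_stage("regress", regress_nuisance(b, des))
  note("regress")
  b <- run_stage("bandpass", bandpass(b, config$denoising$f_lo, config$denoising$f_hi))
  note("bandpass")
  write_volume(b$data, file.path(out_dir, "denoised.nii.gz"), b$affine)

  results <- list(df_loss = des$df_loss)
  if (!is.null(parcellation)) {
    for (sl in config$analysis$seed_labels) {
      cm <- run_stage(sprintf("seed_map(%d)", sl), seed_map(b, parcellation, sl))
      write_volume(cm$r_map, file.path(out_dir, sprintf("seedmap_%03d.nii.gz", sl)),
                   b$affine)
    }
    if (length(config$analysis$seed_labels)) note("seed_maps")
    rmat <- run_stage("roi_matrix", roi_matrix(b, parcellation))
    write_matrix_tsv(rmat, file.path(out_dir, "roi_matrix.tsv"))
    note("roi_matrix")
    results$n_rois <- nrow(rmat$r)
  }
  if (run_fcd) {
    lm_ <- run_stage("lfcd", lfcd(b, config$analysis$fcd_r_thr,
                                  config$analysis$fcd_neighbor_scheme))
    gm_ <- run_stage("gfcd", gfcd(b, config$analysis$fcd_r_thr))
    write_volume(lm_$counts, file.path(out_dir, "lfcd.nii.gz"), b$affine)
    write_volume(gm_$counts, file.path(out_dir, "gfcd.nii.gz"), b$affine)
    note("fcd")
    if (!is.null(gm)) {
      results$gm_mean_lfcd <- summarize_fcd(lm_, as_mask(gm) & b$mask)
      results$gm_mean_gfcd <- summarize_fcd(gm_, as_mask(gm) & b$mask)
    }
  }

  manifest <- list(
    stages = stages,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    df_ledger = b$df_ledger,
    df_total = df_total(b),
    seeds = config$seeds,
    results = results
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
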