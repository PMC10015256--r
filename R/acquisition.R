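#' Describe an EPI acquisition
#'
#' Bundles repetition time, echo times, volume count and voxel geometry.
#' The number of volumes can be given directly or derived from a nominal scan
#' duration as `round(duration / TR)` (a six-minute scan at TR 650 ms yields
#' 554 volumes; at TR 900 ms, 400 volumes).
#'
#' @param tr_ms Repetition time in milliseconds (> 0).
#' @param te_ms Echo times in milliseconds, strictly increasing and positive.
#' @param n_volumes Integer volume count (>= 1). If `NULL`, derived from
#'   `duration_s`.
#' @param voxel_mm Voxel edge lengths in mm (length 3).
#' @param duration_s Nominal scan duration in seconds.
#' @return An `acquisition_spec` object (a list with the fields above).
#' @examples
#' mbme_acquisition()$n_volumes  # 400
#' mb_acquisition()$n_volumes    # 554
#' @export
acquisition_spec <- function(tr_ms, te_ms, n_volumes = NULL,
                             voxel_mm = c(3, 3, 3), duration_s = 360) {
  if (tr_ms <= 0) abort_mefc("tr_ms must be positive")
  if (any(te_ms <= 0) || is.unsorted(te_ms, strictly = TRUE)) {
    abort_mefc("te_ms must be positive and strictly increasing")
  }
  if (is.null(n_volumes)) n_volumes <- as.integer(round(duration_s * 1000 / tr_ms))
  if (n_volumes < 1) abort_mefc("n_volumes must be >= 1")
  structure(
    list(tr_ms = tr_ms, te_ms = te_ms, n_volumes = as.integer(n_volumes),
         voxel_mm = voxel_mm, duration_s = duration_s),
    class = "acquisition_spec"
  )
}

#' @rdname acquisition_spec
#' @export
mb_acquisition <- function(duration_s = 360, n_volumes = NULL) {
  acquisition_spec(tr_ms = 650, te_ms = 30, n_volumes = n_volumes,
                   duration_s = duration_s)
}

#' @rdname acquisition_spec
#' @export
mbme_acquisition <- function(duration_s = 360, n_volumes = NULL) {
  acquisition_spec(tr_ms = 900, te_ms = c(11, 30, 49), n_volumes = n_volumes,
                   duration_s = duration_s)
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> TR %g ms, TE %s ms, %d volumes, voxel %s mm\n",
              x$tr_ms, paste(x$te_ms, collapse = "/"), x$n_volumes,
              paste(x$voxel_mm, collapse = "x")))
  invisible(x)
}

#' Session table for a two-visit test-retest study
#'
#' Enumerates the sessions of a study in which every subject is scanned once
#' and a subset returns for a repeat visit, each session comprising one
#' single-echo MB acquisition and one multi-echo MBME acquisition. The default
#' design (29 subjects, 18 repeats) yields 47 sessions.
#'
#' @param n_subjects Number of subjects (all have timepoint 1).
#' @param n_repeat Number of subjects with a repeat session (timepoint 2);
#'   must not exceed `n_subjects`.
#' @return A tibble with one row per session x acquisition: columns
#'   `subject`, `timepoint`, `acquisition` ("MB"/"MBME"), `session_id`,
#'   `scan_number` (the session's ordinal for that subject).
#' @examples
#' d <- study_design(29, 18)
#' length(unique(d$session_id))  # 47
#' @export
study_design <- function(n_subjects = 29, n_repeat = 18) {
  if (n_repeat > n_subjects) abort_mefc("n_repeat (%d) exceeds n_subjects (%d)",
                                        n_repeat, n_subjects)
  subj <- sprintf("sub%02d", seq_len(n_subjects))
  rows <- list()
  for (s in seq_len(n_subjects)) {
    tps <- if (s <= n_repeat) 1:2 else 1L
    for (tp in tps) {
      for (acq in c("MB", "MBME")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = subj[s], timepoint = as.integer(tp), acquisition = acq,
          session_id = sprintf("%s_tp%d", subj[s], tp),
          scan_number = as.integer(tp)
        )
      }
    }
  }
  do.call(rbind, rows)
}
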