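#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti keeping the voxel-to-world affine with the data.
#' Integer volumes round-trip bit-exactly; floating volumes to single
#' precision unless `datatype = "double"`.
#'
#' @param x 3D or 4D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world transform (RAS+, mm).
#' @param datatype RNifti datatype string (default "auto": integer arrays as
#'   int32, otherwise float64 so floating data round-trips exactly).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, affine = NULL, datatype = "auto") {
  if (is.null(affine)) affine <- default_affine(shape = dim(x)[1:3])
  if (identical(datatype, "auto")) {
    datatype <- if (is.integer(x) || is.logical(x)) "int32" else "double"
  }
  img <- RNifti::asNifti(x * 1)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @return `read_volume`: list with `data` (array) and `affine`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  list(data = data, affine = aff)
}

#' Write a multi-echo series as per-echo NIfTI files
#'
#' Files are named `<prefix>_echo<k>.nii.gz`; a JSON sidecar
#' `<prefix>_meta.json` records `te_ms` and `tr_ms`.
#'
#' @param me A [multi_echo_series()].
#' @param prefix Path prefix.
#' @return Character vector of written volume paths, invisibly.
#' @export
write_multi_echo <- function(me, prefix) {
  paths <- character(length(me$data))
  for (e in seq_along(me$data)) {
    paths[e] <- sprintf("%s_echo%d.nii.gz", prefix, e)
    write_volume(me$data[[e]], paths[e], me$affine)
  }
  jsonlite::write_json(list(te_ms = me$te_ms, tr_ms = me$tr_ms),
                       sprintf("%s_meta.json", prefix),
                       auto_unbox = FALSE, digits = NA)
  invisible(paths)
}

#' Read a multi-echo series written by [write_multi_echo()]
#'
#' @param prefix Path prefix used when writing.
#' @param mask Optional 3D mask (default: all voxels).
#' @return A [multi_echo_series()].
#' @export
read_multi_echo <- function(prefix, mask = NULL) {
  meta <- jsonlite::read_json(sprintf("%s_meta.json", prefix), simplifyVector = TRUE)
  paths <- sprintf("%s_echo%d.nii.gz", prefix, seq_along(meta$te_ms))
  vols <- lapply(paths, read_volume)
  multi_echo_series(lapply(vols, `[[`, "data"), te_ms = meta$te_ms,
                    tr_ms = meta$tr_ms, mask = mask, affine = vols[[1]]$affine)
}

#' Write a motion table as 6-column TSV
#'
#' @param motion t x 6 table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion_tsv <- function(motion, path) {
  write.table(as.data.frame(motion), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t"))
}

#' Write a correlation matrix as TSV with ROI name headers
#'
#' @param cm A `connectivity_matrix` or plain named matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(cm, path) {
  R <- if (inherits(cm, "connectivity_matrix")) cm$r else cm
  df <- data.frame(roi = rownames(R), R, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  R <- as.matrix(df[, -1, drop = FALSE])
  rownames(R) <- df[[1]]
  R
}
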