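#' Integer-labelled parcellation with a label table
#'
#' @param labels 3D integer array; 0 is background.
#' @param table Data frame with columns `label` (unique positive integers),
#'   `name`, and optionally `class` (one of "cortical", "subcortical",
#'   "seed"); defaults to "cortical".
#' @param affine 4x4 voxel-to-world transform.
#' @return A `parcellation` object.
#' @export
parcellation <- function(labels, table, affine = NULL) {
  if (length(dim(labels)) != 3L) abort_mefc("labels must be a 3D array")
  table <- validate_label_table(table)
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0]
  missing <- setdiff(present, table$label)
  if (length(missing)) {
    abort_mefc("labels present in volume but absent from table: %s",
               paste(missing, collapse = ", "))
  }
  if (any(labels < 0)) abort_mefc("labels must be non-negative")
  if (is.null(affine)) affine <- default_affine(shape = dim(labels))
  structure(list(labels = labels, table = table, affine = affine),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %s, %d labels (%s)\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$table),
              paste(sprintf("%d %s", table(x$table$class),
                            names(table(x$table$class))), collapse = ", ")))
  invisible(x)
}

#' @noRd
validate_label_table <- function(table) {
  if (!all(c("label", "name") %in% names(table))) {
    abort_mefc("label table needs columns 'label' and 'name'")
  }
  if (nrow(table) == 0) abort_mefc("label table is empty")
  lab <- table$label
  if (any(is.na(suppressWarnings(as.numeric(lab)))) ||
      any(as.numeric(lab) != round(as.numeric(lab)))) {
    abort_mefc("non-integer label value(s): %s",
               paste(lab[is.na(suppressWarnings(as.integer(lab))) |
                           as.numeric(lab) != round(as.numeric(lab))],
                     collapse = ", "))
  }
  lab <- as.integer(lab)
  dup <- lab[duplicated(lab)]
  if (length(dup)) abort_mefc("duplicated label value(s): %s",
                              paste(unique(dup), collapse = ", "))
  if (is.null(table$class)) table$class <- "cortical"
  bad <- setdiff(unique(table$class), c("cortical", "subcortical", "seed"))
  if (length(bad)) abort_mefc("unknown ROI class(es): %s", paste(bad, collapse = ", "))
  tibble::tibble(label = lab, name = as.character(table$name),
                 class = as.character(table$class))
}

#' Read a parcellation label table from TSV
#'
#' Expects a header row with columns `label`, `name` and optionally `class`.
#' Duplicate or non-integer labels are rejected with an explicit error.
#'
#' @param path Path to a tab-separated file.
#' @return A validated tibble (label, name, class).
#' @export
read_label_table <- function(path) {
  tab <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) abort_mefc("cannot parse label table '%s': %s",
                                   path, conditionMessage(e))
  )
  if (nrow(tab) == 0) abort_mefc("label table '%s' has no rows", path)
  validate_label_table(tab)
}

#' Write a label table to TSV
#'
#' @param table A label table (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(table, path) {
  table <- validate_label_table(table)
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
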