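# CSV readers/writers with schema validation, and FSL-style bval/bvec
# protocol files.  CSV dialect: comma-separated, UTF-8, mandatory header,
# "." decimal separator.

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          "tractsa_schema_error", columns = missing)
  invisible(df)
}

subject_columns <- function() {
  c("subject_id", "group", "age", "sex", "wmh_present",
    names(neurocognitive_measures()))
}

#' Write the subject table
#'
#' Columns: subject_id, group, age, sex, wmh_present, score_1..score_9.
#' The lesion list-column, if present, is not serialized here (see
#' [write_lesions_csv()]).
#'
#' @param records subject data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_subjects_csv <- function(records, path) {
  utils::write.csv(records[, subject_columns()], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the subject table
#'
#' @param path CSV path.
#' @return data.frame with validated schema; `group` kept as character.
#' @export
read_subjects_csv <- function(path) {
  if (!file.exists(path))
    abort(sprintf("no such file: %s", path), "tractsa_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  check_columns(df, subject_columns(), path)
  bad <- setdiff(unique(df$group), c("CTL", "SCD", "ACTL"))
  if (length(bad))
    abort(sprintf("%s: unknown group label(s): %s", path,
                  paste(bad, collapse = ", ")), "tractsa_schema_error")
  df$wmh_present <- as.logical(df$wmh_present)
  df
}

#' Write a vertex dataset as CSV
#'
#' Rows are subjects (first column `subject_id`), remaining columns
#' `v1..vV` hold per-vertex values.
#'
#' @param dataset a [vertex_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vertex_csv <- function(dataset, path) {
  df <- data.frame(subject_id = dataset$subjects,
                   dataset$values, check.names = FALSE)
  colnames(df) <- c("subject_id", paste0("v", seq_len(ncol(dataset$values))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a vertex dataset CSV
#'
#' @param path CSV path.
#' @param tract tract name (default: file stem).
#' @return a [vertex_dataset()].
#' @export
read_vertex_csv <- function(path, tract = NULL) {
  if (!file.exists(path))
    abort(sprintf("no such file: %s", path), "tractsa_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  check_columns(df, "subject_id", path)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (!length(vcols))
    abort(sprintf("%s: no vertex columns (v1, v2, ...)", path),
          "tractsa_schema_error", columns = "v1")
  vals <- as.matrix(df[, vcols, drop = FALSE])
  if (any(!is.finite(vals)))
    abort(sprintf("%s: non-numeric or missing vertex values", path),
          "tractsa_schema_error")
  vertex_dataset(tract %||% sub("\\.csv$", "", basename(path)),
                 df$subject_id, unname(vals))
}

#' Write pooled lesion table
#'
#' @param records subject table with `wmh_lesions` list-column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lesions_csv <- function(records, path) {
  les <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    d <- records$wmh_lesions[[i]]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    cbind(subject_id = records$subject_id[i], d)
  }))
  if (is.null(les))
    les <- cbind(subject_id = character(0), empty_lesions())
  utils::write.csv(les, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write FSL-style bval and bvec files
#'
#' `bval`: one whitespace-separated row of b-values; `bvec`: three rows
#' (x, y, z components).
#'
#' @param protocol a [dwi_protocol()].
#' @param bval_path,bvec_path file paths.
#' @return `write_bvals_bvecs`: invisible NULL; `read_bvals_bvecs`: a
#'   `dwi_protocol`.
#' @export
write_bvals_bvecs <- function(protocol, bval_path, bvec_path) {
  writeLines(paste(fmt_num(protocol$bvals), collapse = " "), bval_path)
  writeLines(apply(t(protocol$bvecs), 1, function(r)
    paste(fmt_num(r), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' @rdname write_bvals_bvecs
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3)
    abort(sprintf("%s: bvec file must have exactly 3 rows", bvec_path),
          "tractsa_schema_error")
  dwi_protocol(bvals, t(bv))
}
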