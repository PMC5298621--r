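# Delimited-text interchange formats: three-phase records, reference tables
# and beat matrices.

#' Read and write three-phase detector records as CSV
#'
#' Column layout `time_s, v1, v2, v3` with a header row; the sampling rate is
#' inferred from the time column and validated to be uniform on read.
#'
#' @param path CSV file path.
#' @return `read_three_phase()` returns the record tibble; the writer returns
#'   `path` invisibly.
#' @export
read_three_phase <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "v1", "v2", "v3")
  if (!all(need %in% names(rec))) {
    stop_fbg("expected columns %s", "fbgbp_invalid_input",
             paste(need, collapse = ", "))
  }
  infer_fs(rec$time_s)
  tibble::as_tibble(rec[, need])
}

#' @rdname read_three_phase
#' @param record A three-phase record tibble.
#' @export
write_three_phase <- function(record, path) {
  readr::write_csv(record[, c("time_s", "v1", "v2", "v3")], path)
  invisible(path)
}

#' Read and write reference-pressure tables as CSV
#'
#' Column layout `record_id, subject_id, reference_bp_mmHg, split`.
#'
#' @param references Data frame with the columns above (a `bp_ref_mmHg`
#'   column is accepted and renamed on write).
#' @param path CSV file path.
#' @export
write_references <- function(references, path) {
  refs <- tibble::as_tibble(references)
  if ("bp_ref_mmHg" %in% names(refs) && !"reference_bp_mmHg" %in% names(refs)) {
    refs <- dplyr::rename(refs, reference_bp_mmHg = "bp_ref_mmHg")
  }
  readr::write_csv(refs[, c("record_id", "subject_id", "reference_bp_mmHg", "split")],
                   path)
  invisible(path)
}

#' @rdname write_references
#' @export
read_references <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write beat matrices as CSV
#'
#' One row per normalized beat, `L` waveform columns (`b001`, `b002`, ...);
#' when reference pressures are attached the final column is
#' `reference_bp_mmHg`.
#'
#' @param beat_data Beat table with a `beat` list column (and optionally
#'   `bp_ref_mmHg`), or a plain numeric matrix.
#' @param path CSV file path.
#' @export
write_beat_matrix <- function(beat_data, path) {
  if (is.data.frame(beat_data) && "beat" %in% names(beat_data)) {
    X <- do.call(rbind, lapply(beat_data$beat, as.numeric))
    y <- beat_data$bp_ref_mmHg %||% beat_data$reference_bp_mmHg
  } else {
    X <- as.matrix(beat_data)
    y <- NULL
  }
  out <- tibble::as_tibble(X, .name_repair = ~ sprintf("b%03d", seq_along(.x)))
  if (!is.null(y)) out$reference_bp_mmHg <- y
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_beat_matrix
#' @return `read_beat_matrix()` returns a tibble with a `beat` list column
#'   and, when present, `bp_ref_mmHg`.
#' @export
read_beat_matrix <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  bcols <- grep("^b[0-9]+$", names(raw), value = TRUE)
  if (!length(bcols)) {
    stop_fbg("no beat columns (b001, ...) found", "fbgbp_invalid_input")
  }
  X <- as.matrix(raw[, bcols])
  out <- tibble::tibble(beat = lapply(seq_len(nrow(X)), function(i) unname(X[i, ])))
  if ("reference_bp_mmHg" %in% names(raw)) {
    out$bp_ref_mmHg <- raw$reference_bp_mmHg
  }
  out
}
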