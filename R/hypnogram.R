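#' Construct a hypnogram
#'
#' A hypnogram is the night's time course of sleep stages: one label from
#' \{W, N1, N2, N3, R\} per scoring epoch (30 s by convention).  Stored as
#' a tibble with columns `epoch` (0-based) and `stage` (factor with the
#' canonical level order), plus attributes `epoch_seconds` and
#' `subject_id`.
#'
#' @param stages Character vector (or factor) of stage labels.
#' @param epoch_seconds Epoch duration in seconds (default 30).
#' @param subject_id Subject identifier.
#' @return A tibble of class `hypnogram`.
#' @examples
#' hypnogram(c("W", "N1", "N2", "N2", "R"))
#' @export
hypnogram <- function(stages, epoch_seconds = 30, subject_id = "subject") {
  stages <- as.character(stages)
  if (length(stages) < 1) abort("hypnogram needs at least one epoch")
  assert_stage_labels(stages)
  out <- tibble::tibble(
    epoch = seq_along(stages) - 1L,
    stage = factor(stages, levels = sleep_stages())
  )
  structure(out, class = c("hypnogram", class(out)),
            epoch_seconds = epoch_seconds, subject_id = as.character(subject_id))
}

#' Read and write hypnogram files
#'
#' The on-disk dialect is a CSV with header `epoch,stage`, one row per
#' 30-s epoch, `epoch` 0-based and `stage` in \{W, N1, N2, N3, R\}.
#'
#' @param path CSV file path.
#' @param hyp A [hypnogram()].
#' @param subject_id Subject id to attach on read.
#' @return `read_hypnogram()` a [hypnogram()]; `write_hypnogram()` `path`,
#'   invisibly.
#' @export
read_hypnogram <- function(path, subject_id = "subject") {
  if (!file.exists(path)) abort(sprintf("hypnogram file not found: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort(sprintf("unreadable hypnogram: %s", path)))
  if (nrow(df) == 0) abort(sprintf("hypnogram file is empty: %s", path))
  if (!all(c("epoch", "stage") %in% names(df)))
    abort("hypnogram CSV must have columns 'epoch' and 'stage'")
  bad <- which(!df$stage %in% sleep_stages())
  if (length(bad) > 0)
    abort(sprintf("unknown stage label '%s' at row %d of %s",
                  df$stage[bad[1]], bad[1], path))
  hypnogram(df$stage[order(df$epoch)], subject_id = subject_id)
}

#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  write.csv(data.frame(epoch = hyp$epoch, stage = as.character(hyp$stage)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' CSV dialect: header `subject_id,age_group,osa_class,spo2`; `age_group`
#' in \{younger, older\}, `osa_class` in \{healthy, mtom, severe\}, `spo2`
#' an optional oxygen-saturation scalar in (0, 100] (empty allowed).
#'
#' @param path CSV file path.
#' @return A tibble with the four columns, `spo2` numeric (NA if empty).
#' @export
read_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_group", "osa_class", "spo2")
  if (!all(need %in% names(df)))
    abort(sprintf("metadata CSV must have columns %s", paste(need, collapse = ",")))
  bad_age <- setdiff(unique(df$age_group), c("younger", "older"))
  if (length(bad_age)) abort(sprintf("unknown age_group: %s", paste(bad_age, collapse = ",")))
  bad_osa <- setdiff(unique(df$osa_class), c("healthy", "mtom", "severe"))
  if (length(bad_osa)) abort(sprintf("unknown osa_class: %s", paste(bad_osa, collapse = ",")))
  df$spo2 <- suppressWarnings(as.numeric(df$spo2))
  if (any(!is.na(df$spo2) & (df$spo2 <= 0 | df$spo2 > 100)))
    abort("spo2 values must lie in (0, 100]")
  tibble::as_tibble(df)
}

#' @rdname read_metadata
#' @param meta Metadata tibble as returned by [read_metadata()].
#' @export
write_metadata <- function(meta, path) {
  write.csv(meta[, c("subject_id", "age_group", "osa_class", "spo2")],
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
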