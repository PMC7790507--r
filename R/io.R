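# Plain-text session persistence: a delimited matrix (delta-HbO2 rows stacked
# over delta-Hb rows) plus a JSON sidecar with sampling rate, channel indices,
# per-sample labels and, when available, injected-artifact ground truth.

#' Write a session to a directory as delimited text + JSON sidecar
#'
#' @param session Either a `hemo_recording` or a [generate_session()] result
#'   (list with `recording` and `truth`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  rec <- if (inherits(session, "hemo_recording")) session else session$recording
  truth <- if (inherits(session, "hemo_recording")) NULL else session$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  X <- rbind(rec$dHbO2, rec$dHb)
  utils::write.table(format(X, digits = 10, trim = TRUE, scientific = TRUE),
                     file.path(dir, "matrix.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(sampling_rate = rec$sampling_rate,
               n_channels = nrow(rec$dHbO2),
               retained_channels = rec$retained_channels,
               labels_per_sample = rec$labels_per_sample)
  if (!is.null(truth))
    meta$ground_truth <- list(
      class_order = truth$class_order,
      injected_spikes = truth$injected_spikes,
      injected_steps = truth$injected_steps)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Persist an inner distance matrix as delimited text with a JSON header
#'
#' @param dm A `distance_matrix` (from [session_distance_matrix()] or
#'   [subject_distance_matrix()]).
#' @param path Output file for the values; the header is written alongside as
#'   `<path>.json` (kind and normalizing dimension).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  utils::write.table(format(dm$values, digits = 10, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(kind = dm$kind, d_norm = dm$d_norm,
                            n = nrow(dm$values)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path File holding the values (with `<path>.json` alongside).
#' @return A `distance_matrix`.
#' @export
read_distance_matrix <- function(path) {
  V <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(V) <- NULL
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_distance_matrix(V, hdr$kind, hdr$d_norm)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing `matrix.tsv` and `meta.json`.
#' @return A [hemo_recording()]; any stored ground truth is attached as
#'   attribute `ground_truth`.
#' @export
read_session <- function(dir) {
  X <- as.matrix(utils::read.table(file.path(dir, "matrix.tsv"), sep = "\t"))
  dimnames(X) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  nch <- meta$n_channels
  rec <- hemo_recording(X[seq_len(nch), , drop = FALSE],
                        X[nch + seq_len(nch), , drop = FALSE],
                        sampling_rate = meta$sampling_rate,
                        labels_per_sample = meta$labels_per_sample,
                        retained_channels = meta$retained_channels)
  if (!is.null(meta$ground_truth))
    attr(rec, "ground_truth") <- meta$ground_truth
  rec
}
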