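# Label transfer across sessions (entropic G-W on within-session geometry)
# and across subjects (FG-W barycenter of the source subject's sessions).

#' Binarize a coupling by column argmax
#'
#' In each column the largest entry is set to 1 and all others to 0; ties are
#' broken toward the lowest row index.
#'
#' @param T A `transport_plan` or nonnegative matrix.
#' @return 0/1 matrix with exactly one 1 per column.
#' @export
binarize_coupling <- function(T) {
  Tm <- if (inherits(T, "transport_plan")) T$matrix else as.matrix(T)
  if (any(Tm < -1e-12)) stop("coupling must be nonnegative", call. = FALSE)
  out <- matrix(0L, nrow(Tm), ncol(Tm))
  sel <- apply(Tm, 2L, which.max)       # which.max: first (lowest) index on ties
  out[cbind(sel, seq_len(ncol(Tm)))] <- 1L
  out
}

#' Transfer source labels through a binarized coupling
#'
#' Target segment j receives the label of the source row selected in column j
#' (equivalently `t(T_cp) %*% y` for one-hot columns).
#'
#' @param T_cp 0/1 matrix from [binarize_coupling()].
#' @param source_labels Vector with one entry per row of `T_cp`.
#' @return Vector of length `ncol(T_cp)`.
#' @export
transfer_labels <- function(T_cp, source_labels) {
  if (nrow(T_cp) != length(source_labels))
    stop("rows of T_cp must match source_labels", call. = FALSE)
  sel <- apply(T_cp, 2L, which.max)
  source_labels[sel]
}

#' Alignment configuration
#'
#' Bundles the tunable parameters shared by the alignment front-ends.
#'
#' @param w Segment window length (samples).
#' @param shrinkage Covariance shrinkage weight for [segment_features()].
#' @param lam,lam_rel Entropic weight (absolute, or relative to the gradient
#'   scale when `lam` is `NULL`).
#' @param alpha FG-W structure/feature trade-off.
#' @param anneal Use the annealed initialization of the quadratic solvers.
#' @param max_outer Outer iteration cap of the quadratic solvers.
#' @return List of class `align_config`.
#' @export
align_config <- function(w = 60L, shrinkage = 0.05, lam = NULL, lam_rel = 5e-3,
                         alpha = 0.5, anneal = TRUE, max_outer = 100L) {
  structure(list(w = as.integer(w), shrinkage = shrinkage, lam = lam,
                 lam_rel = lam_rel, alpha = alpha, anneal = anneal,
                 max_outer = max_outer),
            class = "align_config")
}

as_segment_set <- function(x) {
  if (inherits(x, "segment_set")) return(x)
  if (inherits(x, "hemo_recording"))
    stop("segment the recording first with segment_recording()", call. = FALSE)
  stop("expected a segment_set", call. = FALSE)
}

new_alignment_result <- function(predicted, plan, binarized, source_id,
                                 target_id, cfg) {
  structure(list(predicted_labels = predicted, coupling = plan,
                 binarized_coupling = binarized, source_id = source_id,
                 target_id = target_id, config_snapshot = cfg),
            class = "alignment_result")
}

# Core of Algorithm 1 given precomputed inner distance matrices.
align_from_matrices <- function(Cm, Cn, source_labels, cfg,
                                source_id = NA, target_id = NA) {
  Cmv <- dm_values(Cm); Cnv <- dm_values(Cn)
  if (max(Cmv) <= 1e-8 || max(Cnv) <= 1e-8)   # zero up to sqrtm noise
    stop("degenerate (all-zero) inner distance matrix", call. = FALSE)
  plan <- entropic_gw(Cmv, Cnv, lam = cfg$lam, lam_rel = cfg$lam_rel,
                      max_outer = cfg$max_outer, anneal = cfg$anneal)
  bc <- binarize_coupling(plan)
  pred <- transfer_labels(bc, source_labels)
  new_alignment_result(pred, plan, bc, source_id, target_id, cfg)
}

#' Session-by-session label transfer (Algorithm 1)
#'
#' Computes the within-session inner distance matrices (Hellinger distance of
#' segment covariances plus mean-difference term, normalized by the stacked
#' channel count), couples them with entropic Gromov-Wasserstein, binarizes
#' the plan by column argmax, and transfers the source labels.  Source and
#' target may have different channel counts and different segment counts; no
#' interpolation is performed.
#'
#' @param source A labeled `segment_set` (its `labels` are used).
#' @param target An (unlabeled) `segment_set`.
#' @param cfg An [align_config()].
#' @return An `alignment_result` with `predicted_labels` for the target
#'   segments, the soft `coupling`, the `binarized_coupling`, and a config
#'   snapshot.
#' @export
align_sessions <- function(source, target, cfg = align_config()) {
  source <- as_segment_set(source); target <- as_segment_set(target)
  if (is.null(source$labels)) stop("source must be labeled", call. = FALSE)
  Fs <- segment_features(source, cfg$shrinkage)
  Ft <- segment_features(target, cfg$shrinkage)
  Cm <- session_distance_matrix(Fs)
  Cn <- session_distance_matrix(Ft)
  align_from_matrices(Cm, Cn, source$labels, cfg,
                      source_id = source$session_id,
                      target_id = target$session_id)
}

round_to_classes <- function(x, classes) {
  # nearest valid class, half-up
  cl <- sort(classes)
  snapped <- floor(x + 0.5)
  pmin(pmax(snapped, min(cl)), max(cl))
}

#' Build the FG-W barycenter of a source subject's labeled sessions
#'
#' Uses the mean-free (covariance-only) inner metric per session and even
#' session weights; the barycenter's real-valued label features are rounded
#' half-up to the nearest valid class for downstream transfer.
#'
#' @param sessions List of labeled `segment_set`s (all sessions of the source
#'   subject).
#' @param cfg An [align_config()].
#' @return A `barycenter` with an extra `labels` field (integer classes).
#' @export
build_source_barycenter <- function(sessions, cfg = align_config()) {
  stopifnot(length(sessions) >= 1L)
  sessions <- lapply(sessions, as_segment_set)
  labsets <- lapply(sessions, function(s) sort(unique(s$labels)))
  if (length(unique(vapply(labsets, paste, collapse = ",", ""))) != 1L)
    stop("sessions have inconsistent label alphabets", call. = FALSE)
  Cs <- list(); fs <- list()
  for (k in seq_along(sessions)) {
    if (is.null(sessions[[k]]$labels))
      stop("all source sessions must be labeled", call. = FALSE)
    Fk <- segment_features(sessions[[k]], cfg$shrinkage)
    Cs[[k]] <- subject_distance_matrix(Fk)
    fs[[k]] <- as.numeric(sessions[[k]]$labels)
  }
  bary <- fgw_barycenter(Cs, fs, alpha = cfg$alpha, lam = cfg$lam,
                         lam_rel = cfg$lam_rel)
  bary$labels <- round_to_classes(bary$features, labsets[[1]])
  bary
}

#' Subject-by-subject label transfer (Algorithm 2)
#'
#' Builds the FG-W barycenter of the source subject's labeled sessions once,
#' then aligns it to each target session's mean-free inner distance matrix
#' with entropic G-W and transfers the (rounded) barycenter labels.
#'
#' @param source_sessions List of labeled `segment_set`s (source subject).
#' @param target_sessions List of `segment_set`s (target subject).
#' @param cfg An [align_config()].
#' @param barycenter Optional precomputed [build_source_barycenter()] output
#'   (reused across target subjects).
#' @return List of `alignment_result`, one per target session.
#' @export
align_subjects <- function(source_sessions, target_sessions,
                           cfg = align_config(), barycenter = NULL) {
  if (is.null(barycenter))
    barycenter <- build_source_barycenter(source_sessions, cfg)
  Cb <- barycenter$distance_matrix
  lapply(target_sessions, function(ts) {
    ts <- as_segment_set(ts)
    Ft <- segment_features(ts, cfg$shrinkage)
    Ct <- subject_distance_matrix(Ft)
    align_from_matrices(Cb, Ct, barycenter$labels, cfg,
                        source_id = "barycenter", target_id = ts$session_id)
  })
}

#' Merge four workload levels into low/high classes
#'
#' Levels 0 and 1 map to `"low"`, levels 2 and 3 map to `"high"`.
#'
#' @param labels Integer vector with values in `{0, 1, 2, 3}`.
#' @return Factor with levels `c("low", "high")`.
#' @export
merge_labels <- function(labels) {
  if (!all(labels %in% 0:3))
    stop("labels must lie in {0, 1, 2, 3}", call. = FALSE)
  factor(ifelse(labels <= 1L, "low", "high"), levels = c("low", "high"))
}
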