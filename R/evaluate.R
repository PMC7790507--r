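# Scoring: confusion matrices, inverse-variance weighted summaries,
# significance tests, and the full session-/subject-mode evaluation grid.

coerce_class_int <- function(x) {
  if (is.factor(x)) as.integer(x) - 1L else as.integer(x)
}

#' Row-normalized confusion matrix
#'
#' Entry (r, c) is the fraction of truth-r segments predicted as c.  Rows
#' without support are left at zero.
#'
#' @param true_labels,predicted_labels Equal-length vectors (integer classes
#'   `0..K-1`, or factors with identical level sets).
#' @param K Number of classes.
#' @return `K x K` numeric matrix with rows summing to 1 (where supported).
#' @export
confusion_matrix <- function(true_labels, predicted_labels, K) {
  if (length(true_labels) == 0L) stop("empty input", call. = FALSE)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  tr <- coerce_class_int(true_labels); pr <- coerce_class_int(predicted_labels)
  if (any(tr >= K) || any(pr >= K) || any(tr < 0) || any(pr < 0))
    stop("labels must lie in 0..K-1", call. = FALSE)
  M <- matrix(0, K, K)
  for (i in seq_along(tr)) M[tr[i] + 1L, pr[i] + 1L] <- M[tr[i] + 1L, pr[i] + 1L] + 1
  rs <- rowSums(M)
  M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
  M
}

#' Fraction of correctly transferred labels
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @return Scalar in `[0, 1]`.
#' @export
alignment_accuracy <- function(true_labels, predicted_labels) {
  mean(coerce_class_int(true_labels) == coerce_class_int(predicted_labels))
}

#' Inverse-variance weighted mean and standard error
#'
#' Weights each per-subject mean by the inverse of its variance
#' (`w_i = 1 / sd_i^2`); the standard error is `sqrt(1 / sum(w))`.
#'
#' @param values Per-subject mean accuracies.
#' @param sds Per-subject standard deviations (strictly positive; apply a
#'   floor upstream for degenerate subjects).
#' @return List with `weighted_mean` and `weighted_se`.
#' @export
weighted_summary <- function(values, sds) {
  if (length(values) != length(sds)) stop("length mismatch", call. = FALSE)
  if (any(sds <= 0))
    stop("all sds must be positive; apply a floor for zero-variance subjects",
         call. = FALSE)
  w <- 1 / sds^2
  list(weighted_mean = sum(w * values) / sum(w),
       weighted_se = sqrt(1 / sum(w)))
}

#' Significance tests for alignment accuracies
#'
#' One-sample t-test of the accuracies against the chance level, and optional
#' paired t-tests (e.g. raw vs cleaned data, or method vs method).  P-values
#' are two-sided.  Degenerate (zero-variance) comparisons are flagged instead
#' of tested.
#'
#' @param accuracies Numeric vector (length >= 2).
#' @param chance Chance-level accuracy (default 0.25 for four balanced
#'   classes).
#' @param paired_a,paired_b Optional equal-length vectors for a paired t-test.
#' @return Data frame with columns `name`, `statistic`, `df`, `p_value`,
#'   `flag`.
#' @export
significance_tests <- function(accuracies, chance = 0.25,
                               paired_a = NULL, paired_b = NULL) {
  rows <- list()
  one <- function(name, x, mu, paired = FALSE) {
    if (length(x) < 2L) stop("n >= 2 required per test", call. = FALSE)
    if (var(x) == 0) {
      if (!paired && x[1] == mu)
        return(data.frame(name = name, statistic = 0, df = length(x) - 1L,
                          p_value = 1, flag = "degenerate"))
      return(data.frame(name = name, statistic = NA_real_,
                        df = length(x) - 1L, p_value = NA_real_,
                        flag = "zero-variance"))
    }
    tt <- t.test(x, mu = mu)
    data.frame(name = name, statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value, flag = "")
  }
  rows[[1]] <- one("one-sample vs chance", accuracies, chance)
  if (!is.null(paired_a)) {
    if (is.null(paired_b) || length(paired_a) != length(paired_b))
      stop("paired vectors must have equal length", call. = FALSE)
    rows[[2]] <- one("paired difference", paired_a - paired_b, 0, paired = TRUE)
  }
  do.call(rbind, rows)
}

# Per-session precomputation shared by both evaluation modes: segment labels
# plus the two inner distance matrices (the Hellinger part is computed once).
prepare_session_geometry <- function(rec, cfg, session_id = NA, subject_id = NA) {
  seg <- segment_recording(rec, cfg$w, session_id = session_id,
                           subject_id = subject_id)
  fe <- segment_features(seg, cfg$shrinkage)
  Hg <- hellinger_gram(fe)
  Mg <- unname(as.matrix(stats::dist(t(fe$means))))
  list(labels = seg$labels,
       C_session = new_distance_matrix((Hg + Mg) / fe$d, "session", fe$d),
       C_subject = new_distance_matrix(Hg / fe$d, "subject", fe$d))
}

#' Precompute per-session geometry for a whole study
#'
#' Computes, for every admissible session, the segment labels and both inner
#' distance matrices (the pairwise Hellinger part is computed once and shared
#' between the two metrics).  The result can be passed to [experiment_grid()]
#' to evaluate both modes without recomputing features.
#'
#' @inheritParams experiment_grid
#' @return List with `geoms` (per subject, per session) and `excluded`.
#' @export
prepare_study_geometry <- function(dataset, cfg = align_config(), tara = NULL,
                                   reject_channels = FALSE) {
  subjects <- dataset$subjects
  S <- length(subjects)
  geoms <- vector("list", S)
  excluded <- data.frame(subject = integer(0), session = integer(0))
  for (s in seq_len(S)) {
    sess <- subjects[[s]]$sessions
    gs <- vector("list", length(sess))
    for (m in seq_along(sess)) {
      rec <- sess[[m]]$recording
      if (reject_channels) {
        rj <- reject_noisy_channels(rec)
        if (!session_admissible(rec, rj$removed)) {
          excluded <- rbind(excluded, data.frame(subject = s, session = m))
          next
        }
        rec <- rj$recording
      }
      if (!is.null(tara)) rec <- tara_clean(rec, tara)
      gs[[m]] <- prepare_session_geometry(rec, cfg, session_id = m,
                                          subject_id = s)
    }
    geoms[[s]] <- gs
  }
  list(geoms = geoms, excluded = excluded)
}

#' Run the full alignment evaluation grid
#'
#' Session mode aligns every ordered pair of admissible sessions within each
#' subject (Algorithm 1); subject mode builds one barycenter per source
#' subject and aligns it to every session of every other subject
#' (Algorithm 2).  Accuracies use the generator's ground-truth labels.
#'
#' @param dataset A [simulate_study()] result (or a list with the same
#'   shape: `subjects[[s]]$sessions[[m]]$recording` carrying labels).
#' @param mode `"sessions"` or `"subjects"`.
#' @param cfg An [align_config()].
#' @param merge Merge workload levels into low/high before scoring.
#' @param tara Optional [tara_params()] (or per-species list) applied to every
#'   recording before segmentation.
#' @param reject_channels Apply spectral channel rejection and the 60%
#'   session-admissibility rule; inadmissible sessions contribute no pairs and
#'   are listed in the report.
#' @param sd_floor Floor applied to per-subject accuracy standard deviations
#'   before inverse-variance weighting.
#' @param geometry Optional [prepare_study_geometry()] result; when supplied,
#'   `tara` and `reject_channels` are ignored (they were applied when the
#'   geometry was built).
#' @return List of class `evaluation_report`: `pairs` (per-alignment
#'   accuracies), `confusion` (average row-normalized confusion matrix),
#'   `per_subject` (mean/sd), `weighted` (inverse-variance mean and SE),
#'   `tests` (t-test vs chance over per-subject means), `excluded`.
#' @export
experiment_grid <- function(dataset, mode = c("sessions", "subjects"),
                            cfg = align_config(), merge = FALSE, tara = NULL,
                            reject_channels = FALSE, sd_floor = 1e-3,
                            geometry = NULL) {
  mode <- match.arg(mode)
  if (is.null(geometry))
    geometry <- prepare_study_geometry(dataset, cfg, tara = tara,
                                       reject_channels = reject_channels)
  geoms <- geometry$geoms
  excluded <- geometry$excluded
  S <- length(geoms)
  K <- if (merge) 2L else length(unique(unlist(
    lapply(geoms, function(gs) lapply(gs, function(g) if (!is.null(g)) g$labels)))))
  score <- function(truth, pred) {
    if (merge) { truth <- merge_labels(truth); pred <- merge_labels(pred) }
    list(acc = alignment_accuracy(truth, pred),
         conf = confusion_matrix(truth, pred, K))
  }

  pairs <- list(); confs <- list()
  if (mode == "sessions") {
    for (s in seq_len(S)) {
      gs <- geoms[[s]]
      ok <- which(!vapply(gs, is.null, logical(1)))
      for (m in ok) for (n in setdiff(ok, m)) {
        res <- align_from_matrices(gs[[m]]$C_session, gs[[n]]$C_session,
                                   gs[[m]]$labels, cfg,
                                   source_id = m, target_id = n)
        sc <- score(gs[[n]]$labels, res$predicted_labels)
        pairs[[length(pairs) + 1L]] <-
          data.frame(subject = s, source = m, target = n, accuracy = sc$acc)
        confs[[length(confs) + 1L]] <- sc$conf
      }
    }
  } else {
    for (s in seq_len(S)) {
      gs <- geoms[[s]]
      ok <- which(!vapply(gs, is.null, logical(1)))
      if (length(ok) == 0L) next
      bary <- fgw_barycenter(lapply(gs[ok], `[[`, "C_subject"),
                             lapply(gs[ok], function(g) as.numeric(g$labels)),
                             alpha = cfg$alpha, lam = cfg$lam,
                             lam_rel = cfg$lam_rel)
      bl <- round_to_classes(bary$features, sort(unique(gs[[ok[1]]]$labels)))
      for (t in setdiff(seq_len(S), s)) {
        gt <- geoms[[t]]
        for (n in which(!vapply(gt, is.null, logical(1)))) {
          res <- align_from_matrices(bary$distance_matrix, gt[[n]]$C_subject,
                                     bl, cfg, source_id = s, target_id = t)
          sc <- score(gt[[n]]$labels, res$predicted_labels)
          pairs[[length(pairs) + 1L]] <-
            data.frame(subject = s, source = s, target = t, session = n,
                       accuracy = sc$acc)
          confs[[length(confs) + 1L]] <- sc$conf
        }
      }
    }
  }
  pairs <- do.call(rbind, pairs)
  confusion <- Reduce(`+`, confs) / length(confs)
  agg_mean <- tapply(pairs$accuracy, pairs$subject, mean)
  agg_sd <- tapply(pairs$accuracy, pairs$subject, sd)
  per_subject <- data.frame(subject = as.integer(names(agg_mean)),
                            mean = as.numeric(agg_mean),
                            sd = as.numeric(agg_sd))
  per_subject$sd[is.na(per_subject$sd)] <- sd_floor
  wt <- weighted_summary(per_subject$mean, pmax(per_subject$sd, sd_floor))
  chance <- 1 / K
  tests <- if (nrow(per_subject) >= 2L)
    significance_tests(per_subject$mean, chance = chance) else NULL
  structure(list(mode = mode, merge = merge, pairs = pairs,
                 confusion = confusion, per_subject = per_subject,
                 weighted = wt, tests = tests, chance = chance,
                 excluded = excluded),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> mode=", x$mode,
      if (x$merge) " (merged low/high)", "\n", sep = "")
  cat("  alignments: ", nrow(x$pairs),
      "; mean accuracy ", signif(mean(x$pairs$accuracy), 4),
      "; weighted ", signif(x$weighted$weighted_mean, 4),
      " +/- ", signif(x$weighted$weighted_se, 3), "\n", sep = "")
  if (!is.null(x$tests))
    cat("  t vs chance ", signif(x$chance, 3), ": t=",
        signif(x$tests$statistic[1], 4), ", p=",
        format.pval(x$tests$p_value[1], digits = 3), "\n", sep = "")
  invisible(x)
}
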