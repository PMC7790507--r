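# Synthetic multichannel fNIRS generator with controllable domain shift.
#
# Each session follows the block protocol of a four-level n-back experiment:
# an initial baseline, one contiguous task block per workload level (order
# randomised per session), short rests between blocks, and a final baseline.
# Within a task block the d = 2 * n_channels stacked hemoglobin rows
# (delta-HbO2 over delta-Hb, in micromolar) are drawn from a stationary AR(1)
# process whose marginal covariance and mean are the class covariance and class
# mean, optionally perturbed at the session level (gain jitter, mean drift,
# channel dropout) and at the subject level (feature-space rotation, baseline
# offset, channel-set choice).  Slow sinusoidal trends, white noise, and
# sparse spike/step artifacts can be added on top, with the injected artifact
# signal returned as ground truth.

#' Configuration for the synthetic fNIRS generator
#'
#' @param n_channels Number of physical optode channels; each contributes one
#'   delta-HbO2 row and one delta-Hb row, so the stacked feature dimension is
#'   `d = 2 * n_channels`.
#' @param n_classes Number of workload levels (n-back levels 0..n_classes-1).
#' @param samples_per_task Samples per task block (default 1562, i.e. a 200 s
#'   block at 7.81 Hz).
#' @param sampling_rate Sampling rate in Hz.
#' @param class_covariances List of `d x d` symmetric positive-definite
#'   matrices (uM^2), one per class.  Defaults to a common base matrix
#'   deformed per class by scaling plus a low-rank perturbation, which keeps
#'   classes separable in Hellinger geometry by a tunable margin.
#' @param class_means List of d-vectors (uM), one per class.
#' @param session_shift List with `channel_dropout_probability` (each physical
#'   channel independently dropped for a session), `mean_drift_scale` (sd of a
#'   per-row additive offset shared by all classes of the session, uM) and
#'   `gain_jitter` (sd of a multiplicative per-channel gain perturbation).
#' @param subject_shift List with `rotation_angle_scale` (radians; sd of the
#'   Givens angles composing the subject's feature-space rotation),
#'   `baseline_offset_scale` (uM), `channel_set_size_range` (integer pair;
#'   the subject's channel subset size is drawn in this range) and
#'   `class_dispersion` (sd of the per-subject, per-class log-scale jitter and
#'   rank-one deformation of the class covariances; this is what makes the
#'   class geometry genuinely subject-specific, since a common rotation alone
#'   leaves the Hellinger inner metric unchanged).
#' @param trend_amplitude Amplitude scale of slow sinusoidal drifts (uM).
#' @param noise_sd White measurement noise sd (uM).
#' @param ar_coefficient Lag-1 autocorrelation of the within-block process.
#'   The innovation scale is chosen so the stationary covariance equals the
#'   class covariance.
#' @param baseline_head_s,rest_s Baseline and inter-task rest durations (s).
#' @param artifact_params List with `spike_rate` and `step_rate` (events per
#'   minute per row; 0 disables injection), `spike_amplitude` and
#'   `step_amplitude` (uM).
#' @param seed Integer seed; all randomness is a deterministic function of
#'   `(seed, subject_index, session_index)`.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_channels = 20L,
                             n_classes = 4L,
                             samples_per_task = 1562L,
                             sampling_rate = 7.81,
                             class_covariances = NULL,
                             class_means = NULL,
                             session_shift = list(channel_dropout_probability = 0.1,
                                                  mean_drift_scale = 0.2,
                                                  gain_jitter = 0.05),
                             subject_shift = list(rotation_angle_scale = 0.3,
                                                  baseline_offset_scale = 0.5,
                                                  channel_set_size_range = c(16L, 20L),
                                                  class_dispersion = 0.25),
                             trend_amplitude = 0.5,
                             noise_sd = 0.1,
                             ar_coefficient = 0.5,
                             baseline_head_s = 155,
                             rest_s = 30,
                             artifact_params = list(spike_rate = 0, spike_amplitude = 6,
                                                    step_rate = 0, step_amplitude = 4),
                             seed = 1L) {
  d <- 2L * as.integer(n_channels)
  if (is.null(class_covariances))
    class_covariances <- default_class_covariances(d, n_classes)
  if (is.null(class_means))
    class_means <- default_class_means(d, n_classes)
  cfg <- structure(list(
    n_channels = as.integer(n_channels), n_classes = as.integer(n_classes),
    samples_per_task = as.integer(samples_per_task), sampling_rate = sampling_rate,
    d = d, class_covariances = class_covariances, class_means = class_means,
    session_shift = session_shift, subject_shift = subject_shift,
    trend_amplitude = trend_amplitude, noise_sd = noise_sd,
    ar_coefficient = ar_coefficient,
    baseline_head_s = baseline_head_s, rest_s = rest_s,
    artifact_params = artifact_params, seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_channels >= 1L, cfg$n_classes >= 2L,
            cfg$samples_per_task >= 1L, cfg$sampling_rate > 0)
  if (length(cfg$class_covariances) != cfg$n_classes ||
      length(cfg$class_means) != cfg$n_classes)
    stop("class_covariances and class_means must have one entry per class",
         call. = FALSE)
  for (k in seq_len(cfg$n_classes)) {
    S <- cfg$class_covariances[[k]]
    if (!is.matrix(S) || nrow(S) != cfg$d || ncol(S) != cfg$d)
      stop("class covariance ", k, " must be a ", cfg$d, "x", cfg$d, " matrix",
           call. = FALSE)
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
      stop("class covariance ", k, " is not symmetric", call. = FALSE)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("class covariance ", k, " is not positive-definite", call. = FALSE)
    if (length(cfg$class_means[[k]]) != cfg$d)
      stop("class mean ", k, " must have length d = ", cfg$d, call. = FALSE)
  }
  rng <- cfg$subject_shift$channel_set_size_range
  if (!is.null(rng)) {
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 1L)
      stop("channel_set_size_range must be an increasing integer pair",
           call. = FALSE)
    if (rng[2] > cfg$n_channels)
      stop("channel_set_size_range exceeds n_channels", call. = FALSE)
  }
  ap <- cfg$artifact_params
  if (ap$spike_rate < 0 || ap$step_rate < 0)
    stop("artifact rates must be nonnegative", call. = FALSE)
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Default class covariance matrices
#'
#' A common exponentially-decaying base matrix (unit-scale variances of
#' 0.25 uM^2, lag correlation 0.5) scaled per class by `1 + 0.3 * n` and
#' deformed by a class-specific rank-one perturbation, so that every pair of
#' classes is separated in Hellinger geometry.
#'
#' @param d Stacked feature dimension.
#' @param n_classes Number of classes.
#' @return List of `d x d` SPD matrices.
#' @export
default_class_covariances <- function(d, n_classes) {
  base <- 0.25 * 0.5^abs(outer(seq_len(d), seq_len(d), "-"))
  lapply(seq_len(n_classes) - 1L, function(cl) {
    u <- cos(pi * (cl + 1) * seq_len(d) / d)
    u <- u / sqrt(sum(u^2))
    (1 + 0.3 * cl) * base + 0.35 * tcrossprod(u)
  })
}

#' Default class mean vectors
#'
#' Workload level n shifts the mean along a fixed smooth spatial pattern by
#' 0.4 uM per level, emulating graded prefrontal activation.
#'
#' @inheritParams default_class_covariances
#' @return List of d-vectors.
#' @export
default_class_means <- function(d, n_classes) {
  v <- sin(pi * seq_len(d) / (d + 1))
  v <- v / sqrt(sum(v^2))
  lapply(seq_len(n_classes) - 1L, function(cl) 0.4 * cl * v)
}

# Deterministic integer seed from a stream of nonnegative integers.
mix_seed <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 69069 + (as.numeric(x) + 12345)) %% 2147483647
  as.integer(s)
}

# Random rotation as a composition of Givens rotations on random coordinate
# pairs with N(0, angle_scale^2) angles; identity when angle_scale == 0.
random_rotation <- function(d, angle_scale) {
  Q <- diag(d)
  if (angle_scale <= 0) return(Q)
  for (g in seq_len(2L * d)) {
    ij <- sample.int(d, 2L)
    th <- rnorm(1L, sd = angle_scale)
    G <- diag(d)
    G[ij[1], ij[1]] <- cos(th); G[ij[2], ij[2]] <- cos(th)
    G[ij[1], ij[2]] <- -sin(th); G[ij[2], ij[1]] <- sin(th)
    Q <- G %*% Q
  }
  Q
}

# Draw the per-subject transform once per subject_index.
draw_subject_transform <- function(cfg, subject_index) {
  set.seed(mix_seed(cfg$seed, 9001L, subject_index))
  sh <- cfg$subject_shift
  d <- cfg$d
  Q <- random_rotation(d, sh$rotation_angle_scale)
  baseline <- if (sh$baseline_offset_scale > 0)
    rnorm(d, sd = sh$baseline_offset_scale) else numeric(d)
  rng <- sh$channel_set_size_range
  channels <- if (is.null(rng) || rng[2] >= cfg$n_channels && rng[1] >= cfg$n_channels) {
    seq_len(cfg$n_channels)
  } else {
    size <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    sort(sample.int(cfg$n_channels, size))
  }
  disp <- if (is.null(sh$class_dispersion)) 0 else sh$class_dispersion
  K <- cfg$n_classes
  avg_var <- mean(vapply(cfg$class_covariances,
                         function(S) mean(diag(S)), numeric(1)))
  class_scale <- exp(rnorm(K, sd = disp))
  class_dirs <- matrix(rnorm(d * K), d, K)
  class_dirs <- sweep(class_dirs, 2L, sqrt(colSums(class_dirs^2)), "/")
  class_amp <- abs(rnorm(K, sd = disp)) * avg_var   # PSD rank-one additions
  list(Q = Q, baseline = baseline, channels = channels,
       class_scale = class_scale, class_dirs = class_dirs,
       class_amp = class_amp, subject_index = subject_index)
}

#' Generate one synthetic fNIRS session
#'
#' @param config A [generator_config()].
#' @param session_index Nonnegative integer identifying the session; output is
#'   a deterministic function of `(config$seed, session_index)`.
#' @param subject_transform Optional subject-level transform as drawn by
#'   [generate_subject()]; `NULL` means an identity subject.
#'
#' @return A list with elements `recording` (a `hemo_recording`) and `truth`
#'   (ground truth: per-sample labels with baseline sentinel -1, injected
#'   artifact tables, retained channel indices, the class block order, and the
#'   transforms actually applied).
#' @export
generate_session <- function(config, session_index, subject_transform = NULL) {
  validate_generator_config(config)
  stopifnot(session_index >= 0)
  sub_idx <- if (is.null(subject_transform)) -1L else subject_transform$subject_index
  set.seed(mix_seed(config$seed, sub_idx, session_index))

  d <- config$d; nch <- config$n_channels; fs <- config$sampling_rate
  K <- config$n_classes
  n_base <- round(config$baseline_head_s * fs)
  n_rest <- round(config$rest_s * fs)
  n_task <- config$samples_per_task

  class_order <- sample.int(K) - 1L  # randomized task order, 0-based labels

  # subject transform (identity by default)
  Q <- if (is.null(subject_transform)) diag(d) else subject_transform$Q
  sub_baseline <- if (is.null(subject_transform)) numeric(d) else subject_transform$baseline
  sub_channels <- if (is.null(subject_transform)) seq_len(nch) else subject_transform$channels

  # session perturbations
  ss <- config$session_shift
  gain_ch <- 1 + if (ss$gain_jitter > 0) rnorm(nch, sd = ss$gain_jitter) else numeric(nch)
  gain <- rep(gain_ch, 2L)                       # both species rows of a channel
  drift <- if (ss$mean_drift_scale > 0) rnorm(d, sd = ss$mean_drift_scale) else numeric(d)

  # effective class parameters for this session: the subject transform first
  # rotates, rescales and deforms each class covariance, then the session's
  # gain jitter is applied
  covs <- lapply(seq_len(K), function(cl) {
    S <- Q %*% config$class_covariances[[cl]] %*% t(Q)
    if (!is.null(subject_transform)) {
      S <- subject_transform$class_scale[cl] * S +
        subject_transform$class_amp[cl] *
          tcrossprod(subject_transform$class_dirs[, cl])
    }
    (gain %o% gain) * S
  })
  mus <- lapply(config$class_means, function(m)
    gain * drop(Q %*% m + sub_baseline) + drift)
  base_cov <- (gain %o% gain) * (Q %*% config$class_covariances[[1]] %*% t(Q))
  base_mu <- gain * sub_baseline + drift
  chols <- lapply(covs, function(S) t(chol(S)))
  base_chol <- t(chol(base_cov))

  phi <- config$ar_coefficient
  draw_block <- function(n, Lc) {                  # centered stationary AR(1)
    Z <- matrix(rnorm(d * n), d, n)
    E <- Lc %*% Z
    if (phi > 0) {
      sc <- sqrt(1 - phi^2)
      for (t in 2:n) E[, t] <- phi * E[, t - 1] + sc * E[, t]
    }
    E
  }

  blocks <- list(); labels <- integer(0); mu_cols <- list()
  add_block <- function(n, Lc, mu, lab) {
    blocks[[length(blocks) + 1L]] <<- draw_block(n, Lc)
    mu_cols[[length(mu_cols) + 1L]] <<- matrix(mu, d, n)
    labels <<- c(labels, rep(lab, n))
  }
  add_block(n_base, base_chol, base_mu, -1L)
  for (k in seq_len(K)) {
    cl <- class_order[k]
    add_block(n_task, chols[[cl + 1L]], mus[[cl + 1L]], cl)
    if (k < K) add_block(n_rest, base_chol, base_mu, -1L)
  }
  add_block(n_base, base_chol, base_mu, -1L)
  X <- do.call(cbind, blocks)
  n_total <- ncol(X)
  # hemodynamic transitions are smooth: ramp the blockwise mean trajectory
  # with a raised-cosine window of about 8 s
  MU <- do.call(cbind, mu_cols)
  wl <- max(3L, round(8 * fs))
  ker <- (1 - cos(2 * pi * seq_len(wl) / (wl + 1))) / 2
  ker <- ker / sum(ker)
  half <- (wl - 1L) %/% 2L
  for (r in seq_len(d)) {
    padded <- c(rep(MU[r, 1], half), MU[r, ], rep(MU[r, n_total], wl - half - 1L))
    MU[r, ] <- stats::filter(padded, ker, sides = 1)[wl:(wl + n_total - 1L)]
  }
  X <- X + MU

  # slow sinusoidal trends (per row random frequency/phase/amplitude)
  if (config$trend_amplitude > 0) {
    tt <- seq_len(n_total) / fs
    f0 <- runif(d, 0.005, 0.02)
    ph <- runif(d, 0, 2 * pi)
    amp <- config$trend_amplitude * runif(d, 0.5, 1)
    X <- X + amp * sin(outer(2 * pi * f0, tt) + ph)
  }
  if (config$noise_sd > 0)
    X <- X + matrix(rnorm(d * n_total, sd = config$noise_sd), d, n_total)

  # channel dropout: a physical channel is dropped as a unit for the session
  keep <- sub_channels
  p_drop <- ss$channel_dropout_probability
  if (p_drop > 0) {
    kept <- keep[runif(length(keep)) >= p_drop]
    if (length(kept) >= 2L) keep <- kept
  }
  rows <- c(keep, keep + nch)
  rec <- hemo_recording(dHbO2 = X[keep, , drop = FALSE],
                        dHb = X[keep + nch, , drop = FALSE],
                        sampling_rate = fs, labels_per_sample = labels,
                        retained_channels = keep)

  spikes <- NULL; steps <- NULL
  ap <- config$artifact_params
  if (ap$spike_rate > 0 || ap$step_rate > 0) {
    inj <- inject_artifacts(rec, ap, seed = mix_seed(config$seed, 4099L, sub_idx, session_index))
    rec <- inj$recording
    spikes <- inj$injected_spikes
    steps <- inj$injected_steps
  }

  truth <- list(labels_per_sample = labels,
                injected_spikes = spikes, injected_steps = steps,
                retained_channel_indices = keep,
                class_order = class_order,
                transforms = list(subject = subject_transform,
                                  gain = gain, drift = drift))
  list(recording = rec, truth = truth)
}

#' Generate all sessions of a synthetic subject
#'
#' The subject-level transform (feature-space rotation, baseline offset,
#' channel subset) is drawn once per `subject_index` and applied to every
#' session; session-level perturbations are drawn independently per session.
#'
#' @inheritParams generate_session
#' @param subject_index Nonnegative integer identifying the subject.
#' @param n_sessions Number of sessions (default 4).
#' @return A list with `sessions` (list of `generate_session()` outputs) and
#'   `transform` (the subject transform used).
#' @export
generate_subject <- function(config, subject_index, n_sessions = 4L) {
  stopifnot(n_sessions >= 1L)
  transform <- draw_subject_transform(config, subject_index)
  sessions <- lapply(seq_len(n_sessions), function(m)
    generate_session(config, session_index = m, subject_transform = transform))
  list(sessions = sessions, transform = transform)
}

#' Generate a full synthetic study (several subjects, several sessions)
#'
#' @inheritParams generate_session
#' @param n_subjects,n_sessions Study size (defaults mirror a six-subject,
#'   four-session protocol).
#' @return A list with `subjects` (each a [generate_subject()] output) and the
#'   `config` used.
#' @export
simulate_study <- function(config, n_subjects = 6L, n_sessions = 4L) {
  subjects <- lapply(seq_len(n_subjects), function(s)
    generate_subject(config, subject_index = s, n_sessions = n_sessions))
  list(subjects = subjects, config = config)
}

#' Inject sparse spike and step artifacts into a recording
#'
#' Spike events are short pulses of 1-3 samples; step events are persistent
#' level shifts.  Event times are Poisson-distributed per row with the given
#' rates (events per minute), so the expected event count on a row equals
#' rate x duration.
#'
#' @param recording A `hemo_recording`.
#' @param artifact_params List with `spike_rate`, `spike_amplitude`,
#'   `step_rate`, `step_amplitude` (rates per minute, amplitudes in uM).
#' @param seed Integer seed.
#' @return List with `recording` (artifacts added), `injected_spikes` and
#'   `injected_steps`: per species a list (one entry per row) of data frames
#'   with columns `time` (sample index), `amplitude`, and for spikes `width`.
#' @export
inject_artifacts <- function(recording, artifact_params, seed = 1L) {
  ap <- artifact_params
  if (ap$spike_rate < 0 || ap$step_rate < 0)
    stop("artifact rates must be nonnegative", call. = FALSE)
  set.seed(seed)
  n <- ncol(recording$dHbO2)
  dur_min <- n / recording$sampling_rate / 60
  spikes <- list(); steps <- list()
  out <- recording
  for (sp in c("dHbO2", "dHb")) {
    M <- out[[sp]]
    sp_list <- vector("list", nrow(M)); st_list <- vector("list", nrow(M))
    for (r in seq_len(nrow(M))) {
      sp_df <- data.frame(time = integer(0), amplitude = numeric(0), width = integer(0))
      if (ap$spike_rate > 0) {
        k <- rpois(1L, ap$spike_rate * dur_min)
        if (k > 0) {
          tms <- sort(sample.int(n, k))
          for (ti in tms) {
            wdt <- sample(1:3, 1L)
            amp <- ap$spike_amplitude * runif(1, 0.75, 1.25) * sample(c(-1, 1), 1L)
            idx <- ti:min(n, ti + wdt - 1L)
            M[r, idx] <- M[r, idx] + amp
            sp_df <- rbind(sp_df, data.frame(time = ti, amplitude = amp,
                                             width = length(idx)))
          }
        }
      }
      st_df <- data.frame(time = integer(0), amplitude = numeric(0))
      if (ap$step_rate > 0) {
        k <- rpois(1L, ap$step_rate * dur_min)
        if (k > 0) {
          tms <- sort(sample.int(n, k))
          for (ti in tms) {
            amp <- ap$step_amplitude * runif(1, 0.75, 1.25) * sample(c(-1, 1), 1L)
            M[r, ti:n] <- M[r, ti:n] + amp
            st_df <- rbind(st_df, data.frame(time = ti, amplitude = amp))
          }
        }
      }
      sp_list[[r]] <- sp_df; st_list[[r]] <- st_df
    }
    out[[sp]] <- M
    spikes[[sp]] <- sp_list; steps[[sp]] <- st_list
  }
  list(recording = out, injected_spikes = spikes, injected_steps = steps)
}
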