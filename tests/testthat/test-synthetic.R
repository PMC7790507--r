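test_that("generator reproduces class means and covariances in the noiseless limit", {
  cfg <- generator_config(
    seed = 42, n_channels = 4L, samples_per_task = 4000L,
    session_shift = list(channel_dropout_probability = 0, mean_drift_scale = 0,
                         gain_jitter = 0),
    subject_shift = list(rotation_angle_scale = 0, baseline_offset_scale = 0,
                         channel_set_size_range = c(4L, 4L), class_dispersion = 0),
    trend_amplitude = 0, noise_sd = 0, ar_coefficient = 0)
  out <- generate_session(cfg, 1)
  X <- rbind(out$recording$dHbO2, out$recording$dHb)
  lab <- out$truth$labels_per_sample
  for (cl in 0:3) {
    Xc <- X[, lab == cl, drop = FALSE]
    mu_hat <- rowMeans(Xc)
    mu <- cfg$class_means[[cl + 1L]]
    # sampling error of the mean: sd/sqrt(n) per coordinate, sd <= ~1
    expect_lt(max(abs(mu_hat - mu)), 6 / sqrt(ncol(Xc)))
    P_hat <- tcrossprod(Xc - mu_hat) / (ncol(Xc) - 1)
    P <- cfg$class_covariances[[cl + 1L]]
    expect_lt(max(abs(P_hat - P)), 0.15)
  }
})

test_that("generation is bitwise deterministic given config and indices", {
  cfg <- tiny_config(7)
  expect_identical(generate_session(cfg, 2), generate_session(cfg, 2))
  expect_identical(generate_subject(cfg, 3, 2), generate_subject(cfg, 3, 2))
})

test_that("a default session carries four contiguous task blocks of 1562 samples", {
  cfg <- generator_config(seed = 1)
  out <- generate_session(cfg, 1)
  lab <- out$truth$labels_per_sample
  r <- rle(lab)
  task <- r$values >= 0
  expect_equal(sum(task), 4L)                      # one contiguous block per class
  expect_true(all(r$lengths[task] == 1562L))
  expect_setequal(r$values[task], 0:3)
  expect_equal(sum(lab == 0), 1562L)
})

test_that("subject transforms are shared across sessions and scale with the shift", {
  cfg0 <- generator_config(
    seed = 5, n_channels = 6L, samples_per_task = 600L,
    session_shift = list(channel_dropout_probability = 0, mean_drift_scale = 0,
                         gain_jitter = 0),
    subject_shift = list(rotation_angle_scale = 0, baseline_offset_scale = 0,
                         channel_set_size_range = c(6L, 6L), class_dispersion = 0))
  s1 <- generate_subject(cfg0, 1, 2)
  s2 <- generate_subject(cfg0, 2, 2)
  # degenerate shift: both subjects share the class geometry exactly
  expect_equal(s1$transform$Q, diag(12))
  expect_equal(s1$transform$baseline, numeric(12))
  expect_equal(s1$transform$class_scale, rep(1, 4))
  expect_equal(s2$transform$class_scale, rep(1, 4))

  cfg1 <- tiny_config(5, n_channels = 6L)
  t1 <- generate_subject(cfg1, 1, 1)$transform
  t2 <- generate_subject(cfg1, 2, 1)$transform
  # rotations are orthogonal and differ between subjects
  expect_lt(max(abs(crossprod(t1$Q) - diag(12))), 1e-10)
  expect_gt(max(abs(t1$Q - t2$Q)), 0.01)
  expect_false(isTRUE(all.equal(t1$class_scale, t2$class_scale)))
})

test_that("each session randomizes its own task-block order", {
  cfg <- tiny_config(11)
  sub <- generate_subject(cfg, 1, 4)
  orders <- lapply(sub$sessions, function(s) s$truth$class_order)
  for (o in orders) expect_setequal(o, 0:3)
  expect_gt(length(unique(vapply(orders, paste, collapse = ",", ""))), 1L)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_channels = 4L,
                                subject_shift = list(rotation_angle_scale = 0,
                                                     baseline_offset_scale = 0,
                                                     channel_set_size_range = c(2L, 9L),
                                                     class_dispersion = 0)),
               "exceeds n_channels")
  bad <- generator_config(n_channels = 2L,
                          subject_shift = list(rotation_angle_scale = 0,
                                               baseline_offset_scale = 0,
                                               channel_set_size_range = c(2L, 2L),
                                               class_dispersion = 0))
  S <- diag(4); S[1, 1] <- -1                      # symmetric but indefinite
  bad$class_covariances[[2]] <- S
  expect_error(generate_session(bad, 1), "positive-definite")
})

test_that("artifact injection is a no-op at zero rates and matches its ground truth", {
  cfg <- tiny_config(3)
  rec <- generate_session(cfg, 1)$recording
  out <- inject_artifacts(rec, list(spike_rate = 0, spike_amplitude = 6,
                                    step_rate = 0, step_amplitude = 4), seed = 1)
  expect_identical(out$recording$dHbO2, rec$dHbO2)
  expect_identical(out$recording$dHb, rec$dHb)
  expect_true(all(vapply(out$injected_spikes$dHbO2, nrow, 1L) == 0L))

  inj <- inject_artifacts(rec, list(spike_rate = 1, spike_amplitude = 6,
                                    step_rate = 0.3, step_amplitude = 4), seed = 9)
  n <- ncol(rec$dHbO2)
  for (sp in c("dHbO2", "dHb")) {
    diffm <- inj$recording[[sp]] - rec[[sp]]
    for (r in seq_len(nrow(diffm))) {
      st <- inj$injected_steps[[sp]][[r]]
      sk <- inj$injected_spikes[[sp]][[r]]
      expect_true(all(st$time >= 1 & st$time <= n))
      # reconstruct the injected artifact signal from the ground truth
      art <- numeric(n)
      if (nrow(st)) for (k in seq_len(nrow(st)))
        art[st$time[k]:n] <- art[st$time[k]:n] + st$amplitude[k]
      if (nrow(sk)) for (k in seq_len(nrow(sk))) {
        idx <- sk$time[k]:(sk$time[k] + sk$width[k] - 1L)
        art[idx] <- art[idx] + sk$amplitude[k]
      }
      expect_equal(drop(diffm[r, ]), art, tolerance = 1e-12)
    }
  }
})

test_that("spike counts follow the configured Poisson rate", {
  # one channel, 200 s of samples: expected count = rate x duration
  fs <- 7.81
  n <- 1562L
  rec <- hemo_recording(matrix(0, 1, n), matrix(0, 1, n), fs,
                        labels_per_sample = rep(0L, n))
  rate <- 6                                # per minute
  dur_min <- n / fs / 60
  counts <- vapply(1:200, function(s) {
    inj <- inject_artifacts(rec, list(spike_rate = rate, spike_amplitude = 5,
                                      step_rate = 0, step_amplitude = 0), seed = s)
    nrow(inj$injected_spikes$dHbO2[[1]])
  }, numeric(1))
  expected <- rate * dur_min
  # Monte-Carlo mean over 200 seeds: 4 sigma of the mean
  expect_lt(abs(mean(counts) - expected), 4 * sqrt(expected / 200))
})

test_that("class-covariance dispersion is larger across subjects than across sessions", {
  cfg <- tiny_config(13, samples_per_task = 600L)
  study <- simulate_study(cfg, n_subjects = 3, n_sessions = 3)
  # per (subject, session, class): average segment covariance
  class_cov <- function(rec) {
    seg <- segment_recording(rec)
    fe <- segment_features(seg, shrinkage = 0.05)
    lapply(0:3, function(cl) Reduce(`+`, fe$covariances[seg$labels == cl]) /
             sum(seg$labels == cl))
  }
  covs <- lapply(study$subjects, function(su)
    lapply(su$sessions, function(se) class_cov(se$recording)))
  # sessions of one subject share the channel subset, so Hellinger applies
  # within subject; across subjects compare subjects with equal dimensions
  sess_d <- c(); subj_d <- c()
  for (s in 1:3) {
    for (m in 1:2) for (m2 in (m + 1):3) {
      if (nrow(covs[[s]][[m]][[1]]) != nrow(covs[[s]][[m2]][[1]])) next
      for (cl in 1:4)
        sess_d <- c(sess_d, hellinger(covs[[s]][[m]][[cl]], covs[[s]][[m2]][[cl]]) /
                      nrow(covs[[s]][[m]][[cl]]))
    }
  }
  for (s in 1:2) for (s2 in (s + 1):3) for (m in 1:3) for (m2 in 1:3) {
    if (nrow(covs[[s]][[m]][[1]]) != nrow(covs[[s2]][[m2]][[1]])) next
    for (cl in 1:4)
      subj_d <- c(subj_d, hellinger(covs[[s]][[m]][[cl]], covs[[s2]][[m2]][[cl]]) /
                    nrow(covs[[s]][[m]][[cl]]))
  }
  expect_gt(length(sess_d), 0)
  expect_gt(length(subj_d), 0)
  expect_gt(mean(subj_d), mean(sess_d))
})
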