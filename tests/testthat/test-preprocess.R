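test_that("constant intensities convert to zero concentration changes", {
  I <- array(rep(c(500, 700), each = 1, times = 2 * 50), c(2, 2, 50))
  I[] <- rep(c(500, 700), times = 2 * 50)          # both wavelengths constant
  rec <- intensity_recording(I, sampling_rate = 7.81)
  hemo <- mbll_convert(rec)
  expect_lt(max(abs(hemo$dHbO2)), 1e-12)
  expect_lt(max(abs(hemo$dHb)), 1e-12)
})

test_that("the conversion inverts the forward Beer-Lambert model exactly", {
  set.seed(1)
  nch <- 3L; n <- 400L
  dHbO2 <- matrix(rnorm(nch * n, sd = 0.8), nch, n)
  dHb <- matrix(rnorm(nch * n, sd = 0.3), nch, n)
  base <- 1:40                                     # reference window: true zeros
  dHbO2[, base] <- 0; dHb[, base] <- 0
  I <- forward_intensity(dHbO2, dHb)
  rec <- intensity_recording(I, sampling_rate = 7.81)
  hemo <- mbll_convert(rec, baseline_window = base)
  expect_lt(max(abs(hemo$dHbO2 - dHbO2)), 1e-9)
  expect_lt(max(abs(hemo$dHb - dHb)), 1e-9)

  # linearity in 1/DPF: doubling both pathlength factors halves the output
  hemo2 <- mbll_convert(rec, dpf760 = 2 * 9.1, dpf850 = 2 * 8.0,
                        baseline_window = base)
  expect_equal(hemo2$dHbO2, hemo$dHbO2 / 2, tolerance = 1e-9)
  expect_equal(hemo2$dHb, hemo$dHb / 2, tolerance = 1e-9)
})

test_that("mbll_convert rejects degenerate inputs", {
  I <- array(1, c(1, 2, 10))
  rec <- intensity_recording(I, 7.81)
  expect_error(mbll_convert(rec, extinction_table = matrix(1, 2, 2)), "singular")
  expect_error(intensity_recording(array(c(-1, 1), c(1, 2, 10)), 7.81), "positive")
})

test_that("linear detrending removes exactly the least-squares line", {
  t <- 1:200
  expect_lt(max(abs(linear_detrend(3 * t + 7))), 1e-9)
  x <- sin(2 * pi * t / 40)
  y <- x + 0.05 * t - 2
  # oracle: subtract the closed-form least-squares fit
  fit <- lm.fit(cbind(1, t), y)
  expect_equal(linear_detrend(y), unname(fit$residuals), tolerance = 1e-9)
  # projection property: idempotent
  expect_equal(linear_detrend(linear_detrend(y)), linear_detrend(y),
               tolerance = 1e-12)
  # matrix input works rowwise
  M <- rbind(3 * t + 1, y)
  D <- linear_detrend(M)
  expect_lt(max(abs(D[1, ])), 1e-9)
  expect_equal(D[2, ], linear_detrend(y), tolerance = 1e-12)
})

test_that("channels dominated by high-frequency power are rejected as a pair", {
  fs <- 7.81; t <- seq_len(1000) / fs
  hf <- sin(2 * pi * 2 * t)                        # 2 Hz: above the 1 Hz cutoff
  lf <- sin(2 * pi * 0.05 * t)
  rec <- hemo_recording(rbind(hf, lf, lf), rbind(lf, lf, lf), fs,
                        retained_channels = 1:3)
  out <- reject_noisy_channels(rec)
  expect_equal(out$removed, 1L)                    # whole channel removed
  expect_equal(nrow(out$recording$dHbO2), 2L)
  expect_equal(out$recording$retained_channels, 2:3)

  clean <- hemo_recording(rbind(lf, lf), rbind(lf, lf), fs)
  out2 <- reject_noisy_channels(clean)
  expect_length(out2$removed, 0)
  expect_equal(out2$recording$dHbO2, clean$dHbO2)
})

test_that("sessions are admissible up to (and including) 60% channel loss", {
  rec <- hemo_recording(matrix(0, 20, 10), matrix(0, 20, 10), 7.81)
  expect_false(session_admissible(rec, 1:13))      # 65% removed
  expect_true(session_admissible(rec, 1:12))       # exactly 60%
  expect_true(session_admissible(rec, integer(0)))
})

test_that("segmentation cuts non-overlapping labeled windows per task block", {
  fs <- 7.81
  lab <- c(rep(-1L, 30), rep(0L, 1562))
  X <- matrix(rnorm(2 * length(lab)), 2)
  rec <- hemo_recording(X[1, , drop = FALSE], X[2, , drop = FALSE], fs,
                        labels_per_sample = lab)
  seg <- segment_recording(rec, w = 60)
  expect_length(seg$segments, 26L)                 # floor(1562 / 60)
  expect_true(all(seg$labels == 0L))
  # first window starts exactly at the block start; windows are consecutive
  expect_equal(seg$segments[[1]], rbind(X[1, 31:90], X[2, 31:90]))
  expect_equal(seg$segments[[2]], rbind(X[1, 91:150], X[2, 91:150]))

  lab4 <- rep(c(0L, 1L, 2L, 3L), each = 1562)
  X4 <- matrix(rnorm(2 * length(lab4)), 2)
  rec4 <- hemo_recording(X4[1, , drop = FALSE], X4[2, , drop = FALSE], fs, lab4)
  seg4 <- segment_recording(rec4, w = 60)
  expect_length(seg4$segments, 104L)
  expect_equal(as.integer(table(seg4$labels)), rep(26L, 4))

  # a single hemoglobin species halves the segment row count
  seg_h <- segment_recording(rec4, w = 60, species = "dHbO2")
  expect_equal(seg_h$d, 1L)
  expect_equal(seg_h$segments[[1]], X4[1, 1:60, drop = FALSE])

  # w equal to the block length gives exactly one segment per block
  seg1 <- segment_recording(rec4, w = 1562)
  expect_length(seg1$segments, 4L)
  # a block shorter than w contributes nothing, with a warning
  lab_s <- c(rep(0L, 30), rep(1L, 90))
  rec_s <- hemo_recording(matrix(0, 1, 120), matrix(0, 1, 120), fs, lab_s)
  expect_warning(seg_s <- segment_recording(rec_s, w = 60), "shorter")
  expect_length(seg_s$segments, 1L)
  expect_equal(seg_s$labels, 1L)
})
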