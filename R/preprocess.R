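# Preprocessing: modified Beer-Lambert conversion, detrending, channel and
# session rejection, and segmentation into fixed-width labeled windows.

#' Hemoglobin concentration-change recording
#'
#' Container for one session of delta-HbO2 / delta-Hb multichannel series.
#'
#' @param dHbO2,dHb `channels x time` matrices (uM), same shape.
#' @param sampling_rate Hz.
#' @param labels_per_sample Integer vector (length = time): n-back level of
#'   each sample, with -1 marking baseline/rest samples.
#' @param retained_channels Integer indices of the physical channels present
#'   (relative to the original montage).
#' @return An object of class `hemo_recording`.
#' @export
hemo_recording <- function(dHbO2, dHb, sampling_rate, labels_per_sample = NULL,
                           retained_channels = seq_len(nrow(dHbO2))) {
  dHbO2 <- as.matrix(dHbO2); dHb <- as.matrix(dHb)
  if (!all(dim(dHbO2) == dim(dHb)))
    stop("dHbO2 and dHb must share shape", call. = FALSE)
  if (length(retained_channels) != nrow(dHbO2))
    stop("retained_channels must index every channel row", call. = FALSE)
  if (!is.null(labels_per_sample) && length(labels_per_sample) != ncol(dHbO2))
    stop("labels_per_sample must have one entry per sample", call. = FALSE)
  structure(list(dHbO2 = dHbO2, dHb = dHb, sampling_rate = sampling_rate,
                 labels_per_sample = labels_per_sample,
                 retained_channels = as.integer(retained_channels)),
            class = "hemo_recording")
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat("<hemo_recording> ", nrow(x$dHbO2), " channels x ", ncol(x$dHbO2),
      " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Raw two-wavelength intensity recording
#'
#' @param intensity `channels x 2 x time` array of strictly positive light
#'   intensities; the second dimension indexes the 760 nm and 850 nm
#'   wavelengths, in that order.
#' @param sampling_rate Hz.
#' @param source_detector_distance Source-detector distance in cm (default 3).
#' @param labels_per_sample As in [hemo_recording()].
#' @return An object of class `intensity_recording`.
#' @export
intensity_recording <- function(intensity, sampling_rate,
                                source_detector_distance = 3,
                                labels_per_sample = NULL) {
  stopifnot(length(dim(intensity)) == 3L, dim(intensity)[2] == 2L)
  if (any(intensity <= 0))
    stop("intensities must be strictly positive", call. = FALSE)
  structure(list(intensity = intensity, sampling_rate = sampling_rate,
                 source_detector_distance = source_detector_distance,
                 labels_per_sample = labels_per_sample),
            class = "intensity_recording")
}

#' Default hemoglobin extinction coefficients
#'
#' Molar extinction coefficients (L mmol^-1 cm^-1) for oxy- and
#' deoxy-hemoglobin at 760 and 850 nm, from the standard compiled tabulation
#' (Prahl).  Rows are wavelengths (760, 850), columns are species
#' (HbO2, Hb).
#'
#' @return 2x2 numeric matrix with dimnames.
#' @export
default_extinction_table <- function() {
  matrix(c(0.5864, 1.5485,
           1.0580, 0.6913),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO2", "Hb")))
}

#' Modified Beer-Lambert conversion of intensities to hemoglobin changes
#'
#' Per channel, the optical density change is
#' `dOD(lambda, t) = -log10(I(t) / I0)` with `I0` the mean intensity over the
#' initial baseline window, and the 2x2 system
#' `dOD(lambda) = eps(lambda, .) %*% dC * DPF(lambda) * L` is solved for
#' `dC = (d[HbO2], d[Hb])` at each sample (L = source-detector distance).
#'
#' @param rec An [intensity_recording()].
#' @param dpf760,dpf850 Differential pathlength factors (defaults 9.1 and 8.0).
#' @param extinction_table 2x2 matrix as [default_extinction_table()].
#' @param baseline_window Integer sample indices defining I0.  Default: the
#'   leading run of baseline-labeled samples if labels are present, otherwise
#'   the first 10% of samples.
#' @return A [hemo_recording()] in uM.  The extinction table used is attached
#'   as attribute `extinction_table`.
#' @export
mbll_convert <- function(rec, dpf760 = 9.1, dpf850 = 8.0,
                         extinction_table = default_extinction_table(),
                         baseline_window = NULL) {
  stopifnot(inherits(rec, "intensity_recording"))
  E <- as.matrix(extinction_table)
  if (abs(det(E)) < 1e-12)
    stop("extinction matrix is singular", call. = FALSE)
  I <- rec$intensity
  if (any(I <= 0)) stop("non-positive intensity", call. = FALSE)
  n <- dim(I)[3]; nch <- dim(I)[1]
  if (is.null(baseline_window)) {
    lab <- rec$labels_per_sample
    if (!is.null(lab) && lab[1] == -1L) {
      baseline_window <- seq_len(match(TRUE, lab != -1L, nomatch = n + 1L) - 1L)
    } else baseline_window <- seq_len(max(2L, floor(0.1 * n)))
  }
  L <- rec$source_detector_distance
  # M maps concentrations (mmol/L) to optical densities at the two wavelengths
  M <- diag(c(dpf760, dpf850) * L) %*% E
  Minv <- solve(M)
  dHbO2 <- matrix(0, nch, n); dHb <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    Ich <- I[ch, , ]                     # 2 x n
    I0 <- rowMeans(Ich[, baseline_window, drop = FALSE])
    OD <- -log10(Ich / I0)
    C <- Minv %*% OD                     # mmol/L
    dHbO2[ch, ] <- C[1, ] * 1000         # -> uM
    dHb[ch, ] <- C[2, ] * 1000
  }
  out <- hemo_recording(dHbO2, dHb, rec$sampling_rate, rec$labels_per_sample)
  attr(out, "extinction_table") <- E
  out
}

#' Remove the least-squares line from each row of a series
#'
#' @param series Numeric vector or `channels x time` matrix.
#' @return Same shape with the per-row best-fit line subtracted; idempotent.
#' @export
linear_detrend <- function(series) {
  vec <- is.null(dim(series))
  X <- if (vec) matrix(series, nrow = 1L) else as.matrix(series)
  n <- ncol(X)
  if (n < 2L) stop("series length must be >= 2", call. = FALSE)
  t0 <- seq_len(n) - (n + 1) / 2                # centered time
  denom <- sum(t0^2)
  slope <- (X %*% t0) / denom
  out <- X - rowMeans(X) - slope %*% t0
  if (vec) drop(out) else out
}

# Fraction of (positive-frequency) periodogram power above a cutoff.
hf_power_fraction <- function(x, fs, cutoff) {
  x <- linear_detrend(x)
  n <- length(x)
  P <- Mod(fft(x))^2
  f <- (seq_len(n) - 1L) * fs / n
  pos <- f > 0 & f <= fs / 2
  sum(P[pos & f > cutoff]) / sum(P[pos])
}

#' Reject channels contaminated by high-frequency noise
#'
#' A physical channel is removed (both hemoglobin rows together) when the
#' fraction of its periodogram power above `hf_cutoff` exceeds
#' `power_fraction_threshold` on either hemoglobin species.  This is an
#' automated surrogate for manual inspection of channels with >1 Hz noise.
#'
#' @param rec A [hemo_recording()].
#' @param hf_cutoff Hz (default 1).
#' @param power_fraction_threshold In `[0, 1]` (default 0.25).
#' @return List with `recording` (channels removed) and `removed` (original
#'   channel indices removed).
#' @export
reject_noisy_channels <- function(rec, hf_cutoff = 1.0,
                                  power_fraction_threshold = 0.25) {
  stopifnot(inherits(rec, "hemo_recording"))
  if (rec$sampling_rate <= 2 * hf_cutoff)
    stop("sampling_rate must exceed twice the cutoff", call. = FALSE)
  nch <- nrow(rec$dHbO2)
  bad <- logical(nch)
  for (ch in seq_len(nch)) {
    fr <- max(hf_power_fraction(rec$dHbO2[ch, ], rec$sampling_rate, hf_cutoff),
              hf_power_fraction(rec$dHb[ch, ], rec$sampling_rate, hf_cutoff))
    bad[ch] <- fr > power_fraction_threshold
  }
  removed <- rec$retained_channels[bad]
  out <- rec
  if (any(bad)) {
    out$dHbO2 <- rec$dHbO2[!bad, , drop = FALSE]
    out$dHb <- rec$dHb[!bad, , drop = FALSE]
    out$retained_channels <- rec$retained_channels[!bad]
  }
  list(recording = out, removed = removed)
}

#' Session admissibility under the 60% channel-rejection rule
#'
#' A session is inadmissible when more than 60% of its channels were
#' identified as noisy (strictly more; exactly 60% is still admissible).
#'
#' @param rec The original [hemo_recording()] (before removal).
#' @param removed Integer vector of removed channel indices.
#' @return Logical.
#' @export
session_admissible <- function(rec, removed) {
  total <- nrow(rec$dHbO2)
  length(removed) / total <= 0.60
}

#' Cut task data into fixed-width labeled segments
#'
#' Each contiguous task block contributes `floor(block_length / w)`
#' consecutive non-overlapping windows; the trailing remainder is discarded
#' and baseline/rest samples are excluded.  Each segment is the stacked
#' `d x w` matrix of delta-HbO2 rows over delta-Hb rows.
#'
#' @param rec A [hemo_recording()] with labels.
#' @param w Window length in samples (default 60, about 8 s at 7.81 Hz).
#' @param session_id,subject_id Optional identifiers carried along.
#' @param species `"both"` (default: delta-HbO2 rows stacked over delta-Hb
#'   rows, `d = 2 x channels`) or a single hemoglobin species.
#' @return An object of class `segment_set`: list with `segments` (list of
#'   `d x w` matrices), `labels` (integer vector), `window`, `d`, ids.
#' @export
segment_recording <- function(rec, w = 60L, session_id = NA, subject_id = NA,
                              species = c("both", "dHbO2", "dHb")) {
  stopifnot(inherits(rec, "hemo_recording"))
  species <- match.arg(species)
  lab <- rec$labels_per_sample
  if (is.null(lab)) stop("recording carries no labels", call. = FALSE)
  X <- switch(species, both = rbind(rec$dHbO2, rec$dHb),
              dHbO2 = rec$dHbO2, dHb = rec$dHb)
  d <- nrow(X)
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segments <- list(); labels <- integer(0)
  for (b in seq_along(r$values)) {
    if (r$values[b] < 0) next
    len <- r$lengths[b]
    k <- len %/% w
    if (k == 0L) {
      warning("task block shorter than window; contributes no segments")
      next
    }
    for (i in seq_len(k)) {
      i0 <- starts[b] + (i - 1L) * w
      segments[[length(segments) + 1L]] <- X[, i0:(i0 + w - 1L), drop = FALSE]
      labels <- c(labels, r$values[b])
    }
  }
  structure(list(segments = segments, labels = labels, window = as.integer(w),
                 d = d, session_id = session_id, subject_id = subject_id),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> N=", length(x$segments), " segments of ", x$d, "x",
      x$window, "; classes: ", paste(sort(unique(x$labels)), collapse = ","),
      "\n", sep = "")
  invisible(x)
}
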