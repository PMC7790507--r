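# Shared fixtures and independent oracles used across the suite.

# Random symmetric positive-definite matrix.
rand_spd <- function(d, seed = NULL, jitter = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + jitter * diag(d)
}

# Random within-domain distance matrix from points in the plane (all pairwise
# distances distinct with probability one).
rand_metric <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.matrix(dist(matrix(rnorm(2 * n), n)))
}

# Feasibility contract for every returned plan (marginals + nonnegativity).
expect_feasible <- function(plan, tol = 1e-6) {
  Tm <- plan$matrix
  expect_true(all(Tm >= -1e-15))
  expect_lt(max(abs(rowSums(Tm) - plan$row_marginal)), tol)
  expect_lt(max(abs(colSums(Tm) - plan$col_marginal)), tol)
}

expect_monotone_trace <- function(trace, slack = 1e-8) {
  if (length(trace) > 1L)
    expect_true(all(diff(trace) <= slack * pmax(1, abs(trace[-length(trace)]))))
}

# Independent quadruple-sum evaluation of the squared-loss G-W objective.
gw_objective_quad <- function(Ca, Cb, T) {
  n <- nrow(Ca); m <- nrow(Cb); o <- 0
  for (i in 1:n) for (ii in 1:n) for (j in 1:m) for (jj in 1:m)
    o <- o + (Ca[i, ii] - Cb[j, jj])^2 * T[i, j] * T[ii, jj]
  o
}

# Independent quadruple-sum FG-W objective (squared feature + structure loss).
fgw_objective_quad <- function(Ca, Cb, fa, fb, alpha, T) {
  n <- nrow(Ca); m <- nrow(Cb); o <- 0
  for (i in 1:n) for (ii in 1:n) for (j in 1:m) for (jj in 1:m)
    o <- o + ((1 - alpha) * (fa[i] - fb[j])^2 +
                alpha * (Ca[i, ii] - Cb[j, jj])^2) * T[i, j] * T[ii, jj]
  o
}

# All permutations of 1..n (n <= 7).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# Compact generator configuration for fast end-to-end tests (8 channels,
# shorter task blocks); study conditions otherwise as the defaults.
tiny_config <- function(seed, samples_per_task = 600L, n_channels = 8L, ...) {
  generator_config(
    seed = seed, n_channels = n_channels, samples_per_task = samples_per_task,
    subject_shift = list(rotation_angle_scale = 0.3, baseline_offset_scale = 0.5,
                         channel_set_size_range = c(n_channels - 2L, n_channels),
                         class_dispersion = 0.25),
    ...)
}

# The artifact-injection study conditions: compact sessions with severe motion
# events; thresholds sit at the extreme-value scale of the artifact-free
# high-pass residual and the detected amplitudes are refit without penalty.
artifact_config <- function(seed) {
  generator_config(
    seed = seed, n_channels = 8L, samples_per_task = 900L,
    subject_shift = list(rotation_angle_scale = 0.3, baseline_offset_scale = 0.5,
                         channel_set_size_range = c(6L, 8L),
                         class_dispersion = 0.25),
    artifact_params = list(spike_rate = 2, spike_amplitude = 10,
                           step_rate = 0.4, step_amplitude = 8))
}

artifact_tara_params <- function() tara_params(sigma = 0.6, beta = 4, step_weight = 3.3)

# Forward modified Beer-Lambert model: synthesize two-wavelength intensities
# from known concentration changes (uM); independent of the package inverse.
forward_intensity <- function(dHbO2_uM, dHb_uM, I0 = c(1000, 800),
                              dpf760 = 9.1, dpf850 = 8.0, L = 3,
                              E = default_extinction_table()) {
  nch <- nrow(dHbO2_uM); n <- ncol(dHbO2_uM)
  M <- diag(c(dpf760, dpf850) * L) %*% E
  I <- array(0, c(nch, 2, n))
  for (ch in seq_len(nch)) {
    C <- rbind(dHbO2_uM[ch, ], dHb_uM[ch, ]) / 1000   # -> mmol/L
    OD <- M %*% C
    I[ch, 1, ] <- I0[1] * 10^(-OD[1, ])
    I[ch, 2, ] <- I0[2] * 10^(-OD[2, ])
  }
  I
}
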