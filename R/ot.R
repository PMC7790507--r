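# Discrete optimal-transport solvers: entropic OT (Sinkhorn), entropic
# Gromov-Wasserstein, fused Gromov-Wasserstein, and the FG-W barycenter.
#
# The quadratic (G-W / FG-W) problems use the squared structure loss
# L(x, y) = (x - y)^2, for which the objective at a feasible plan T is
#   <constC, T> - 2 <Ca T Cb, T>,
# with constC_ij = sum_i' Ca_ii'^2 a_i' + sum_j' Cb_jj'^2 b_j'.  They are
# solved by projected mirror descent: each outer iteration runs Sinkhorn on
# the current gradient.  An optional annealing phase (geometrically decreasing
# entropic weight, warm-started) initializes the final solve; the reported
# objective trace covers the outer iterations at the requested weight and is
# non-increasing by construction (a candidate iterate that would increase the
# objective is rejected and the solver stops).

uniform_hist <- function(n) rep(1 / n, n)

check_histogram <- function(h, n, name) {
  if (length(h) != n) stop(name, " has wrong length", call. = FALSE)
  if (any(h < 0) || abs(sum(h) - 1) > 1e-12)
    stop(name, " must be nonnegative and sum to 1", call. = FALSE)
  h
}

new_transport_plan <- function(T, a, b, objective_value, converged, iterations,
                               lam, extra = list()) {
  structure(c(list(matrix = T, row_marginal = a, col_marginal = b,
                   objective_value = objective_value, converged = converged,
                   iterations = iterations, lam = lam,
                   marginal_error = max(max(abs(rowSums(T) - a)),
                                        max(abs(colSums(T) - b)))),
              extra),
            class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat("<transport_plan> ", nrow(x$matrix), "x", ncol(x$matrix),
      "; objective ", signif(x$objective_value, 6),
      "; marginal error ", signif(x$marginal_error, 3),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}


# Core scaling iterations, stabilized by log-absorption: scaling vectors are
# absorbed into the dual potentials (and the kernel rebuilt) whenever they
# leave a safe numeric range, so arbitrarily small lam is handled without
# underflow while keeping plain matrix-vector iterations.  The loop lives in
# C++ (src/sinkhorn.cpp); this wrapper manages the warm-started potentials.
sinkhorn_core <- function(cost, a, b, lam, tol = 1e-9, max_iter = 1000L,
                          warm = NULL) {
  n <- length(a); m <- length(b)
  f <- if (!is.null(warm$f)) warm$f else numeric(n)
  g <- if (!is.null(warm$g)) warm$g else numeric(m)
  res <- sinkhorn_core_cpp(cost, a, b, lam, tol, as.integer(max_iter), f, g)
  list(matrix = res$matrix, converged = res$converged,
       iterations = res$iterations,
       warm = list(f = drop(res$f), g = drop(res$g)))
}

# Project a nonnegative matrix exactly onto U(a, b) (rounding of Altschuler
# et al.): row/column rescaling capped at 1, then a rank-one correction.
# Leaves already-feasible plans essentially unchanged.
round_to_marginals <- function(T, a, b) {
  r <- rowSums(T)
  T <- T * pmin(1, a / pmax(r, .Machine$double.xmin))
  cs <- colSums(T)
  T <- T * rep(pmin(1, b / pmax(cs, .Machine$double.xmin)), each = nrow(T))
  er <- pmax(a - rowSums(T), 0); ec <- pmax(b - colSums(T), 0)
  s <- sum(er)
  if (s > 0) T <- T + outer(er, ec) / s
  pmax(T, 0)
}

#' Entropic optimal transport (Sinkhorn)
#'
#' Minimizes `<cost, T> - lam * H(T)` over couplings with marginals `a`, `b`.
#'
#' @param cost `n x m` finite cost matrix.
#' @param a,b Marginal histograms (default uniform).
#' @param lam Positive entropic regularization weight.
#' @param tol Marginal feasibility tolerance.
#' @param max_iter Iteration cap; exceeding it returns the best iterate with
#'   `converged = FALSE`.
#' @return A `transport_plan` whose `objective_value` is the linear cost
#'   `<cost, T>` at the returned plan.
#' @export
sinkhorn <- function(cost, a = NULL, b = NULL, lam, tol = 1e-9,
                     max_iter = 1000L) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop("cost must be finite", call. = FALSE)
  if (lam <= 0) stop("lam must be positive", call. = FALSE)
  n <- nrow(cost); m <- ncol(cost)
  a <- if (is.null(a)) uniform_hist(n) else check_histogram(a, n, "a")
  b <- if (is.null(b)) uniform_hist(m) else check_histogram(b, m, "b")
  res <- sinkhorn_core(cost, a, b, lam, tol, max_iter)
  Tm <- res$matrix
  if (!res$converged) Tm <- round_to_marginals(Tm, a, b)
  new_transport_plan(Tm, a, b, sum(cost * Tm),
                     res$converged, res$iterations, lam)
}

# Shared solver for the quadratic transport problems.
#   F(T) = <M, T> + alpha * [<constC, T> - 2 <Ca T Cb, T>]
# where M already carries its (1 - alpha) feature weight; alpha = 1, M = 0
# gives plain entropic G-W.
ot_quad_solve <- function(Ca, Cb, M, alpha, a, b, lam = NULL, lam_rel = 5e-3,
                          tol = 1e-7, max_outer = 100L, init = "product",
                          anneal = TRUE, sinkhorn_tol = 1e-8,
                          sinkhorn_max = 500L, T0 = NULL) {
  n <- nrow(Ca); m <- nrow(Cb)
  fCa <- drop((Ca * Ca) %*% a)
  fCb <- drop((Cb * Cb) %*% b)
  constC <- outer(fCa, rep(1, m)) + outer(rep(1, n), fCb)
  tens <- function(T) constC - 2 * (Ca %*% T %*% Cb)
  obj <- function(T, tT = NULL) {
    if (is.null(tT)) tT <- tens(T)
    sum(M * T) + alpha * sum(tT * T)
  }
  T <- if (!is.null(T0)) T0
       else if (identical(init, "identity")) {
         if (n != m) stop("identity initialization needs n == m", call. = FALSE)
         diag(a, n)
       } else outer(a, b)

  G0 <- M + 2 * alpha * tens(T)
  if (is.null(lam)) {
    sc <- median(abs(G0))
    lam <- lam_rel * if (sc > 0) sc else 1
  }

  warm <- NULL
  step <- function(T, lam_s, warm, inner_max = sinkhorn_max,
                   inner_tol = sinkhorn_tol) {
    G <- M + 2 * alpha * tens(T)
    sk <- sinkhorn_core(G, a, b, lam_s, inner_tol, inner_max, warm)
    list(T = sk$matrix, warm = sk$warm, G = G)
  }

  if (anneal) {
    # initialization phase: coarse-to-fine entropic weights with loose inner
    # tolerance; only the final solve below is run to full precision
    for (lam_s in lam * c(50, 10, 3)) {
      warm <- NULL                       # potentials are lam-specific
      for (it in seq_len(8L)) {
        st <- step(T, lam_s, warm, inner_max = 200L, inner_tol = 1e-6)
        dT <- max(abs(st$T - T))
        T <- st$T; warm <- st$warm
        if (dT < 1e-10) break
      }
    }
    warm <- NULL
  }

  o_cur <- obj(T)
  trace <- o_cur
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    st <- step(T, lam, warm)
    o_new <- obj(st$T)
    if (o_new > o_cur + 1e-9 * max(1, abs(o_cur))) break  # reject increase
    rel <- abs(o_cur - o_new) / max(1e-300, abs(o_cur))
    T <- st$T; warm <- st$warm; o_cur <- o_new
    trace <- c(trace, o_new)
    if (rel < tol) { converged <- TRUE; break }
  }
  # feasibility polish: finish the scaling iterations at the current gradient
  # if the accepted plan's marginals are not yet tight
  merr <- max(max(abs(rowSums(T) - a)), max(abs(colSums(T) - b)))
  if (merr > 1e-7) {
    G <- M + 2 * alpha * tens(T)
    sk <- sinkhorn_core(G, a, b, lam, 1e-9, 5000L, warm)
    T <- sk$matrix
    merr <- max(max(abs(rowSums(T) - a)), max(abs(colSums(T) - b)))
    if (merr > 1e-7) T <- round_to_marginals(T, a, b)
    o_cur <- obj(T)
  }
  list(T = T, objective = o_cur, trace = trace, converged = converged,
       lam = lam, iterations = length(trace) - 1L)
}

#' Entropic Gromov-Wasserstein coupling between two metric spaces
#'
#' Minimizes the squared-loss G-W objective with entropic smoothing between
#' two within-domain distance matrices, which may have different sizes; each
#' outer iteration projects the gradient with Sinkhorn.
#'
#' @param Ca,Cb Square symmetric distance matrices (or `distance_matrix`
#'   objects), possibly of different sizes.
#' @param a,b Marginals (default uniform of the respective sizes).
#' @param lam Entropic weight; default `lam_rel` times the median magnitude of
#'   the initial gradient, so the smoothing scales with the problem.
#' @param lam_rel Relative entropic weight used when `lam` is `NULL`.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_outer Outer iteration cap.
#' @param init `"product"` (independent coupling) or `"identity"` (requires
#'   equal sizes).
#' @param anneal Run a short warm-start phase at geometrically decreasing
#'   entropic weights before the final solve.
#' @return A `transport_plan` with fields `objective_value` (the G-W
#'   objective, entropy excluded), `objective_trace` (non-increasing over the
#'   final solve's outer iterations) and `converged`.
#' @export
entropic_gw <- function(Ca, Cb, a = NULL, b = NULL, lam = NULL, lam_rel = 5e-3,
                        tol = 1e-7, max_outer = 100L, init = "product",
                        anneal = TRUE) {
  Ca <- dm_values(Ca); Cb <- dm_values(Cb)
  n <- nrow(Ca); m <- nrow(Cb)
  a <- if (is.null(a)) uniform_hist(n) else check_histogram(a, n, "a")
  b <- if (is.null(b)) uniform_hist(m) else check_histogram(b, m, "b")
  res <- ot_quad_solve(Ca, Cb, M = matrix(0, n, m), alpha = 1, a = a, b = b,
                       lam = lam, lam_rel = lam_rel, tol = tol,
                       max_outer = max_outer, init = init, anneal = anneal)
  new_transport_plan(res$T, a, b, res$objective, res$converged,
                     res$iterations, res$lam,
                     extra = list(objective_trace = res$trace))
}

#' Fused Gromov-Wasserstein distance between labeled metric spaces
#'
#' Combines a feature-matching cost (squared difference of the scalar labels,
#' weight `1 - alpha`) with the G-W structure cost (weight `alpha`).
#'
#' @inheritParams entropic_gw
#' @param fa,fb Numeric label/feature vectors for the two sides.
#' @param alpha Structure/feature trade-off in `[0, 1]`; `alpha = 1` recovers
#'   plain G-W.
#' @param q Loss exponent (default 2, squared losses).
#' @return List with `value` (the FG-W objective at the plan) and `plan` (a
#'   `transport_plan`).
#' @export
fgw_distance <- function(Ca, Cb, fa, fb, a = NULL, b = NULL, alpha = 0.5,
                         q = 2, lam = NULL, lam_rel = 5e-3, tol = 1e-7,
                         max_outer = 100L, anneal = TRUE) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  Ca <- dm_values(Ca); Cb <- dm_values(Cb)
  n <- nrow(Ca); m <- nrow(Cb)
  if (length(fa) != n || length(fb) != m)
    stop("feature vectors must match the distance matrices", call. = FALSE)
  a <- if (is.null(a)) uniform_hist(n) else check_histogram(a, n, "a")
  b <- if (is.null(b)) uniform_hist(m) else check_histogram(b, m, "b")
  M <- (1 - alpha) * abs(outer(fa, fb, "-"))^q
  res <- ot_quad_solve(Ca, Cb, M = M, alpha = alpha, a = a, b = b, lam = lam,
                       lam_rel = lam_rel, tol = tol, max_outer = max_outer,
                       anneal = anneal)
  plan <- new_transport_plan(res$T, a, b, res$objective, res$converged,
                             res$iterations, res$lam,
                             extra = list(objective_trace = res$trace))
  list(value = res$objective, plan = plan)
}

#' Fused Gromov-Wasserstein barycenter of labeled distance matrices
#'
#' Block coordinate descent for the Frechet mean under the FG-W distance:
#' alternately (i) solves the K coupling subproblems with the barycenter
#' `(C, f)` fixed, and (ii) updates `C` (weighted quadratic average of the
#' inputs under the couplings) and `f` (weighted average of the input
#' features) in closed form.  All histograms are uniform.
#'
#' @param Cs List of square symmetric distance matrices (or `distance_matrix`
#'   objects), one per input session.
#' @param fs List of numeric label vectors matching `Cs`.
#' @param zeta Input weights summing to 1 (default even).
#' @param alpha,q As in [fgw_distance()].
#' @param N_bary Barycenter support size; defaults to the common input size
#'   (rounded mean when the inputs differ).
#' @param lam,lam_rel Entropic weight for the coupling subproblems.
#' @param tol Relative objective-change tolerance of the outer BCD loop.
#' @param max_iter Outer BCD iteration cap.
#' @return Object of class `barycenter`: `distance_matrix` (N x N), `features`
#'   (length-N numeric), `couplings` (list of `transport_plan`),
#'   `weights_used`, `objective_trace` (non-increasing), `converged`.
#' @export
fgw_barycenter <- function(Cs, fs, zeta = NULL, alpha = 0.5, q = 2,
                           N_bary = NULL, lam = NULL, lam_rel = 5e-3,
                           tol = 1e-6, max_iter = 30L) {
  if (length(Cs) == 0L) stop("empty input list", call. = FALSE)
  if (length(Cs) != length(fs)) stop("Cs and fs must match", call. = FALSE)
  Cs <- lapply(Cs, dm_values)
  K <- length(Cs)
  Ns <- vapply(Cs, nrow, integer(1))
  for (k in seq_len(K))
    if (length(fs[[k]]) != Ns[k])
      stop("feature vector ", k, " does not match its matrix", call. = FALSE)
  zeta <- if (is.null(zeta)) rep(1 / K, K) else zeta
  if (abs(sum(zeta) - 1) > 1e-9) stop("zeta must sum to 1", call. = FALSE)
  if (is.null(N_bary))
    N_bary <- if (length(unique(Ns)) == 1L) Ns[1] else as.integer(round(mean(Ns)))
  a <- uniform_hist(N_bary)

  # deterministic init: the dominant input, ordered by label, resampled to
  # N_bary evenly spaced support points
  k0 <- which.max(zeta)
  ord <- order(fs[[k0]])
  idx <- ord[unique(pmax(1L, round(seq(1, Ns[k0], length.out = N_bary))))]
  if (length(idx) < N_bary)
    idx <- rep_len(idx, N_bary)
  C <- Cs[[k0]][idx, idx]
  f <- fs[[k0]][idx]

  plans <- vector("list", K)
  Ts <- lapply(Ns, function(nk) outer(a, uniform_hist(nk)))
  o_cur <- Inf; trace <- numeric(0); converged <- FALSE
  lam_used <- lam
  for (it in seq_len(max_iter)) {
    o_new <- 0
    plans_new <- vector("list", K); Ts_new <- vector("list", K)
    for (k in seq_len(K)) {
      bk <- uniform_hist(Ns[k])
      Mk <- (1 - alpha) * abs(outer(f, fs[[k]], "-"))^q
      res <- ot_quad_solve(C, Cs[[k]], M = Mk, alpha = alpha, a = a, b = bk,
                           lam = lam_used, lam_rel = lam_rel, tol = tol,
                           max_outer = 25L, anneal = (it == 1L),
                           T0 = if (it > 1L) Ts[[k]] else NULL)
      if (is.null(lam_used)) lam_used <- res$lam   # freeze across k and iters
      plans_new[[k]] <- new_transport_plan(res$T, a, bk, res$objective,
                                           res$converged, res$iterations,
                                           res$lam)
      Ts_new[[k]] <- res$T
      o_new <- o_new + zeta[k] * res$objective
    }
    if (o_new > o_cur + 1e-9 * max(1, abs(o_cur))) break  # keep previous iterate
    rel <- if (is.finite(o_cur)) abs(o_cur - o_new) / max(1e-300, abs(o_cur)) else Inf
    plans <- plans_new; Ts <- Ts_new; o_cur <- o_new
    trace <- c(trace, o_new)
    if (rel < tol) { converged <- TRUE; break }
    # closed-form updates under the couplings (uniform barycenter histogram)
    Cnum <- matrix(0, N_bary, N_bary); fnum <- numeric(N_bary)
    for (k in seq_len(K)) {
      Tk <- Ts[[k]]
      Cnum <- Cnum + zeta[k] * (Tk %*% Cs[[k]] %*% t(Tk))
      fnum <- fnum + zeta[k] * drop(Tk %*% fs[[k]])
    }
    C <- Cnum / outer(a, a)
    C <- (C + t(C)) / 2
    diag(C) <- 0
    f <- fnum / a
  }
  structure(list(distance_matrix = C, features = f, couplings = plans,
                 weights_used = zeta, objective = o_cur,
                 objective_trace = trace, converged = converged,
                 lam = lam_used),
            class = "barycenter")
}

#' @export
print.barycenter <- function(x, ...) {
  cat("<barycenter> N=", nrow(x$distance_matrix), ", K=", length(x$couplings),
      " inputs; objective ", signif(x$objective, 6),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}
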