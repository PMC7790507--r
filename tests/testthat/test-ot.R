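test_that("sinkhorn solves the degenerate and near-LP cases", {
  p <- sinkhorn(matrix(0, 4, 4), lam = 0.1)
  expect_equal(p$matrix, matrix(1 / 16, 4, 4), tolerance = 1e-9)
  expect_feasible(p)

  # 2x2 antidiagonal cost, uniform marginals: the feasible set is the segment
  # T(t) = [[t, 1/2 - t], [1/2 - t, t]], objective 1 - 2t -> optimum t = 1/2
  p2 <- sinkhorn(matrix(c(0, 1, 1, 0), 2), lam = 1e-4)
  expect_equal(p2$matrix, diag(2) / 2, tolerance = 1e-6)
  expect_feasible(p2)

  # feasibility contract on random rectangular instances, including tiny lam
  set.seed(8)
  for (k in 1:10) {
    n <- sample(3:7, 1); m <- sample(3:7, 1)
    lam <- 10^runif(1, -6, -1)
    p3 <- sinkhorn(matrix(runif(n * m), n, m), lam = lam)
    expect_feasible(p3)
  }
  expect_error(sinkhorn(matrix(0, 2, 2), lam = -1), "positive")
  expect_error(sinkhorn(matrix(c(0, Inf, 0, 0), 2), lam = 1), "finite")
})

test_that("entropic G-W beats every permutation on a self-comparison", {
  Ca <- rand_metric(6, seed = 9)
  g <- entropic_gw(Ca, Ca, lam_rel = 1e-3, init = "identity")
  expect_feasible(g)
  expect_monotone_trace(g$objective_trace)
  o_plan <- gw_objective_quad(Ca, Ca, g$matrix)
  for (p in all_perms(6)) {
    Tp <- diag(6)[unlist(p), ] / 6
    expect_lte(o_plan, gw_objective_quad(Ca, Ca, Tp) + 1e-9)
  }
})

test_that("entropic G-W recovers a planted permutation by column argmax", {
  for (sd in 1:3) {
    n <- 5 + sd %% 2
    Ca <- rand_metric(n, seed = 20 + sd)
    set.seed(30 + sd)
    perm <- sample(n)
    P <- diag(n)[perm, ]
    Cb <- P %*% Ca %*% t(P)
    g <- entropic_gw(Ca, Cb, lam_rel = 1e-3)
    expect_feasible(g)
    bc <- binarize_coupling(g)
    expect_equal(transfer_labels(bc, seq_len(n)), perm)
  }
})

test_that("all-zero structure matrices give the independence coupling", {
  g <- entropic_gw(matrix(0, 4, 4), matrix(0, 5, 5), lam = 0.01, anneal = FALSE)
  expect_equal(g$matrix, outer(rep(1 / 4, 4), rep(1 / 5, 5)), tolerance = 1e-9)
})

test_that("the G-W objective is symmetric in its arguments", {
  Ca <- rand_metric(7, seed = 40); Cb <- rand_metric(5, seed = 41)
  g1 <- entropic_gw(Ca, Cb, lam_rel = 1e-3)
  g2 <- entropic_gw(Cb, Ca, lam_rel = 1e-3)
  expect_equal(g1$objective_value, g2$objective_value,
               tolerance = 1e-4 * max(1, abs(g1$objective_value)))
})

test_that("fused G-W interpolates between feature matching and structure matching", {
  Ca <- rand_metric(4, seed = 50); Cb <- rand_metric(4, seed = 51)
  fa <- c(0, 1, 2, 3); fb <- c(3, 1, 0, 2)
  # alpha = 1: coincides with plain entropic G-W
  f1 <- fgw_distance(Ca, Cb, fa, fb, alpha = 1, lam_rel = 1e-3)
  g <- entropic_gw(Ca, Cb, lam_rel = 1e-3)
  expect_equal(f1$value, g$objective_value, tolerance = 1e-8)
  expect_equal(f1$plan$matrix, g$matrix, tolerance = 1e-8)
  # alpha = 0: pure label matching concentrates on equal-label pairs
  f0 <- fgw_distance(Ca, Cb, fa, fb, alpha = 0, lam_rel = 1e-4)
  expect_feasible(f0$plan)
  expect_lt(f0$value, 1e-6)
  on_label <- sum(f0$plan$matrix[cbind(1:4, match(fa, fb))])
  expect_gt(on_label, 1 - 1e-6)
  # the reported objective matches an independent quadruple-sum evaluation
  fh <- fgw_distance(Ca, Cb, fa, fb, alpha = 0.5, lam_rel = 1e-3)
  expect_equal(fh$value,
               fgw_objective_quad(Ca, Cb, fa, fb, 0.5, fh$plan$matrix),
               tolerance = 1e-9)
  expect_monotone_trace(fh$plan$objective_trace)
})

test_that("the FG-W barycenter of identical inputs reproduces the input", {
  Cin <- rand_metric(8, seed = 60)
  f <- c(0, 0, 1, 1, 2, 2, 3, 3)
  b1 <- fgw_barycenter(list(Cin), list(f), lam_rel = 1e-3)
  expect_lt(b1$objective, 1e-8)
  expect_equal(sort(b1$features), sort(f), tolerance = 1e-6)
  expect_equal(sort(as.vector(b1$distance_matrix)), sort(as.vector(Cin)),
               tolerance = 1e-5)
  for (pl in b1$couplings) expect_feasible(pl)

  b3 <- fgw_barycenter(list(Cin, Cin, Cin), list(f, f, f), lam_rel = 1e-3)
  expect_lt(b3$objective, 1e-8)
  expect_equal(sort(as.vector(b3$distance_matrix)), sort(as.vector(Cin)),
               tolerance = 1e-5)
  expect_monotone_trace(b3$objective_trace)

  # degenerate weights reduce to the single-input case
  C2 <- rand_metric(8, seed = 61)
  bz <- fgw_barycenter(list(Cin, C2), list(f, rev(f)), zeta = c(1, 0),
                       lam_rel = 1e-3)
  expect_lt(abs(bz$objective), 1e-8)
  expect_equal(sort(as.vector(bz$distance_matrix)), sort(as.vector(Cin)),
               tolerance = 1e-5)
  expect_error(fgw_barycenter(list(), list()), "empty")
})
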