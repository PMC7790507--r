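test_that("segment covariances concentrate on the truth and stay positive-definite", {
  set.seed(2)
  d <- 4L; w <- 5000L
  X <- matrix(rnorm(d * w), d, w)                  # iid unit-variance rows
  fe <- segment_features(list(X), shrinkage = 0)
  expect_lt(max(abs(fe$covariances[[1]] - diag(d))), 0.1)
  expect_equal(drop(fe$means[, 1]), rowMeans(X))

  # constant segment: shrinkage turns the zero matrix into a small multiple of I
  fe0 <- segment_features(list(matrix(1, 3, 10)), shrinkage = 0.01)
  ev <- eigen(fe0$covariances[[1]], symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_error(segment_features(list(matrix(1, 3, 10)), shrinkage = 0),
               "shrinkage")

  # more rows than window samples: the raw sample covariance is
  # rank-deficient (rank <= w - 1), the shrinkage-regularized one is SPD
  set.seed(3)
  X2 <- matrix(rnorm(80 * 60), 80, 60)
  P_raw <- tcrossprod(X2 - rowMeans(X2)) / 59
  expect_lt(min(eigen(P_raw, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  fe2 <- segment_features(list(X2), shrinkage = 0.05)
  expect_gt(min(eigen(fe2$covariances[[1]], symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("the matrix Hellinger distance matches its closed forms", {
  expect_equal(hellinger(matrix(1, 1, 1), matrix(4, 1, 1)), 1)   # |sqrt1 - sqrt4|
  expect_equal(hellinger(diag(c(1, 4)), diag(c(9, 16))), sqrt(8))
  A <- rand_spd(6, seed = 1)
  expect_equal(hellinger(A, A), 0, tolerance = 1e-6)
  # commuting case: distance reduces to ||A^{1/2} - B^{1/2}||_F
  set.seed(4)
  for (k in 1:20) {
    Q <- qr.Q(qr(matrix(rnorm(25), 5)))
    la <- runif(5, 0.1, 3); lb <- runif(5, 0.1, 3)
    A <- Q %*% diag(la) %*% t(Q); B <- Q %*% diag(lb) %*% t(Q)
    expect_equal(hellinger(A, B), sqrt(sum((sqrt(la) - sqrt(lb))^2)),
                 tolerance = 1e-8)
  }
  expect_error(hellinger(matrix(c(1, 2, 2, 1), 2), diag(2)), "positive-definite")
  expect_error(hellinger(matrix(1:4, 2), diag(2)), "symmetric")
})

test_that("hellinger is a metric with congruence scaling sqrt(c)", {
  set.seed(5)
  for (k in 1:40) {
    d <- sample(2:6, 1)
    A <- rand_spd(d); B <- rand_spd(d); C <- rand_spd(d)
    dab <- hellinger(A, B); dbc <- hellinger(B, C); dac <- hellinger(A, C)
    expect_gte(dab, 0)
    expect_equal(dab, hellinger(B, A), tolerance = 1e-10)
    expect_lte(dac, dab + dbc + 1e-10)
    cc <- runif(1, 0.2, 4)
    expect_equal(hellinger(cc * A, cc * B), sqrt(cc) * dab, tolerance = 1e-8)
  }
})

test_that("inner distance matrices match per-pair brute force", {
  set.seed(6)
  d <- 5L; N <- 7L
  covs <- lapply(1:N, function(i) rand_spd(d))
  means <- matrix(rnorm(d * N), d, N)
  fe <- structure(list(covariances = covs, means = means, labels = NULL,
                       d = d, shrinkage = 0), class = "segment_features")
  Cs <- session_distance_matrix(fe)
  Cj <- subject_distance_matrix(fe)
  expect_equal(Cs$kind, "session"); expect_equal(Cj$kind, "subject")
  for (i in 1:N) for (j in 1:N) {
    h <- if (i == j) 0 else hellinger(covs[[i]], covs[[j]])
    m <- sqrt(sum((means[, i] - means[, j])^2))
    expect_equal(Cs$values[i, j], (h + m) / d, tolerance = 1e-9)
    expect_equal(Cj$values[i, j], h / d, tolerance = 1e-9)
  }
  expect_true(isSymmetric(Cs$values))
  expect_true(all(diag(Cs$values) == 0))
  expect_true(all(Cs$values >= 0))
})

test_that("the subject metric ignores means; the session metric does not", {
  set.seed(7)
  d <- 4L; N <- 5L
  covs <- lapply(1:N, function(i) rand_spd(d))
  m1 <- matrix(rnorm(d * N), d, N)
  m2 <- m1 + matrix(rnorm(d * N, sd = 10), d, N)   # wildly different means
  fe1 <- structure(list(covariances = covs, means = m1, d = d, shrinkage = 0),
                   class = "segment_features")
  fe2 <- structure(list(covariances = covs, means = m2, d = d, shrinkage = 0),
                   class = "segment_features")
  expect_equal(subject_distance_matrix(fe1)$values,
               subject_distance_matrix(fe2)$values, tolerance = 1e-12)
  expect_gt(max(abs(session_distance_matrix(fe1)$values -
                      session_distance_matrix(fe2)$values)), 0.1)
  # identical means: the two metrics coincide
  feq <- structure(list(covariances = covs, means = matrix(0, d, N), d = d,
                        shrinkage = 0), class = "segment_features")
  expect_equal(session_distance_matrix(feq)$values,
               subject_distance_matrix(feq)$values, tolerance = 1e-12)
})
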