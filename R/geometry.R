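# Segment features (covariance + mean) and the inner distance matrices built
# on the matrix Hellinger distance.

# Symmetric PSD square root via eigendecomposition with an eigenvalue floor.
sqrtm_sym <- function(A, floor = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  ev <- pmax(e$values, floor)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

check_spd <- function(A, name = "matrix") {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(name, " must be square", call. = FALSE)
  if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))))
    stop(name, " is not symmetric", call. = FALSE)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(name, " is not positive-definite", call. = FALSE)
  invisible(TRUE)
}

#' Matrix Hellinger distance between SPD matrices
#'
#' Computes
#' \deqn{\rho(A,B) = \{tr(A+B) - 2\,tr[A^{1/2}(A^{-1/2} B A^{-1/2})^{1/2} A^{1/2}]\}^{1/2},}
#' evaluated via the equivalent nuclear-norm form
#' `tr(A) + tr(B) - 2 ||A^{1/2} B^{1/2}||_*`.  For commuting arguments it
#' reduces to the Frobenius norm of `A^{1/2} - B^{1/2}`.  Tiny negative values
#' under the outer square root (|value| < 1e-8) are clamped to zero; larger
#' negatives raise an error.
#'
#' @param A,B Symmetric positive-definite matrices of equal size.
#' @return Nonnegative scalar; zero iff `A == B`.
#' @export
hellinger <- function(A, B) {
  check_spd(A, "A"); check_spd(B, "B")
  if (nrow(A) != nrow(B)) stop("A and B must have equal size", call. = FALSE)
  SA <- sqrtm_sym(A); SB <- sqrtm_sym(B)
  nuc <- sum(svd(SA %*% SB, nu = 0, nv = 0)$d)
  v <- sum(diag(A)) + sum(diag(B)) - 2 * nuc
  if (v < 0) {
    if (v > -1e-8) v <- 0
    else stop("negative value under square root in Hellinger distance",
              call. = FALSE)
  }
  sqrt(v)
}

#' Per-segment covariance and mean features
#'
#' For each `d x w` segment, the sample covariance over time plus shrinkage
#' regularization `shrinkage * (tr(P)/d) * I` (guaranteeing strict positive
#' definiteness even when `w <= d`), and the row-mean vector.
#'
#' @param segments A `segment_set` (or plain list of `d x w` matrices).
#' @param shrinkage Nonnegative shrinkage weight (default 0.05).
#' @return Object of class `segment_features`: `covariances` (list of SPD
#'   `d x d`), `means` (`d x N` matrix), `labels` (if available), `d`,
#'   `shrinkage`.
#' @export
segment_features <- function(segments, shrinkage = 0.05) {
  labels <- NULL
  if (inherits(segments, "segment_set")) {
    labels <- segments$labels
    segments <- segments$segments
  }
  stopifnot(length(segments) >= 1L)
  d <- nrow(segments[[1]])
  w <- ncol(segments[[1]])
  if (w < 2L) stop("window length must be >= 2", call. = FALSE)
  covs <- vector("list", length(segments))
  means <- matrix(0, d, length(segments))
  for (i in seq_along(segments)) {
    X <- segments[[i]]
    h <- rowMeans(X)
    P <- tcrossprod(X - h) / (w - 1)
    tr <- sum(diag(P))
    if (tr <= 0 && shrinkage <= 0)
      stop("zero-variance segment: positive shrinkage required", call. = FALSE)
    if (tr <= 0) tr <- d                       # degenerate: fall back to I scale
    P <- P + shrinkage * (tr / d) * diag(d)
    if (shrinkage <= 0) {
      ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0)
        stop("rank-deficient segment covariance: positive shrinkage required",
             call. = FALSE)
    }
    covs[[i]] <- P
    means[, i] <- h
  }
  structure(list(covariances = covs, means = means, labels = labels,
                 d = d, shrinkage = shrinkage),
            class = "segment_features")
}

# N x N matrix of pairwise Hellinger distances between the feature covariances
# (C++ kernel over precomputed symmetric square roots).
hellinger_gram <- function(features) {
  covs <- features$covariances
  N <- length(covs); d <- features$d
  S <- array(0, c(d, d, N)); trs <- numeric(N)
  for (i in seq_len(N)) {
    S[, , i] <- sqrtm_sym(covs[[i]])
    trs[i] <- sum(diag(covs[[i]]))
  }
  hellinger_gram_cpp(S, trs)
}

new_distance_matrix <- function(values, kind, d_norm) {
  structure(list(values = values, kind = kind, d_norm = as.integer(d_norm)),
            class = "distance_matrix")
}

#' Within-session inner distance matrix (Hellinger + mean term)
#'
#' Entry (i, i') is `(rho_hellinger(P_i, P_i') + ||h_i - h_i'||_2) / d`,
#' normalizing by the stacked channel count d of the session.
#'
#' @param features A [segment_features()] object.
#' @return A `distance_matrix` of kind `"session"`.
#' @export
session_distance_matrix <- function(features) {
  H <- hellinger_gram(features)
  M <- unname(as.matrix(stats::dist(t(features$means))))
  new_distance_matrix((H + M) / features$d, "session", features$d)
}

#' Mean-free inner distance matrix for cross-subject alignment
#'
#' Entry (i, i') is `rho_hellinger(P_i, P_i') / d`; the mean-difference term is
#' dropped because mean offsets are subject-specific, leaving a distance on
#' segment covariances only.
#'
#' @inheritParams session_distance_matrix
#' @return A `distance_matrix` of kind `"subject"`.
#' @export
subject_distance_matrix <- function(features) {
  H <- hellinger_gram(features)
  new_distance_matrix(H / features$d, "subject", features$d)
}

# Accept either a distance_matrix or a plain matrix.
dm_values <- function(x) {
  if (inherits(x, "distance_matrix")) x$values else as.matrix(x)
}
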