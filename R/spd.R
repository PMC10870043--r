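#' Spatial covariance matrix of an EMG window
#'
#' The channel-by-channel second-moment matrix `X X' / (N - 1)` of a
#' (mean-uncentred) window `X` with C channels and N time samples, plus an
#' optional diagonal shrinkage `shrinkage * (trace / C) * I` that
#' guarantees positive definiteness for rank-deficient windows without
#' materially perturbing well-conditioned ones (for an all-zero window,
#' where the trace scale is undefined, plain `shrinkage * I` is used).
#'
#' @param window Numeric matrix, channels x samples (C >= 2, N >= 2).
#' @param shrinkage Non-negative diagonal loading factor (default 1e-8).
#' @return A C x C symmetric positive (semi-)definite matrix of class
#'   `spd_matrix`.
#' @examples
#' spatial_covariance(matrix(c(1, 2, -1, -2), nrow = 2), shrinkage = 0)
#' @export
spatial_covariance <- function(window, shrinkage = 1e-8) {
  if (!is.matrix(window) || !is.numeric(window)) {
    stop_emg("invalid_samples", "`window` must be a numeric matrix")
  }
  if (ncol(window) < 2) stop_emg("too_few_samples", "need N >= 2 time samples")
  if (nrow(window) < 2) stop_emg("too_few_channels", "need C >= 2 channels")
  if (!all(is.finite(window))) stop_emg("nonfinite_samples", "non-finite window values")
  if (shrinkage < 0) stop_emg("invalid_shrinkage", "`shrinkage` must be >= 0")
  C <- nrow(window)
  scm <- tcrossprod(window) / (ncol(window) - 1)
  scm <- (scm + t(scm)) / 2
  if (shrinkage > 0) {
    tr <- sum(diag(scm))
    scale <- if (tr > 0) tr / C else 1
    scm <- scm + diag(shrinkage * scale, C)
  }
  structure(scm, class = c("spd_matrix", "matrix", "array"))
}

#' @export
print.spd_matrix <- function(x, ...) {
  cat(sprintf("<spd_matrix> %d x %d\n", nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

as_spd <- function(x) {
  x <- as.matrix(x)
  if (max(abs(x - t(x))) > 1e-10 * max(1, max(abs(x)))) {
    stop_emg("not_symmetric", "matrix is not symmetric")
  }
  (x + t(x)) / 2
}

# eigendecomposition with positivity check; shared by all spd ops
eig_spd <- function(P, require_pd = TRUE) {
  e <- eigen(as_spd(P), symmetric = TRUE)
  if (require_pd && any(e$values <= 0)) {
    stop_emg("not_positive_definite", "matrix has non-positive eigenvalues (min ",
             format(min(e$values)), ")")
  }
  e
}

# f applied to the spectrum: V f(L) V'
spd_fun <- function(P, f, require_pd = TRUE) {
  e <- eig_spd(P, require_pd)
  s <- e$vectors %*% (f(e$values) * t(e$vectors))
  (s + t(s)) / 2
}

#' Matrix logarithm and exponential on the SPD cone
#'
#' Eigendecomposition-based principal matrix log of a symmetric
#' positive-definite matrix, and matrix exponential of a symmetric matrix.
#' They are mutual inverses: `expm_sym(logm_spd(P)) == P` to ~1e-9.
#'
#' @param P Symmetric positive-definite matrix.
#' @param S Symmetric matrix.
#' @return A symmetric matrix (`logm_spd`) or SPD matrix (`expm_sym`).
#' @export
logm_spd <- function(P) spd_fun(P, log)

#' @rdname logm_spd
#' @export
expm_sym <- function(S) spd_fun(S, exp, require_pd = FALSE)

# P^(+/-1/2) pair, computed from one decomposition
sqrtm_pair <- function(P) {
  e <- eig_spd(P)
  sq <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  isq <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
  list(sqrt = (sq + t(sq)) / 2, isqrt = (isq + t(isq)) / 2)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta(P, Q) = sqrt(sum(log(lambda_i)^2))` where `lambda_i` are the
#' eigenvalues of `solve(P) %*% Q` (equivalently of the whitened matrix
#' `P^(-1/2) Q P^(-1/2)`). Invariant under congruence `P -> A P A'` by any
#' invertible `A`, i.e. under linear re-mixing of channels.
#'
#' @param P,Q Symmetric positive-definite matrices of equal dimension.
#' @return Non-negative scalar; zero iff `P == Q`.
#' @examples
#' airm_distance(diag(2), diag(c(exp(2), 1)))  # = 2
#' @export
airm_distance <- function(P, Q) {
  P <- as_spd(P); Q <- as_spd(Q)
  if (!all(dim(P) == dim(Q))) stop_emg("dim_mismatch", "P and Q differ in dimension")
  w <- sqrtm_pair(P)$isqrt
  lam <- eig_spd(w %*% Q %*% w)$values
  sqrt(sum(log(lam)^2))
}

#' Frechet (geometric) mean of SPD matrices
#'
#' The Riemannian centre of mass under the affine-invariant metric: the
#' point minimizing the sum of squared [airm_distance()]s to the inputs.
#' Computed by the standard fixed-point iteration
#' `M <- M^(1/2) expm(mean_i logm(M^(-1/2) P_i M^(-1/2))) M^(1/2)`,
#' initialized at the arithmetic mean, stopping when the Frobenius norm of
#' the mean log (the Riemannian gradient) drops below `tol`.
#'
#' @param covs List of SPD matrices of equal dimension (e.g. per-window
#'   spatial covariances).
#' @param weights Optional non-negative weights, normalized internally.
#' The step size starts at 1 and adapts to progress: the product of step
#' size and gradient norm is tracked against the best value seen, the step
#' shrinking gently (x0.95) while progress continues and halving when it
#' does not. This keeps the iteration contracting on large, widely spread
#' covariance sets where the unit-step iteration oscillates or stalls.
#'
#' @param tol Convergence tolerance on the gradient norm (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @return The mean as an `spd_matrix`, with attributes `iterations` and
#'   `gradient_norm`.
#' @examples
#' frechet_mean(list(diag(2), diag(c(exp(2), exp(2)))))  # = e * I
#' @export
frechet_mean <- function(covs, weights = NULL, tol = 1e-8, max_iter = 200) {
  if (length(covs) == 0) stop_emg("empty_input", "`covs` must be non-empty")
  covs <- lapply(covs, as_spd)
  d <- dim(covs[[1]])
  if (!all(vapply(covs, function(p) all(dim(p) == d), logical(1)))) {
    stop_emg("dim_mismatch", "all matrices must share one dimension")
  }
  if (length(covs) == 1) {
    return(structure(covs[[1]], class = c("spd_matrix", "matrix", "array"),
                     iterations = 0L, gradient_norm = 0))
  }
  w <- weights %||% rep(1, length(covs))
  w <- w / sum(w)
  M <- Reduce(`+`, Map(`*`, covs, w))
  grad_norm <- Inf
  nu <- 1                                   # adaptive step size
  tau <- Inf                                # best nu * grad_norm seen so far
  for (it in seq_len(max_iter)) {
    sp <- sqrtm_pair(M)
    logs <- lapply(covs, function(p) logm_spd(sp$isqrt %*% p %*% sp$isqrt))
    G <- Reduce(`+`, Map(`*`, logs, w))
    grad_norm <- sqrt(sum(G^2))
    if (grad_norm <= tol) {
      return(structure((M + t(M)) / 2, class = c("spd_matrix", "matrix", "array"),
                       iterations = it - 1L, gradient_norm = grad_norm))
    }
    h <- nu * grad_norm
    if (h < tau) {
      nu <- 0.95 * nu
      tau <- h
    } else {
      nu <- 0.5 * nu
    }
    M <- sp$sqrt %*% expm_sym(nu * G) %*% sp$sqrt
    M <- (M + t(M)) / 2
  }
  stop_emg("mean_nonconvergence",
           "Frechet mean did not converge in ", max_iter,
           " iterations (gradient norm ", format(grad_norm), ")")
}

#' Map SPD matrices to tangent-space feature vectors
#'
#' Each covariance `P` is whitened by the reference `M` and logged,
#' `S = logm(M^(-1/2) P M^(-1/2))`, then half-vectorized: upper triangle,
#' row-major, off-diagonal entries weighted by `sqrt(2)`. The weighting
#' makes the map an isometry at the reference: the Euclidean norm of the
#' feature vector of `P` equals `airm_distance(M, P)`. Feature dimension
#' is `C (C + 1) / 2` (36 for 8 channels).
#'
#' @param covs List of SPD matrices (or a single matrix).
#' @param reference The SPD reference point `M`, normally the
#'   [frechet_mean()] of the *training* covariances.
#' @return A `tangent_features` object: numeric matrix n x d with the
#'   reference stored as attribute `"reference"`.
#' @export
tangent_map <- function(covs, reference) {
  if (is.matrix(covs)) covs <- list(covs)
  M <- as_spd(reference)
  isq <- sqrtm_pair(M)$isqrt
  C <- nrow(M)
  # row-major upper triangle: transpose trick yields (i,j), i<=j ordered by row
  vecs <- t(vapply(covs, function(p) {
    if (!all(dim(p) == dim(M))) stop_emg("dim_mismatch", "covariance/reference dimension mismatch")
    s <- logm_spd(isq %*% as_spd(p) %*% isq)
    t(s)[t(upper.tri(s, diag = TRUE))] * row_major_weights(C)
  }, numeric(C * (C + 1) / 2)))
  ij <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  colnames(vecs) <- paste0("s", ij[order(ij[, 1], ij[, 2]), 1], "_",
                           ij[order(ij[, 1], ij[, 2]), 2])
  structure(vecs, class = c("tangent_features", "matrix", "array"), reference = M)
}

row_major_weights <- function(C) {
  unlist(lapply(seq_len(C), function(i) c(1, rep(sqrt(2), C - i))))
}

#' @export
print.tangent_features <- function(x, ...) {
  cat(sprintf("<tangent_features> %d vectors of dimension %d\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Geodesic between two SPD matrices
#'
#' The affine-invariant geodesic `P^(1/2) (P^(-1/2) Q P^(-1/2))^t P^(1/2)`
#' at parameter `t`; `t = 0.5` is the midpoint, which equals the Frechet
#' mean of the pair.
#'
#' @param P,Q SPD matrices.
#' @param t Position along the geodesic in `[0, 1]`.
#' @return An SPD matrix.
#' @export
spd_geodesic <- function(P, Q, t = 0.5) {
  sp <- sqrtm_pair(as_spd(P))
  inner <- spd_fun(sp$isqrt %*% as_spd(Q) %*% sp$isqrt, function(l) l^t)
  m <- sp$sqrt %*% inner %*% sp$sqrt
  (m + t(m)) / 2
}
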