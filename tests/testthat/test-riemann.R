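# test-local AIRM tools, kept independent of the package implementation:
# distance via the whitened-log Frobenius norm with chol/solve (no shared
# code path with airm_distance's P^-1 Q eigenvalue formula)
ref_airm <- function(P, Q) {
  L <- chol(P)                      # P = L'L
  W <- solve(t(L), t(solve(t(L), t(Q))))   # L'^-1 Q L^-1, similar whitening
  lam <- eigen((W + t(W)) / 2, symmetric = TRUE)$values
  sqrt(sum(log(lam)^2))
}

test_that("spatial covariance matches the hand-computed X X' / (N - 1)", {
  X <- matrix(c(1, 2, -1, -2), nrow = 2)        # columns (1,2), (-1,-2)
  expect_equal(unclass(spatial_covariance(X, shrinkage = 0)),
               matrix(c(2, 4, 4, 8), 2), ignore_attr = TRUE)

  # all-zero window with shrinkage eps -> eps I
  Z <- matrix(0, 3, 10)
  expect_equal(unclass(spatial_covariance(Z, shrinkage = 1e-4)),
               diag(1e-4, 3), ignore_attr = TRUE)

  set.seed(7)
  W <- matrix(rnorm(8 * 600), 8)
  scm <- spatial_covariance(W)
  expect_identical(dim(scm), c(8L, 8L))
  expect_equal(unclass(scm), t(unclass(scm)))

  expect_error(spatial_covariance(matrix(1:2, 2, 1)), class = "emg_too_few_samples")
  expect_error(spatial_covariance(matrix(c(1, NA, 2, 3), 2)),
               class = "emg_nonfinite_samples")
})

test_that("SCMs with shrinkage are SPD for arbitrary (even rank-1) windows", {
  set.seed(8)
  for (i in 1:20) {
    C <- sample(2:8, 1)
    # rank-1 window: outer product of a channel pattern and a time course
    W <- outer(rnorm(C), rnorm(50))
    scm <- spatial_covariance(W, shrinkage = 1e-8)
    ev <- eigen(scm, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_lt(max(abs(scm - t(scm))), 1e-12 * max(abs(scm)))
  }
})

test_that("airm_distance has the closed-form value and metric properties", {
  P <- random_spd(4)
  expect_equal(airm_distance(P, P), 0, tolerance = 1e-10)
  expect_equal(airm_distance(diag(2), diag(c(exp(2), 1))), 2, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:25) {
    P <- random_spd(5); Q <- random_spd(5); R <- random_spd(5)
    d <- airm_distance(P, Q)
    expect_equal(d, ref_airm(P, Q), tolerance = 1e-8)
    expect_equal(d, airm_distance(Q, P), tolerance = 1e-8)   # symmetry
    expect_lte(d, airm_distance(P, R) + airm_distance(R, Q) + 1e-8)
    # affine invariance under congruence
    A <- matrix(rnorm(25), 5)
    expect_equal(airm_distance(A %*% P %*% t(A), A %*% Q %*% t(A)), d,
                 tolerance = 1e-8)
  }
  expect_error(airm_distance(diag(2), diag(3)), class = "emg_dim_mismatch")
  expect_error(airm_distance(diag(c(1, -1)), diag(2)),
               class = "emg_not_positive_definite")
})

test_that("frechet_mean matches closed forms and an independent minimizer", {
  P <- random_spd(3)
  expect_equal(unclass(frechet_mean(list(P))), P, ignore_attr = TRUE)

  # commuting case: geometric mean. {I, e^2 I} -> e I
  m <- frechet_mean(list(diag(2), diag(exp(2), 2)))
  expect_equal(unclass(m), diag(exp(1), 2), tolerance = 1e-8, ignore_attr = TRUE)

  # two-matrix mean = geodesic midpoint (closed form)
  set.seed(31)
  for (i in 1:5) {
    P <- random_spd(4); Q <- random_spd(4)
    mid <- spd_geodesic(P, Q, 0.5)
    expect_equal(unclass(frechet_mean(list(P, Q))), mid,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }

  # independent oracle: direct numerical minimization of the summed squared
  # distance over the symmetric-log parameterization M = expm(S), C = 2
  set.seed(32)
  covs <- replicate(4, random_spd(2), simplify = FALSE)
  obj <- function(par) {
    S <- matrix(c(par[1], par[3], par[3], par[2]), 2)
    e <- eigen(S, symmetric = TRUE)
    M <- e$vectors %*% (exp(e$values) * t(e$vectors))
    sum(vapply(covs, function(p) ref_airm(M, p)^2, numeric(1)))
  }
  opt <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  S <- matrix(c(opt$par[1], opt$par[3], opt$par[3], opt$par[2]), 2)
  e <- eigen(S, symmetric = TRUE)
  M_opt <- e$vectors %*% (exp(e$values) * t(e$vectors))
  M_fix <- frechet_mean(covs)
  expect_lt(airm_distance(M_opt, M_fix), 1e-4)

  # gradient condition at the returned mean
  expect_lt(attr(M_fix, "gradient_norm"), 1e-8)
})

test_that("frechet_mean is permutation-invariant and congruence-equivariant", {
  set.seed(33)
  covs <- replicate(6, random_spd(4), simplify = FALSE)
  m1 <- frechet_mean(covs)
  m2 <- frechet_mean(rev(covs))
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-7, ignore_attr = TRUE)

  A <- matrix(rnorm(16), 4)
  mA <- frechet_mean(lapply(covs, function(p) A %*% p %*% t(A)))
  expect_equal(unclass(mA), A %*% unclass(m1) %*% t(A),
               tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(frechet_mean(list()), class = "emg_empty_input")
  expect_error(frechet_mean(list(diag(2), diag(3))), class = "emg_dim_mismatch")
})

test_that("tangent mapping is the sqrt(2)-weighted isometric vectorization", {
  set.seed(41)
  M <- random_spd(8)
  # at the reference -> zero vector, dimension C(C+1)/2 = 36
  f0 <- tangent_map(list(M), M)
  expect_identical(ncol(f0), 36L)
  expect_lt(max(abs(f0)), 1e-10)

  covs <- replicate(10, random_spd(8), simplify = FALSE)
  feats <- tangent_map(covs, M)
  for (i in seq_along(covs)) {
    expect_equal(sqrt(sum(feats[i, ]^2)), airm_distance(M, covs[[i]]),
                 tolerance = 1e-8)
  }

  # at the Frechet mean, the tangent vectors average to ~0 (gradient condition)
  mu <- frechet_mean(covs, tol = 1e-10)
  fm <- tangent_map(covs, mu)
  expect_lt(sqrt(sum(colMeans(fm)^2)), 10 * 1e-10 + 1e-9)

  expect_error(tangent_map(list(diag(3)), M), class = "emg_dim_mismatch")
})

test_that("matrix log/exp round-trip on the SPD cone", {
  expect_equal(logm_spd(diag(3)), matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(logm_spd(diag(c(exp(1), exp(2)))), diag(1:2),
               tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(51)
  for (i in 1:5) {
    P <- random_spd(8)
    expect_lt(max(abs(expm_sym(logm_spd(P)) - P)), 1e-9 * max(abs(P)))
  }
  expect_error(logm_spd(matrix(1:4, 2)), class = "emg_not_symmetric")
})
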