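test_that("full-rank PLS equals ordinary least squares", {
  set.seed(12)
  for (trial in 1:10) {
    X <- matrix(rnorm(12 * 8), 12, 8)
    y <- rnorm(12)
    m <- fit_plsr(X, y, 8)
    ols <- unname(coef(lm(y ~ X))[-1])
    expect_equal(unname(m$beta), ols, tolerance = 1e-8)
    expect_equal(unname(regression_coefficients(m)), ols, tolerance = 1e-8)
  }
})

test_that("predictions agree with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(77)
  X <- matrix(rnorm(30 * 40), 30, 40)
  colnames(X) <- paste0("wl", 1:40)
  y <- drop(X %*% rnorm(40) * 0.1 + rnorm(30))
  m <- fit_plsr(X, y, 5)
  ref <- mixOmics::pls(X, y, ncomp = 5, scale = FALSE, mode = "regression")
  Xnew <- matrix(rnorm(10 * 40), 10, 40)
  colnames(Xnew) <- colnames(X)
  pref <- predict(ref, Xnew)$predict[, 1, 5]
  expect_equal(unname(predict(m, Xnew)), unname(pref), tolerance = 1e-8)
})

test_that("rank-1 signal is captured by a single component", {
  set.seed(3)
  d <- rnorm(20)
  t_score <- rnorm(15)
  X <- outer(t_score, d)
  y <- 2 * t_score + 5
  m <- fit_plsr(X, y, 1)
  expect_equal(unname(predict(m, X)), unname(y), tolerance = 1e-8)
})

test_that("model invariants hold on random fits", {
  set.seed(21)
  X <- matrix(rnorm(25 * 60), 25, 60)
  y <- rnorm(25)
  m <- fit_plsr(X, y, 8)
  # scores orthogonal, weights unit-norm, SS non-negative
  G <- crossprod(m$T)
  expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
  expect_equal(colSums(m$W^2), rep(1, m$A), tolerance = 1e-10)
  expect_true(all(m$SS >= 0))
  # beta reproduces fitted values through centering
  expect_equal(unname(predict(m, X)),
               unname(m$y_mean + drop(sweep(X, 2, m$x_mean) %*% m$beta)),
               tolerance = 1e-12)
  # centering: mean spectrum predicts y_mean
  expect_equal(unname(predict(m, matrix(m$x_mean, 1))), m$y_mean,
               tolerance = 1e-8)
  # training RMSE non-increasing in the component count
  rmse <- vapply(seq_len(m$A), function(a)
    sqrt(mean((y - predict(m, X, ncomp = a))^2)), 0)
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("VIP follows the explained-variance-weighted definition", {
  set.seed(5)
  X <- matrix(rnorm(20 * 12), 20, 12)
  y <- rnorm(20)
  m <- fit_plsr(X, y, 5)
  v <- vip(m)
  expect_true(all(v >= 0))
  expect_equal(sum(v^2), m$p, tolerance = 1e-8)
  # direct evaluation of the formula
  manual <- sqrt(m$p * drop((m$W^2) %*% m$SS) / sum(m$SS))
  expect_equal(v, manual, tolerance = 1e-10)

  # closed form: one component, weights (1, 0) -> VIP (sqrt(2), 0)
  t_score <- rnorm(15)
  X2 <- cbind(t_score, 0)
  m2 <- fit_plsr(X2 + 1e-12, t_score, 1)
  expect_equal(unname(vip(m2)), c(sqrt(2), 0), tolerance = 1e-6)

  # equal absolute weights -> all VIP exactly 1
  X3 <- outer(t_score, rep(1, 4))
  m3 <- fit_plsr(X3, t_score, 1)
  expect_equal(unname(vip(m3)), rep(1, 4), tolerance = 1e-12)
})

test_that("coefficients match the explicit W (P'W)^-1 q expansion", {
  set.seed(8)
  X <- matrix(rnorm(18 * 10), 18, 10)
  y <- rnorm(18)
  m <- fit_plsr(X, y, 4)
  beta_alg <- m$W %*% solve(crossprod(m$P, m$W), m$q)
  expect_equal(unname(m$beta), unname(drop(beta_alg)), tolerance = 1e-8)
})

test_that("the model is equivariant and shift-stable", {
  set.seed(13)
  X <- matrix(rnorm(16 * 9), 16, 9)
  y <- rnorm(16)
  m <- fit_plsr(X, y, 3)
  perm <- sample(9)
  mp <- fit_plsr(X[, perm], y, 3)
  expect_equal(mp$beta, m$beta[perm], tolerance = 1e-10)
  expect_equal(vip(mp), vip(m)[perm], tolerance = 1e-10)
  # adding a constant to y shifts only the intercept
  ms <- fit_plsr(X, y + 100, 3)
  expect_equal(ms$beta, m$beta, tolerance = 1e-8)
  expect_equal(ms$y_mean, m$y_mean + 100)
})

test_that("degenerate inputs are rejected or truncated", {
  X <- matrix(rnorm(10 * 4), 10, 4)
  expect_error(fit_plsr(X, rep(1, 10), 2), "zero-variance")
  expect_error(fit_plsr(X, c(rnorm(9), NA), 2), "non-finite")
  # rank deficiency truncates with a warning
  Xr <- outer(rnorm(10), rnorm(4))
  expect_warning(m <- fit_plsr(Xr, drop(Xr[, 1]) + 0, 3), "rank")
  expect_lt(m$A, 3)
  m4 <- fit_plsr(X, rnorm(10), 2)
  expect_error(predict(m4, X[, 1:3]), "mismatch")
  expect_error(vip(m4, ncomp = 5), "out of range")
})
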