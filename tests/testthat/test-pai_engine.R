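# Final model, cross-validated counterfactual predictions, PAI scores and
# Johnson-Neyman regions.

test_that("the empty model reduces to a difference of arm means", {
  set.seed(1)
  y <- rnorm(40)
  a <- rep(0:1, 20)
  m <- fit_final_model(y, a, matrix(0, 40, 0))
  expect_equal(unname(m$coef["arm"]),
               mean(y[a == 1]) - mean(y[a == 0]), tolerance = 1e-12)
})

test_that("final model equals the normal-equations oracle", {
  set.seed(2)
  n <- 10
  Z <- cbind(p1 = rnorm(n), m1 = rnorm(n))
  a <- rep(0:1, 5)
  y <- rnorm(n)
  m <- fit_final_model(y, a, Z, predictors = "p1", moderators = "m1")
  X <- cbind(1, a, Z[, "p1"], Z[, "m1"], Z[, "m1"] * a)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(m$coef), unname(drop(beta)), tolerance = 1e-10)
  s2 <- sum((y - X %*% beta)^2) / (n - 5)
  expect_equal(m$vcov, s2 * solve(crossprod(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # covariance is symmetric positive semidefinite
  expect_equal(m$vcov, t(m$vcov))
  expect_true(all(eigen(m$vcov, symmetric = TRUE)$values > -1e-12))
})

test_that("final model recovers generating coefficients at n=5000", {
  set.seed(3)
  n <- 5000
  Z <- cbind(p1 = rnorm(n), m1 = rnorm(n))
  a <- rep(0:1, n / 2)
  y <- 1 + 0.4 * a + 0.8 * Z[, "p1"] + 0.5 * Z[, "m1"] -
    0.7 * Z[, "m1"] * a + rnorm(n)
  m <- fit_final_model(y, a, Z, "p1", "m1")
  truth <- c(1, 0.4, 0.8, 0.5, -0.7)
  se <- sqrt(diag(m$vcov))
  expect_true(all(abs(m$coef - truth) < 3 * se))
})

test_that("leave-one-out predictions match the brute-force refit oracle", {
  set.seed(4)
  n <- 12
  Z <- cbind(m1 = rnorm(n))
  a <- rep(0:1, 6)
  y <- rnorm(n) + Z[, "m1"] * a
  folds <- seq_len(n)                      # k = n: each row its own fold
  tab <- crossval_predict(y, a, Z, moderators = "m1", folds = folds)
  for (i in seq_len(n)) {
    m <- fit_final_model(y[-i], a[-i], Z[-i, , drop = FALSE],
                         moderators = "m1")
    expect_equal(tab$pred_ct[i],
                 unname(paitrial:::predict_final(m, Z[i, , drop = FALSE], 0)),
                 tolerance = 1e-10)
    expect_equal(tab$pred_ipt[i],
                 unname(paitrial:::predict_final(m, Z[i, , drop = FALSE], 1)),
                 tolerance = 1e-10)
  }
})

test_that("null generating model shrinks the PAI toward zero", {
  mean_abs <- vapply(c(200, 2000), function(n) {
    set.seed(5)
    Z <- cbind(m1 = rnorm(n))
    y <- rnorm(n)
    a <- rep(0:1, n / 2)
    tab <- crossval_predict(y, a, Z, moderators = "m1", k = 5, seed = 6)
    mean(tab$pai_abs)
  }, 0)
  expect_lt(mean_abs[2], mean_abs[1])
  expect_lt(mean_abs[2], 0.2)
})

test_that("PAI signs follow the fold-model algebra", {
  set.seed(7)
  n <- 150
  Z <- cbind(m1 = rnorm(n))
  a <- rep(0:1, n / 2)
  y <- 2 + 1.5 * Z[, "m1"] * a + rnorm(n, 0, 0.5)
  tab <- crossval_predict(y, a, Z, moderators = "m1", k = 5, seed = 8)
  for (f in 1:5) {
    train <- tab$fold != f
    m <- fit_final_model(y[train], a[train], Z[train, , drop = FALSE],
                         moderators = "m1")
    test <- which(tab$fold == f)
    delta <- m$coef["arm"] + m$coef["m1:arm"] * Z[test, "m1"]
    expect_equal(sign(tab$pai_signed[test]), sign(-delta),
                 ignore_attr = TRUE)
  }
  # factual prediction corresponds to the arm actually received
  expect_equal(tab$factual,
               ifelse(tab$arm == "IPT", tab$pred_ipt, tab$pred_ct))
  # indicated arm follows the documented sign convention
  expect_true(all(tab$indicated[tab$pai_signed < 0] == "CT"))
  expect_true(all(tab$indicated[tab$pai_signed > 0] == "IPT"))
})

test_that("PAI is antisymmetric under an arm-label swap", {
  set.seed(9)
  n <- 80
  Z <- cbind(m1 = rnorm(n), p1 = rnorm(n))
  a <- rep(0:1, n / 2)
  y <- 1 + 0.5 * a + Z[, "p1"] + 1.2 * Z[, "m1"] * (a - 0.5) + rnorm(n)
  folds <- rep_len(1:4, n)
  t1 <- crossval_predict(y, a, Z, "p1", "m1", folds = folds)
  t2 <- crossval_predict(y, 1 - a, Z, "p1", "m1", folds = folds)
  expect_equal(t1$pred_ct, t2$pred_ipt, tolerance = 1e-10)
  expect_equal(t1$pai_signed, -t2$pai_signed, tolerance = 1e-10)
  swap <- c(CT = "IPT", IPT = "CT", none = "none")
  expect_equal(unname(swap[t1$indicated]), t2$indicated)
})

test_that("fold assignment varies with the seed but is seed-stable", {
  set.seed(10)
  n <- 60
  Z <- cbind(m1 = rnorm(n))
  a <- rep(0:1, n / 2)
  y <- rnorm(n)
  ta <- crossval_predict(y, a, Z, moderators = "m1", seed = 11)
  tb <- crossval_predict(y, a, Z, moderators = "m1", seed = 11)
  tc <- crossval_predict(y, a, Z, moderators = "m1", seed = 12)
  expect_identical(ta, tb)
  expect_false(identical(ta$fold, tc$fold))
})

test_that("Johnson-Neyman matches closed forms and a dense grid", {
  set.seed(12)
  n <- 300
  Z <- cbind(m1 = rnorm(n))
  a <- rep(0:1, n / 2)
  # strong arm effect, null interaction: whole range significant
  y1 <- 3 * a + rnorm(n, 0, 0.5)
  m1 <- fit_final_model(y1, a, Z, moderators = "m1")
  jn1 <- johnson_neyman(m1, "m1")
  expect_equal(nrow(jn1$regions), 1)
  expect_equal(unname(unlist(jn1$regions[, c("lower", "upper")])),
               unname(m1$moderator_range[, "m1"]), tolerance = 1e-9)
  # delta = +3 here: outcomes are higher (worse) under IPT, so CT is favored
  expect_equal(unique(jn1$regions$favored), "CT")
  expect_gt(jn1$delta[["intercept"]], 0)

  # interaction only: boundaries from the quadratic match the grid search
  y2 <- 2 * Z[, "m1"] * a + rnorm(n)
  m2 <- fit_final_model(y2, a, Z, moderators = "m1")
  jn2 <- johnson_neyman(m2, "m1")
  rng <- m2$moderator_range[, "m1"]
  grid <- seq(rng[1], rng[2], length.out = 1e4)
  tc2 <- qt(0.975, m2$df_residual)
  u <- as.numeric(names(m2$coef) == "arm")
  v <- as.numeric(names(m2$coef) == "m1:arm")
  dl <- m2$coef["arm"] + m2$coef["m1:arm"] * grid
  se <- sqrt(drop(t(u) %*% m2$vcov %*% u) +
               2 * grid * drop(t(u) %*% m2$vcov %*% v) +
               grid^2 * drop(t(v) %*% m2$vcov %*% v))
  sig <- abs(dl) > tc2 * se
  # boundaries agree with the grid to grid resolution
  step <- diff(grid[1:2])
  for (b in jn2$boundaries) {
    j <- which.min(abs(grid - b))
    expect_true(any(sig[max(1, j - 2):min(1e4, j + 2)]) &&
                  !all(sig[max(1, j - 2):min(1e4, j + 2)]))
  }
  # significant region matches the grid classification away from boundaries
  inside <- vapply(grid, function(g)
    any(jn2$regions$lower <= g & g <= jn2$regions$upper), TRUE)
  away <- vapply(grid, function(g)
    all(abs(g - jn2$boundaries) > 2 * step), TRUE)
  expect_equal(inside[away], sig[away])
})
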