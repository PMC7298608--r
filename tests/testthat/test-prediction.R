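test_that("E-BLUP equals a brute-force universal kriging solution", {
  set.seed(40)
  n <- 5
  co <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  st <- as_obs_stack(tibble::tibble(
    var = 1L, site_id = sprintf("s%d", 1:n),
    x_km = co[, 1], y_km = co[, 2], value = rnorm(n), z = runif(n)
  ))
  f <- fit_lmm(st,
    fixed = "z", method = "ML", kappa = 0.5, starts = 1,
    maxit = 80, polish = FALSE
  )
  cg <- f$coreg
  tgt <- tibble::tibble(x_km = 4.2, y_km = 5.1, z = 0.7)
  pr <- eblup_predict(f, tgt, hull_warn = FALSE)
  # independent assembly of the universal kriging equations
  V <- cg$S[1, 1] * matern_corr(as.matrix(dist(co)), cg$kappa, cg$phi) +
    cg$T[1, 1] * diag(n)
  X <- cbind(1, st$z)
  x0 <- c(1, 0.7)
  d <- sqrt((co[, 1] - 4.2)^2 + (co[, 2] - 5.1)^2)
  cc <- cg$S[1, 1] * matern_corr(d, cg$kappa, cg$phi)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% st$value)
  pred_bf <- drop(x0 %*% beta + t(cc) %*% Vi %*% (st$value - X %*% beta))
  dd <- x0 - drop(t(X) %*% Vi %*% cc)
  pev_bf <- cg$T[1, 1] + cg$S[1, 1] - drop(t(cc) %*% Vi %*% cc) +
    drop(t(dd) %*% solve(XtVX) %*% dd)
  expect_equal(pr$eblup_log, pred_bf, tolerance = 1e-8)
  expect_equal(pr$pev_log, pev_bf, tolerance = 1e-8)
})

test_that("zero-nugget E-BLUP interpolates observed data exactly", {
  set.seed(41)
  n <- 8
  co <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  st <- as_obs_stack(tibble::tibble(
    var = 1L, site_id = sprintf("s%d", 1:n),
    x_km = co[, 1], y_km = co[, 2], value = rnorm(n)
  ))
  f <- fit_lmm(st, method = "ML", starts = 1, maxit = 5, polish = FALSE)
  f$coreg <- coregionalization(matrix(0), matrix(1.4), 1.5, 6)
  V <- build_joint_cov(st, f$coreg)
  f$beta$estimate <- grainse:::gls_loglik(st$value, f$X, V)$beta
  pr <- eblup_predict(f, tibble::tibble(x_km = co[3, 1], y_km = co[3, 2]),
    hull_warn = FALSE
  )
  expect_equal(pr$eblup_log, st$value[3], tolerance = 1e-8)
  expect_equal(pr$pev_log, 0, tolerance = 1e-8)
})

test_that("E-BLUP is invariant to a constant shift of a covariate column", {
  set.seed(42)
  n <- 40
  st <- make_stack1(n, seed = 42)
  st$z <- rnorm(n)
  st$value <- 1 + 0.5 * st$z + st$value
  f <- fit_lmm(st, fixed = "z", method = "ML", starts = 2, maxit = 300)
  tgt <- tibble::tibble(x_km = c(10, 30), y_km = c(20, 15), z = c(0.3, -1))
  p1 <- eblup_predict(f, tgt, hull_warn = FALSE)
  # shift the covariate by a constant and compensate the intercept
  st2 <- st
  st2$z <- st$z + 5
  f2 <- f
  f2$stack <- st2
  f2$X <- grainse:::build_design(st2, "z")
  i_int <- match("y1:(Intercept)", f2$beta$term)
  i_z <- match("y1:z", f2$beta$term)
  f2$beta$estimate[i_int] <- f$beta$estimate[i_int] - 5 * f$beta$estimate[i_z]
  tgt2 <- tgt
  tgt2$z <- tgt$z + 5
  p2 <- eblup_predict(f2, tgt2, hull_warn = FALSE)
  expect_equal(p1$eblup_log, p2$eblup_log, tolerance = 1e-8)
  expect_equal(p1$pev_log, p2$pev_log, tolerance = 1e-8)
})

test_that("with S = 0 and no shared nugget the E-BLUP is the GLS mean", {
  set.seed(43)
  n <- 20
  st <- make_stack1(n, seed = 43)
  f <- fit_lmm(st, method = "ML", starts = 1, maxit = 5, polish = FALSE)
  f$coreg <- coregionalization(matrix(1.2), matrix(0), 1, 10)
  V <- build_joint_cov(st, f$coreg)
  f$beta$estimate <- grainse:::gls_loglik(st$value, f$X, V)$beta
  tgt <- tibble::tibble(x_km = 5.5, y_km = 7.7) # not a data site
  pr <- eblup_predict(f, tgt, hull_warn = FALSE)
  expect_equal(pr$eblup_log, f$beta$estimate[1], tolerance = 1e-10)
})

test_that("ordinary kriging matches the brute-force system and its constraint", {
  set.seed(44)
  n <- 5
  co <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  v <- rnorm(n)
  tgt <- cbind(c(4, 8), c(4, 2))
  pr <- ok_predict(v, co, 0.3, 0.7, 0.5, 5, tgt)
  K <- 0.7 * matern_corr(as.matrix(dist(co)), 0.5, 5) + 0.3 * diag(n)
  A <- rbind(cbind(K, 1), c(rep(1, n), 0))
  for (j in 1:2) {
    d <- sqrt((co[, 1] - tgt[j, 1])^2 + (co[, 2] - tgt[j, 2])^2)
    b <- c(0.7 * matern_corr(d, 0.5, 5), 1)
    sol <- solve(A, b)
    expect_equal(pr$eblup_log[j], sum(sol[1:n] * v), tolerance = 1e-8)
    expect_equal(pr$pev_log[j], 1 - sum(sol[1:n] * b[1:n]) - sol[n + 1],
      tolerance = 1e-8
    )
  }
  # weights sum to one at every target
  w <- attr(pr, "weights")
  expect_equal(colSums(w), c(1, 1), tolerance = 1e-10)
  # constant data reproduce the constant
  pc <- ok_predict(rep(2.2, n), co, 0.3, 0.7, 0.5, 5, tgt)
  expect_equal(pc$eblup_log, c(2.2, 2.2), tolerance = 1e-8)
  expect_true(all(pc$pev_log >= 0))
})

test_that("secondary variables never hurt: cokriging PEV <= univariate PEV", {
  set.seed(45)
  cg <- default_survey_coreg(trivariate = TRUE)
  st3 <- make_stack3(60, cg, seed = 46, frame = 60)
  f3 <- fit_lmm(st3, method = "ML", kappa = 2, starts = 1, maxit = 5,
    polish = FALSE)
  f3$coreg <- cg # identical parameters in both predictors
  V <- build_joint_cov(st3, cg)
  f3$beta$estimate <- grainse:::gls_loglik(st3$value, f3$X, V)$beta
  st1 <- st3[st3$var == 1L, ]
  f1 <- fit_lmm(st1, method = "ML", kappa = 2, starts = 1, maxit = 5,
    polish = FALSE)
  f1$coreg <- coregionalization(
    matrix(cg$T[1, 1]), matrix(cg$S[1, 1]), cg$kappa, cg$phi
  )
  V1 <- build_joint_cov(st1, f1$coreg)
  f1$beta$estimate <- grainse:::gls_loglik(st1$value, f1$X, V1)$beta
  tgt <- tibble::tibble(
    x_km = runif(50, 0, 60), y_km = runif(50, 0, 60)
  )
  pev3 <- eblup_predict(f3, tgt, hull_warn = FALSE)$pev_log
  pev1 <- eblup_predict(f1, tgt, hull_warn = FALSE)$pev_log
  expect_true(all(pev3 <= pev1 + 1e-8))
  expect_lt(mean(pev3), mean(pev1))
})

test_that("back-transform is the exponential and preserves order", {
  expect_equal(back_transform_median(0), 1)
  expect_equal(back_transform_median(log(0.183)), 0.183)
  x <- sort(rnorm(20))
  expect_true(all(diff(back_transform_median(x)) > 0))
})

test_that("missing target covariates raise a named error", {
  st <- make_stack1(20, seed = 47)
  st$z <- rnorm(20)
  f <- fit_lmm(st, fixed = "z", method = "ML", starts = 1, maxit = 50,
    polish = FALSE)
  expect_error(
    eblup_predict(f, tibble::tibble(x_km = 1, y_km = 1)),
    "z"
  )
})
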