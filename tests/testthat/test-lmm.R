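test_that("stack validation catches malformed inputs", {
  expect_error(as_obs_stack(tibble::tibble(var = 1, value = 1)), "columns")
  bad <- tibble::tibble(
    var = c(1L, 1L), site_id = "a", x_km = 0, y_km = 0, value = 1:2
  )
  expect_error(as_obs_stack(bad), "at most once")
})

test_that("iid likelihood matches the closed-form Gaussian log-likelihood", {
  st <- make_stack1(40, seed = 1, value_fun = function(co) rnorm(40, 2, 1.5))
  s2 <- 1.7
  cg <- coregionalization(matrix(s2), matrix(0), 0.5, 10)
  n <- 40
  rss <- sum((st$value - mean(st$value))^2)
  ll_oracle <- -0.5 * (n * log(2 * pi) + n * log(s2) + rss / s2)
  expect_equal(-negloglik(cg, st, method = "ML"), ll_oracle, tolerance = 1e-8)
})

test_that("REML and ML differ by the restricted determinant term", {
  st <- make_stack1(10, seed = 2)
  st$z <- runif(10)
  cg <- coregionalization(matrix(0.8), matrix(1.2), 1.5, 6)
  V <- build_joint_cov(st, cg)
  X <- cbind(1, st$z)
  gap <- (-negloglik(cg, st, fixed = "z", method = "REML")) -
    (-negloglik(cg, st, fixed = "z", method = "ML"))
  expect_equal(
    gap,
    -0.5 * determinant(t(X) %*% solve(V, X))$modulus[[1]] +
      0.5 * ncol(X) * log(2 * pi),
    tolerance = 1e-8
  )
})

test_that("GLS coefficients are scale-invariant and match brute-force WLS", {
  st <- make_stack1(12, seed = 3)
  st$z <- rnorm(12)
  cg <- coregionalization(matrix(0.5), matrix(0.9), 1, 8)
  V <- build_joint_cov(st, cg)
  X <- grainse:::build_design(st, "z")
  g1 <- grainse:::gls_loglik(st$value, X, V)
  # brute force WLS with weight matrix V^-1
  beta_bf <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, st$value))
  expect_equal(g1$beta, drop(beta_bf),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  # scaling T and S by c leaves beta-hat unchanged
  g2 <- grainse:::gls_loglik(st$value, X, 3.7 * V)
  expect_equal(g1$beta, g2$beta, tolerance = 1e-10)
})

test_that("likelihood is invariant to row order of the stack", {
  st <- make_stack3(20, default_survey_coreg(trivariate = TRUE), seed = 4)
  cg <- default_survey_coreg(trivariate = TRUE)
  set.seed(5)
  perm <- sample(nrow(st))
  expect_equal(
    negloglik(cg, st),
    negloglik(cg, st[perm, ]),
    tolerance = 1e-10
  )
})

test_that("likelihood-ratio test follows the chi-square calibration", {
  st <- make_stack1(30, seed = 6)
  st$z <- rnorm(30)
  f0 <- fit_lmm(st, method = "ML", starts = 1, maxit = 200, polish = FALSE)
  f1 <- fit_lmm(st,
    fixed = "z", method = "ML", starts = 1, maxit = 200,
    polish = FALSE
  )
  out <- lr_test(f0, f1)
  expect_equal(out$df, 1)
  expect_equal(out$p_value, pchisq(out$statistic, 1, lower.tail = FALSE))
  # chi-square anchor: D = 3.841 on 1 df is p = 0.05
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  # equal likelihoods give p = 1; tiny negative D clamps with a warning
  f1b <- f1
  f1b$logLik <- f0$logLik
  expect_equal(lr_test(f0, f1b)$p_value, 1)
  f1c <- f1
  f1c$logLik <- f0$logLik - 1e-9
  expect_warning(out_c <- lr_test(f0, f1c), "clamped")
  expect_equal(out_c$p_value, 1)
  # contract errors: REML fits and non-nested specs are rejected
  fr <- fit_lmm(st, method = "REML", starts = 1, maxit = 50, polish = FALSE)
  expect_error(lr_test(fr, f1), "ML")
  expect_error(lr_test(f1, f1), "nested")
})

test_that("single-variable parameter recovery at moderate size", {
  # truth: tau2 = 0.5, sigma2 = 0.5, phi = 15
  truth <- coregionalization(matrix(0.5), matrix(0.5), 0.5, 15)
  ests <- purrr::map_dfr(1:6, function(r) {
    set.seed(400 + r)
    n <- 150
    co <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    z <- drop(simulate_fields(co, truth, seed = 500 + r))
    st <- as_obs_stack(tibble::tibble(
      var = 1L, site_id = sprintf("s%03d", 1:n),
      x_km = co[, 1], y_km = co[, 2], value = z
    ))
    f <- fit_lmm(st, method = "ML", kappa = 0.5, starts = 2, maxit = 500)
    tibble::tibble(
      tau2 = f$coreg$T[1, 1], sigma2 = f$coreg$S[1, 1], phi = f$coreg$phi
    )
  })
  # median estimates are in the right neighbourhood
  expect_lt(abs(median(ests$tau2) / 0.5 - 1), 0.5)
  expect_lt(abs(median(ests$sigma2) / 0.5 - 1), 0.5)
  expect_gt(median(ests$phi), 15 / 2.5)
  expect_lt(median(ests$phi), 15 * 2.5)
})

test_that("kappa profiling returns the grid optimum and full table", {
  st <- make_stack1(25, seed = 8)
  pr <- profile_kappa(st,
    kappa_grid = 2.0, starts = 1, maxit = 50,
    polish = FALSE
  )
  expect_equal(pr$best_kappa, 2.0)
  pr2 <- profile_kappa(st,
    kappa_grid = c(0.5, 2), starts = 1, maxit = 50,
    polish = FALSE
  )
  expect_equal(nrow(pr2$profile), 2)
  expect_true(pr2$best_kappa %in% c(0.5, 2))
  expect_equal(
    pr2$best_kappa,
    pr2$profile$kappa[which.max(pr2$profile$logLik)]
  )
})

test_that("adjusted R-squared honours its conventions", {
  st <- make_stack1(50, seed = 9)
  f0 <- fit_lmm(st, method = "ML", starts = 1, maxit = 50, polish = FALSE)
  expect_identical(adjusted_r2(f0), 0) # constant-only convention
  # perfect linear fit: noiseless response
  st2 <- make_stack1(50, seed = 10)
  st2$z <- rnorm(50)
  st2$value <- 2 + 3 * st2$z
  f2 <- fit_lmm(st2, fixed = "z", method = "ML", starts = 1, maxit = 200)
  expect_gt(adjusted_r2(f2), 0.999)
  # an orthogonal pure-noise predictor barely moves it
  set.seed(11)
  st3 <- make_stack1(120, seed = 12)
  st3$z <- rnorm(120)
  st3$junk <- rnorm(120)
  st3$value <- st3$value + st3$z
  f3a <- fit_lmm(st3, fixed = "z", method = "ML", starts = 1, maxit = 300)
  f3b <- fit_lmm(st3,
    fixed = c("z", "junk"), method = "ML", starts = 1,
    maxit = 300
  )
  expect_lt(adjusted_r2(f3b) - adjusted_r2(f3a), 0.01)
})

test_that("tidy and glance expose the fit in broom style", {
  st <- make_stack1(30, seed = 13)
  st$z <- rnorm(30)
  f <- fit_lmm(st, fixed = "z", method = "ML", starts = 1, maxit = 100)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std_error", "statistic") %in% names(td)))
  expect_equal(nrow(td), 2)
  gl <- glance(f)
  expect_equal(gl$method, "ML")
  expect_true(is.finite(gl$logLik))
  expect_true(all(td$std_error >= 0))
})
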