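test_that("Matern correlation matches closed forms and is monotone", {
  expect_identical(matern_corr(0, 2, 10), 1)
  # half-integer smoothness agrees with the Bessel-function expression
  h <- seq(0.1, 40, by = 0.7)
  bessel_form <- function(h, k, phi) {
    u <- h / phi
    2^(1 - k) / gamma(k) * u^k * besselK(u, k)
  }
  for (k in c(0.5, 1.5, 2.5)) {
    expect_equal(matern_corr(h, k, 8), bessel_form(h, k, 8),
      tolerance = 1e-12, label = paste("kappa =", k)
    )
  }
  # kappa = 1/2 is the exponential model
  expect_equal(matern_corr(15, 0.5, 15), exp(-1), tolerance = 1e-12)
  # kappa = 3/2 closed form (1 + h/phi) exp(-h/phi)
  expect_equal(matern_corr(15, 1.5, 15), 2 * exp(-1), tolerance = 1e-12)
  # monotone decreasing on a grid, for several smoothness values
  for (k in c(0.25, 0.5, 1, 2, 5)) {
    r <- matern_corr(seq(0, 60, by = 0.5), k, 12)
    expect_true(all(diff(r) < 0), info = paste("kappa =", k))
    expect_true(all(r > 0 & r <= 1))
  }
})

test_that("the spline fast-path evaluator matches the Bessel form", {
  for (k in c(0.25, 1, 2, 3)) {
    f <- grainse:::matern_evaluator(k)
    u <- exp(seq(log(1e-7), log(59), length.out = 2000))
    expect_lt(max(abs(f(u) - matern_corr(u, k, 1))), 1e-6,
      label = paste("kappa =", k)
    )
    expect_identical(f(0), 1)
  }
})

test_that("large-kappa Matern approaches the Gaussian correlation shape", {
  # compare at matched effective range (correlation 0.5), kappa = 50
  phi <- 1
  h <- seq(0.01, 3, by = 0.01) * sqrt(2 * 50) * phi
  r_mat <- matern_corr(h, 50, phi)
  h_half <- h[which.min(abs(r_mat - 0.5))]
  r_gauss <- exp(-log(2) * (h / h_half)^2)
  expect_lt(max(abs(r_mat - r_gauss)), 0.03)
})

test_that("coregionalization validation enforces PSD and structural zeros", {
  expect_error(
    coregionalization(matrix(c(1, 2, 2, 1), 2), diag(2), 1, 10),
    "positive semi-definite"
  )
  expect_error(
    coregionalization(diag(c(1, -0.1)), diag(2), 1, 10),
    "negative variance"
  )
  expect_error(
    coregionalization(matrix(c(1, 0.5, 0.5, 1), 2), diag(2), 1, 10,
      nugget_zero = cbind(1, 2)
    ),
    "structurally zero"
  )
  cg <- coregionalization(diag(2), diag(2), 1, 10, nugget_zero = cbind(1, 2))
  expect_s3_class(cg, "se_coreg")
})

test_that("joint covariance entries follow the coregionalization formula", {
  # one variable, two far-apart sites, no spatial component: tau^2 I
  rows <- tibble::tibble(
    var = 1L, site_id = c("a", "b"), x_km = c(0, 1e5), y_km = 0
  )
  cg <- coregionalization(matrix(2.5), matrix(0), 1, 10)
  expect_equal(build_joint_cov(rows, cg), 2.5 * diag(2))

  # two variables at one site: off-diagonal = T12 + S12 (rho(0) = 1)
  rows2 <- tibble::tibble(
    var = c(1L, 2L), site_id = "a", x_km = 0, y_km = 0
  )
  s1 <- sqrt(0.39)
  s2 <- sqrt(0.25)
  S <- outer(c(s1, s2), c(s1, s2)) * matrix(c(1, 0.52, 0.52, 1), 2)
  cg2 <- coregionalization(diag(c(0.62, 0.21)), S, 2, 15)
  V2 <- build_joint_cov(rows2, cg2)
  expect_equal(V2[1, 2], 0.52 * s1 * s2, tolerance = 1e-12)
  expect_equal(diag(V2), c(0.62 + 0.39, 0.21 + 0.25))

  # random valid coregionalizations stay PSD over random layouts
  set.seed(7)
  for (r in 1:5) {
    p <- sample(2:3, 1)
    A <- matrix(rnorm(p * p), p)
    B <- matrix(rnorm(p * p), p)
    cg3 <- coregionalization(crossprod(A), crossprod(B), runif(1, 0.3, 3),
      runif(1, 2, 30)
    )
    rows3 <- tibble::tibble(
      var = sample(1:p, 50, replace = TRUE),
      site_id = sprintf("s%02d", sample(1:25, 50, replace = TRUE))
    )
    rows3 <- rows3[!duplicated(rows3), ]
    xy <- matrix(runif(50, 0, 50), 25)
    sidx <- as.integer(sub("s", "", rows3$site_id))
    rows3$x_km <- xy[sidx, 1]
    rows3$y_km <- xy[sidx, 2]
    V <- build_joint_cov(rows3, cg3)
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("single-variable zero-nugget covariance is sigma2 times correlation", {
  set.seed(9)
  n <- 20
  rows <- tibble::tibble(
    var = 1L, site_id = sprintf("s%02d", 1:n),
    x_km = runif(n, 0, 30), y_km = runif(n, 0, 30)
  )
  cg <- coregionalization(matrix(0), matrix(1.3), 1.5, 7)
  V <- build_joint_cov(rows, cg)
  R <- matern_corr(as.matrix(dist(cbind(rows$x_km, rows$y_km))), 1.5, 7)
  expect_equal(V, 1.3 * R, tolerance = 1e-12)
})

test_that("teff-wheat nugget covariance is structurally zero when masked", {
  cg <- default_survey_coreg(trivariate = TRUE)
  expect_identical(cg$T[1, 2], 0)
  rows <- tibble::tibble(
    var = c(1L, 2L, 3L), site_id = c("a", "b", "a"),
    x_km = c(0, 0, 0), y_km = c(0, 0, 0)
  )
  V <- build_joint_cov(rows, cg)
  # vars 1 and 2 share coordinates but not a site: only S contributes
  expect_equal(V[1, 2], cg$S[1, 2], tolerance = 1e-12)
})

test_that("empirical variogram reproduces hand calculations", {
  # two points, values 0 and 2: semivariance 2 in the containing bin
  ev <- empirical_variogram(c(0, 2), cbind(c(0, 3), c(0, 0)),
    bin_edges = c(0, 2, 4)
  )
  expect_equal(ev$gamma[2], 2)
  expect_equal(ev$npairs, c(0L, 1L))
  expect_true(is.na(ev$gamma[1])) # empty bin reported, not dropped

  # constant field: zero in every populated bin
  set.seed(2)
  co <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  ev2 <- empirical_variogram(rep(3.3, 40), co)
  expect_true(all(ev2$gamma[ev2$npairs > 0] == 0))

  # white noise with unit variance: plateau near 1
  set.seed(3)
  co3 <- cbind(runif(800, 0, 100), runif(800, 0, 100))
  ev3 <- empirical_variogram(rnorm(800), co3)
  big <- ev3$npairs > 2000
  expect_true(all(abs(ev3$gamma[big] - 1) < 0.15))
})
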