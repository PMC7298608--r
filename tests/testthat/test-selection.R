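test_that("alpha-investing wealth accounting follows the adopted rule", {
  # all p = 1: no rejections, wealth strictly decreasing, never negative
  led <- alpha_investing(letters[1:8], rep(1, 8))
  expect_true(all(led$decision == "accept"))
  expect_true(all(diff(c(0.05, led$wealth)) < 0))
  expect_true(all(led$wealth >= 0))
  expect_true(all(led$alpha > 0))
  # explicit update arithmetic: alpha_1 = W0/2, spend alpha/(1-alpha)
  expect_equal(led$alpha[1], 0.05 / 2)
  expect_equal(led$wealth[1], 0.05 - (0.025 / 0.975))

  # an early rejection earns the payout
  led2 <- alpha_investing(letters[1:3], c(1e-9, 1, 1))
  expect_equal(led2$decision[1], "reject")
  expect_equal(led2$wealth[1], 0.05 - 0.025 / 0.975 + 0.05)
  expect_gt(led2$wealth[1], 0.05 - led2$alpha[1])
  # after a rejection the clock resets: alpha_2 = W(1)/2 again
  expect_equal(led2$alpha[2], led2$wealth[1] / 2)

  expect_error(alpha_investing("a", 1.5), "outside")
  expect_error(alpha_investing("a", -0.1), "outside")
})

test_that("rejections are monotone in the p-values", {
  set.seed(20)
  for (r in 1:20) {
    p <- runif(9)
    led <- alpha_investing(letters[1:9], p)
    j <- sample(nrow(led), 1)
    p2 <- p
    p2[j] <- p[j] * runif(1) # lower one p-value
    led2 <- alpha_investing(letters[1:9], p2)
    rej1 <- led$label[led$decision == "reject"]
    rej2 <- led2$label[led2$decision == "reject"]
    # a rejection at or before position j can only be gained, not lost
    expect_true(all(setdiff(rej1, rej2) == character(0)) ||
      all(match(setdiff(rej1, rej2), letters) > j))
  }
})

test_that("marginal FDR is controlled under the global null", {
  # independent uniform p-values (all hypotheses truly null)
  set.seed(21)
  nrep <- 4000
  rejections <- vapply(seq_len(nrep), function(r) {
    led <- alpha_investing(paste0("h", 1:11), runif(11))
    sum(led$decision == "reject")
  }, 0)
  mfdr <- mean(rejections) / (mean(rejections) + 1)
  expect_lte(mfdr, 0.05)

  # permuting the testing order preserves control under the null
  set.seed(22)
  rej_perm <- vapply(seq_len(nrep), function(r) {
    led <- alpha_investing(sample(paste0("h", 1:11)), runif(11))
    sum(led$decision == "reject")
  }, 0)
  expect_lte(mean(rej_perm) / (mean(rej_perm) + 1), 0.05)
})

test_that("sequential model selection finds strong true predictors", {
  # true soil model uses predictors ranked 1, 2 and 4 with strong effects
  hits <- vapply(1:8, function(r) {
    set.seed(700 + r)
    n <- 120
    st <- make_stack1(n, seed = 700 + r)
    Xp <- matrix(rnorm(n * 5), n)
    colnames(Xp) <- paste0("p", 1:5)
    st <- dplyr::bind_cols(st, tibble::as_tibble(Xp))
    st$value <- 1 + 0.8 * Xp[, 1] - 0.7 * Xp[, 2] + 0.6 * Xp[, 4] + rnorm(n, 0, 0.8)
    sel <- select_predictors(as_obs_stack(st), paste0("p", 1:5),
      refit_each = FALSE, final_fit = FALSE, starts = 1, maxit = 150
    )
    all(c("p1", "p2", "p4") %in% sel$selected)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("selection on pure-noise predictors rarely selects anything", {
  n_sel <- vapply(1:12, function(r) {
    set.seed(800 + r)
    n <- 80
    st <- make_stack1(n, seed = 800 + r)
    Xp <- matrix(rnorm(n * 6), n)
    colnames(Xp) <- paste0("p", 1:6)
    st <- dplyr::bind_cols(st, tibble::as_tibble(Xp))
    sel <- select_predictors(as_obs_stack(st), paste0("p", 1:6),
      refit_each = FALSE, final_fit = FALSE, starts = 1, maxit = 150
    )
    length(sel$selected)
  }, 0)
  expect_lte(mean(n_sel > 0), 0.25)
  # ledger thresholds stay strictly positive until the stop
  set.seed(23)
  st <- make_stack1(60, seed = 24)
  st$p1 <- rnorm(60)
  sel <- select_predictors(as_obs_stack(st), "p1",
    refit_each = FALSE,
    final_fit = FALSE, starts = 1, maxit = 100
  )
  expect_true(all(sel$ledger$alpha > 0))
})

test_that("an empty candidate sequence returns the null model", {
  st <- make_stack1(30, seed = 25)
  sel <- select_predictors(st, character(0), starts = 1, maxit = 50)
  expect_identical(sel$selected, character(0))
  expect_equal(nrow(sel$ledger), 0)
  expect_s3_class(sel$fit, "se_lmm")
  expect_equal(nrow(sel$fit$beta), 1)
})

test_that("soil-based prediction is a deterministic fixed-effect map", {
  set.seed(26)
  n <- 60
  st <- make_stack1(n, seed = 26)
  st$a <- rnorm(n)
  st$b <- rnorm(n)
  st$value <- 2 + st$a - 0.5 * st$b + rnorm(n, 0, 0.3)
  f <- fit_lmm(st, fixed = c("a", "b"), method = "ML", starts = 1, maxit = 300)
  d <- tibble::tibble(a = c(1, 1, 0), b = c(0, 0, 2))
  y3 <- predict_from_soil(f, d)
  b <- f$beta$estimate
  expect_equal(y3[1], b[1] + b[2], tolerance = 1e-10)
  expect_equal(y3[1], y3[2]) # identical soil values, identical prediction
  expect_error(predict_from_soil(f, tibble::tibble(a = 1)), "missing")
  # constant-only model predicts the intercept everywhere
  f0 <- fit_lmm(st, method = "ML", starts = 1, maxit = 50, polish = FALSE)
  expect_equal(
    predict_from_soil(f0, d),
    rep(f0$beta$estimate[1], 3)
  )
})

test_that("soil prediction correlates with the true signal in a survey", {
  sv <- assemble_survey(survey_config(
    frame_km = c(120, 100), n_primary = 200, n_close_pairs = 10,
    grid_cell_km = 10, seed = 9
  ))
  tr <- apply_transform_rule(sv$sites)
  st <- stack_from_survey(tr, "teff", carry = soil_property_names())
  st1 <- st[st$var == 1L, ]
  sel <- select_predictors(st1, soil_property_names(),
    refit_each = FALSE,
    starts = 1, maxit = 200
  )
  y3 <- predict_from_soil(sel$fit, tr)
  # compare with the true deterministic part of the teff linear predictor
  truth_lp <- sv$truth$linear_predictor - rowSums(sv$truth$crop_effects) *
    0 # crop effects are not part of the soil signal
  co <- default_soil_coef()$teff
  sig <- rep(co[["(Intercept)"]], nrow(tr))
  for (nm in setdiff(names(co), "(Intercept)")) sig <- sig + co[[nm]] * tr[[nm]]
  expect_gt(cor(y3, sig), 0.7)
})
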