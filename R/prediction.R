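#' E-BLUP cokriging prediction with prediction error variances
#'
#' Empirical best linear unbiased prediction of the target variable
#' (variable 1, log scale) at arbitrary target locations from a fitted
#' multivariate spatial model:
#' \deqn{\hat Z(x_0) = x_0'\hat\beta + c' V^{-1} (y - X\hat\beta),}
#' with the full universal-kriging prediction error variance
#' \deqn{PEV = \sigma_{00} - c'V^{-1}c + d'(X'V^{-1}X)^{-1}d,\quad
#'   d = x_0 - X'V^{-1}c,}
#' which includes the fixed-effect estimation term.  Observations of the
#' secondary variables (the other grain, the soil-predicted grain)
#' contribute through their cross-covariances (cokriging).  A target
#' co-located with a data site shares that site's nugget.
#'
#' @param fit An `se_lmm` (variable 1 = target).
#' @param targets Tibble/data frame with `x_km`, `y_km` and every
#'   covariate column used by variable 1's fixed effects.
#' @param hull_warn Warn for targets further than one distance parameter
#'   phi outside the data bounding box?
#' @return Tibble of class `se_prediction`: x_km, y_km, eblup_log,
#'   pev_log, median_mg_kg (`exp(eblup_log)`, the median-unbiased
#'   back-transform under log-normal errors).
#' @export
eblup_predict <- function(fit, targets, hull_warn = TRUE) {
  stopifnot(inherits(fit, "se_lmm"))
  stack <- fit$stack
  fx1 <- fit$fixed[["1"]]
  miss <- setdiff(fx1, names(targets))
  if (length(miss) > 0) {
    abort(paste("targets are missing covariate columns:", paste(miss, collapse = ", ")))
  }
  if (hull_warn) {
    pad <- fit$coreg$phi
    out_hull <- targets$x_km < min(stack$x_km) - pad |
      targets$x_km > max(stack$x_km) + pad |
      targets$y_km < min(stack$y_km) - pad |
      targets$y_km > max(stack$y_km) + pad
    if (any(out_hull)) {
      warn(paste(sum(out_hull), "target(s) lie far outside the data hull"))
    }
  }
  cg <- fit$coreg
  V <- build_joint_cov(stack, cg)
  U <- chol_jitter(V)
  X <- fit$X
  y <- stack$value
  beta <- fit$beta$estimate
  r <- y - drop(X %*% beta)
  a <- backsolve(U, backsolve(U, r, transpose = TRUE)) # V^-1 r
  wX <- backsolve(U, X, transpose = TRUE)
  cov_beta <- chol2inv(chol(crossprod(wX)))

  # cross-covariance of target (variable 1) with every stack row
  Dt <- sqrt(
    outer(stack$x_km, targets$x_km, "-")^2 +
      outer(stack$y_km, targets$y_km, "-")^2
  )
  Cc <- cg$S[1, stack$var] * matern_corr(Dt, cg$kappa, cg$phi) +
    cg$T[1, stack$var] * (Dt < 1e-9)

  # target design row: intercept + variable-1 covariates
  m <- nrow(targets)
  X0 <- matrix(0, m, ncol(X))
  X0[, match("y1:(Intercept)", colnames(X))] <- 1
  for (cn in fx1) {
    X0[, match(paste0("y1:", cn), colnames(X))] <- targets[[cn]]
  }

  pred <- drop(X0 %*% beta) + drop(crossprod(Cc, a))
  Wc <- backsolve(U, Cc, transpose = TRUE)
  dmat <- X0 - t(crossprod(wX, Wc)) # m x p : x0 - X'V^-1 c
  pev <- pmax(
    cg$T[1, 1] + cg$S[1, 1] - colSums(Wc^2) +
      rowSums((dmat %*% cov_beta) * dmat),
    0
  )
  out <- tibble(
    x_km = targets$x_km, y_km = targets$y_km,
    eblup_log = pred, pev_log = pev,
    median_mg_kg = exp(pred)
  )
  class(out) <- unique(c("se_prediction", class(out)))
  out
}

#' Ordinary kriging with a nugget + Matern model
#'
#' Single-variable ordinary kriging: the mean is implicit and estimated
#' through the unbiasedness (weights-sum-to-one) constraint.  Serves as
#' the comparison predictor for the multivariate E-BLUP.
#'
#' @param values,coords Data and coordinates (two columns, km).
#' @param tau2 Nugget variance.
#' @param sigma2 Spatially correlated variance.
#' @param kappa,phi Matern parameters.
#' @param targets Two-column matrix/data frame of target coordinates.
#' @return Tibble of class `se_prediction` (as [eblup_predict()]); the
#'   kriging weights are attached as attribute `weights` (n x m).
#' @export
ok_predict <- function(values, coords, tau2, sigma2, kappa, phi, targets) {
  coords <- as.matrix(coords)
  targets <- as.matrix(targets)
  n <- length(values)
  stopifnot(n >= 3, nrow(coords) == n)
  D <- as.matrix(dist(coords))
  K <- sigma2 * matern_corr(D, kappa, phi) + tau2 * diag(n)
  A <- rbind(cbind(K, 1), c(rep(1, n), 0))
  Dt <- sqrt(
    outer(coords[, 1], targets[, 1], "-")^2 +
      outer(coords[, 2], targets[, 2], "-")^2
  )
  c0 <- sigma2 * matern_corr(Dt, kappa, phi) + tau2 * (Dt < 1e-9)
  B <- rbind(c0, 1)
  sol <- tryCatch(solve(A, B), error = function(e) {
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-10
    solve(A, B)
  })
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  pred <- drop(crossprod(lambda, values))
  pev <- pmax(tau2 + sigma2 - colSums(lambda * c0) - mu, 0)
  out <- tibble(
    x_km = targets[, 1], y_km = targets[, 2],
    eblup_log = pred, pev_log = pev, median_mg_kg = exp(pred)
  )
  attr(out, "weights") <- lambda
  class(out) <- unique(c("se_prediction", class(out)))
  out
}

#' Median-unbiased back-transform of log-scale predictions
#'
#' Element-wise exponential: under log-normal prediction errors the
#' exponential of the log-scale predictor is the median-unbiased
#' prediction on the concentration scale.
#'
#' @param log_pred Log-scale predictions.
#' @return Concentrations (mg/kg).
#' @export
back_transform_median <- function(log_pred) {
  stopifnot(all(is.finite(log_pred)))
  exp(log_pred)
}
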