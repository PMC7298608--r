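#' Leave-one-out cross-validation with SSPE diagnostics
#'
#' For every target-variable site the grain observation (and, for the
#' E-BLUP, the co-located soil-predicted value) is deleted and the site is
#' re-predicted from the remaining data, with covariance and fixed-effect
#' parameters held fixed at their full-data estimates.  The standardized
#' squared prediction error \eqn{\theta = (z - \hat z)^2 / PEV} has mean
#' about 1 and median about 0.455 (the chi-square(1) median) when the
#' PEVs are valid.
#'
#' Deletion re-prediction uses the Gaussian conditional identity on the
#' precision matrix (equivalent to re-solving the kriging system without
#' the deleted rows, with beta fixed).
#'
#' @param fit An `se_lmm` fitted to the full stack.
#' @param predictor "EBLUP" (multivariate cokriging) or "OK" (ordinary
#'   kriging from the target variable only, with the variogram given by
#'   the fitted model's variable-1 marginal).
#' @param interval_nsim Monte Carlo size for the median-SSPE reference
#'   interval (see [median_sspe_interval()]); 0 skips it.
#' @param interval_seed Seed for that interval.
#' @return Tibble of class `se_crossval` (site_id, x_km, y_km, observed,
#'   predicted, pev, error, sspe) with a `summary` attribute; see
#'   `glance()`.
#' @export
loocv <- function(fit, predictor = c("EBLUP", "OK"), interval_nsim = 2000,
                  interval_seed = 1L) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(fit, "se_lmm"))
  stack <- fit$stack
  t_rows <- which(stack$var == 1L)
  if (length(t_rows) < 10) abort("need >= 10 target-variable sites")

  if (predictor == "EBLUP") {
    cg <- fit$coreg
    V <- build_joint_cov(stack, cg)
    Q <- chol2inv(chol_jitter(V))
    r <- stack$value - drop(fit$X %*% fit$beta$estimate)
    Qr <- drop(Q %*% r)
    res <- purrr::map_dfr(t_rows, function(i) {
      del <- which(stack$site_id == stack$site_id[i] & stack$var %in% c(1L, 3L))
      if (nrow(stack) - length(del) < 3) {
        return(tibble(
          site_id = stack$site_id[i], x_km = stack$x_km[i],
          y_km = stack$y_km[i], observed = stack$value[i],
          predicted = NA_real_, pev = NA_real_, error = NA_real_,
          sspe = NA_real_
        ))
      }
      pos <- match(i, del)
      Qaa_inv <- solve(Q[del, del, drop = FALSE])
      err <- drop(Qaa_inv %*% Qr[del])[pos]
      pev <- Qaa_inv[pos, pos]
      tibble(
        site_id = stack$site_id[i], x_km = stack$x_km[i],
        y_km = stack$y_km[i], observed = stack$value[i],
        predicted = stack$value[i] - err, pev = pev, error = err,
        sspe = err^2 / pev
      )
    })
  } else {
    sub <- stack[t_rows, ]
    cg <- fit$coreg
    res <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
      pr <- ok_predict(
        sub$value[-i], cbind(sub$x_km, sub$y_km)[-i, , drop = FALSE],
        tau2 = cg$T[1, 1], sigma2 = cg$S[1, 1],
        kappa = cg$kappa, phi = cg$phi,
        targets = cbind(sub$x_km[i], sub$y_km[i])
      )
      err <- sub$value[i] - pr$eblup_log
      tibble(
        site_id = sub$site_id[i], x_km = sub$x_km[i], y_km = sub$y_km[i],
        observed = sub$value[i], predicted = pr$eblup_log,
        pev = pr$pev_log, error = err, sspe = err^2 / pr$pev_log
      )
    })
  }

  valid <- is.finite(res$sspe) & res$pev > 0
  smry <- tibble(
    predictor = predictor,
    n = sum(valid),
    mean_sspe = mean(res$sspe[valid]),
    median_sspe = median(res$sspe[valid]),
    mean_pev = mean(res$pev[valid])
  )
  if (interval_nsim > 0) {
    ci <- median_sspe_interval(sum(valid),
      nsim = max(interval_nsim, 1000),
      seed = interval_seed
    )
    smry$interval_lower <- ci[1]
    smry$interval_upper <- ci[2]
  }
  attr(res, "summary") <- smry
  class(res) <- unique(c("se_crossval", class(res)))
  res
}

#' @rdname loocv
#' @param x An `se_crossval`.
#' @param ... Ignored.
#' @export
glance.se_crossval <- function(x, ...) {
  attr(x, "summary")
}

#' Reference interval for the median SSPE under valid PEVs
#'
#' Monte Carlo central interval for the median of `n` independent
#' chi-square(1) draws — the null distribution of the median standardized
#' squared prediction error when the prediction error variances are
#' correct.  Shrinks toward the chi-square(1) median 0.455 as n grows.
#'
#' @param n Number of cross-validation sites (>= 2; n = 1 gives the
#'   central interval of a single chi-square(1) draw).
#' @param nsim Monte Carlo replicates (>= 1000).
#' @param level Interval coverage.
#' @param seed Seed.
#' @return Numeric `c(lower, upper)`.
#' @export
median_sspe_interval <- function(n, nsim = 10000, level = 0.95, seed = 1L) {
  stopifnot(n >= 1, nsim >= 1000, level > 0, level < 1)
  with_seed(seed, {
    meds <- apply(matrix(rchisq(n * nsim, df = 1), nrow = nsim), 1, median)
  })
  unname(quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' @rdname loocv
#' @param object An `se_crossval`.
#' @export
autoplot.se_crossval <- function(object, ...) {
  ok <- object[is.finite(object$sspe), ]
  p1 <- ggplot2::ggplot(ok, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(x = "predicted (log)", y = "observed (log)") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(
    ok, ggplot2::aes(.data$error / sqrt(.data$pev))
  ) +
    ggplot2::geom_histogram(bins = 25, fill = "grey40") +
    ggplot2::labs(x = "standardized error", y = "count") +
    ggplot2::theme_minimal()
  p3 <- ggplot2::ggplot(ok, ggplot2::aes(.data$x_km, .data$y_km,
    colour = .data$sspe
  )) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(trans = "sqrt") +
    ggplot2::labs(x = "Easting / km", y = "Northing / km", colour = "SSPE") +
    ggplot2::theme_minimal()
  p4 <- ggplot2::ggplot(ok, ggplot2::aes(.data$x_km, .data$y_km,
    colour = .data$pev
  )) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "Easting / km", y = "Northing / km", colour = "PEV") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, p3, p4, ncol = 2)
}
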