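#' Multivariate observation stacks
#'
#' The stacked data layout of the multivariate spatial model: one row per
#' (variable, site) observation with columns `var` (1 = target grain log
#' Se, 2 = other grain log Se, 3 = soil-predicted log Se), `site_id`,
#' `x_km`, `y_km`, `value`, plus any covariate columns used as fixed
#' effects.  `as_obs_stack()` validates the layout; `stack_from_survey()`
#' builds the trivariate stack of a survey for a chosen target crop.
#'
#' @param data A data frame in stack layout.
#' @return A validated tibble of class `se_stack`.
#' @export
as_obs_stack <- function(data) {
  need <- c("var", "site_id", "x_km", "y_km", "value")
  if (!all(need %in% names(data))) {
    abort(paste("stack must have columns:", paste(need, collapse = ", ")))
  }
  if (anyNA(data[need])) abort("stack has missing values in required columns")
  if (anyDuplicated(data[c("var", "site_id")])) {
    abort("each (variable, site) pair may appear at most once")
  }
  out <- as_tibble(data)
  out$var <- as.integer(out$var)
  class(out) <- unique(c("se_stack", class(out)))
  out
}

#' @rdname as_obs_stack
#' @param sites Survey sample table (one crop per site) with a
#'   `log_grain_se` column (see [apply_transform_rule()]).
#' @param target_crop `"teff"` or `"wheat"` — becomes variable 1.
#' @param y3 Optional soil-predicted log grain Se at every site (variable
#'   3), e.g. from [predict_from_soil()].
#' @param carry Covariate columns of `sites` to carry into the stack.
#' @export
stack_from_survey <- function(sites, target_crop = "teff", y3 = NULL,
                              carry = character(0)) {
  stopifnot(target_crop %in% c("teff", "wheat"), "log_grain_se" %in% names(sites))
  other <- setdiff(c("teff", "wheat"), target_crop)
  base_cols <- function(d) d[, c("site_id", "x_km", "y_km", carry)]
  s1 <- sites[sites$crop == target_crop, ]
  s2 <- sites[sites$crop == other, ]
  out <- bind_rows(
    dplyr::bind_cols(tibble(var = 1L, value = s1$log_grain_se), base_cols(s1)),
    dplyr::bind_cols(tibble(var = 2L, value = s2$log_grain_se), base_cols(s2))
  )
  if (!is.null(y3)) {
    stopifnot(length(y3) == nrow(sites))
    out <- bind_rows(
      out,
      dplyr::bind_cols(tibble(var = 3L, value = y3), base_cols(sites))
    )
  }
  as_obs_stack(out)
}

# Normalise a fixed-effect spec to a list: variable index -> column names.
normalize_fixed <- function(fixed, p) {
  out <- rep(list(character(0)), p)
  names(out) <- as.character(seq_len(p))
  if (is.null(fixed)) return(out)
  if (is.character(fixed)) {
    out[["1"]] <- fixed
    return(out)
  }
  for (nm in names(fixed)) out[[nm]] <- fixed[[nm]]
  out
}

# Block-structured design matrix: per-variable intercept + covariates.
build_design <- function(stack, fixed) {
  p <- max(stack$var)
  fixed <- normalize_fixed(fixed, p)
  cols <- list()
  labels <- character(0)
  for (u in seq_len(p)) {
    ind <- as.numeric(stack$var == u)
    cols[[length(cols) + 1]] <- ind
    labels <- c(labels, paste0("y", u, ":(Intercept)"))
    for (cn in fixed[[as.character(u)]]) {
      if (!cn %in% names(stack)) {
        abort(paste0("fixed-effect column '", cn, "' not found in stack"))
      }
      cols[[length(cols) + 1]] <- ind * stack[[cn]]
      labels <- c(labels, paste0("y", u, ":", cn))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  X
}

# Profiled Gaussian log-likelihood given V (beta by GLS); reml adds the
# restricted-likelihood determinant term for X.
gls_loglik <- function(y, X, V, reml = FALSE) {
  U <- chol_jitter(V)
  wy <- backsolve(U, y, transpose = TRUE)
  wX <- backsolve(U, X, transpose = TRUE)
  XtX <- crossprod(wX)
  Xty <- crossprod(wX, wy)
  cXtX <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(cXtX)) abort("singular fixed-effect design under this covariance")
  beta <- backsolve(cXtX, backsolve(cXtX, Xty, transpose = TRUE))
  res <- wy - wX %*% beta
  rss <- sum(res^2)
  n <- length(y)
  np <- ncol(X)
  logdetV <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi) + logdetV + rss)
  if (reml) {
    ll <- ll - 0.5 * 2 * sum(log(diag(cXtX))) + 0.5 * np * log(2 * pi)
  }
  list(
    ll = ll, beta = drop(beta), cov_beta = chol2inv(cXtX), U = U,
    rss = rss, labels = colnames(X)
  )
}

#' Negative log-likelihood of the multivariate spatial model
#'
#' Gaussian negative log-likelihood of an observation stack under a given
#' coregionalization, with the fixed-effect coefficients profiled out by
#' generalized least squares.  `method = "REML"` adds the restricted
#' likelihood's \eqn{\frac12\log|X'V^{-1}X|} adjustment.
#'
#' @param coreg An `se_coreg`.
#' @param stack An observation stack ([as_obs_stack()]).
#' @param fixed Fixed-effect spec: `NULL` (per-variable intercepts only), a
#'   character vector of stack columns for variable 1, or a named list of
#'   such vectors by variable index.
#' @param method "ML" or "REML".
#' @return The negative log-likelihood (a single number).
#' @export
negloglik <- function(coreg, stack, fixed = NULL, method = c("ML", "REML")) {
  method <- match.arg(method)
  stack <- as_obs_stack(stack)
  X <- build_design(stack, fixed)
  if (nrow(stack) <= ncol(X)) abort("stack is degenerate: n <= fixed-effect columns")
  V <- build_joint_cov(stack, coreg)
  -gls_loglik(stack$value, X, V, reml = method == "REML")$ll
}

# ---- packing of covariance parameters ----------------------------------
# Variance structure is packed through Cholesky factors (log diagonals,
# free off-diagonals) which guarantees PSD; phi is packed as log.  Nugget
# structural zeros are imposed as zeros of the T factor and excluded.

lower_mask <- function(p, nugget_zero = NULL) {
  M <- lower.tri(matrix(0, p, p))
  if (!is.null(nugget_zero)) {
    nz <- as.matrix(nugget_zero)
    for (k in seq_len(nrow(nz))) {
      u <- max(nz[k, ])
      v <- min(nz[k, ])
      M[u, v] <- FALSE
    }
  }
  M
}

chol_lower <- function(M, floor = 1e-8) {
  L <- tryCatch(t(chol(M)), error = function(e) {
    t(chol(M + diag(max(floor, 1e-8 * max(diag(M), 1)), nrow(M))))
  })
  L
}

pack_coreg <- function(coreg) {
  p <- coreg$p
  mT <- lower_mask(p, coreg$nugget_zero)
  mS <- lower_mask(p)
  LT <- chol_lower(coreg$T)
  LS <- chol_lower(coreg$S)
  c(
    log(pmax(diag(LT), 1e-8)), LT[mT],
    log(pmax(diag(LS), 1e-8)), LS[mS],
    log(coreg$phi)
  )
}

unpack_coreg <- function(par, p, kappa, nugget_zero = NULL) {
  mT <- lower_mask(p, nugget_zero)
  mS <- lower_mask(p)
  nT <- sum(mT)
  nS <- sum(mS)
  i <- 0
  LT <- matrix(0, p, p)
  diag(LT) <- exp(par[i + seq_len(p)])
  i <- i + p
  LT[mT] <- par[i + seq_len(nT)]
  i <- i + nT
  LS <- matrix(0, p, p)
  diag(LS) <- exp(par[i + seq_len(p)])
  i <- i + p
  LS[mS] <- par[i + seq_len(nS)]
  i <- i + nS
  phi <- exp(par[i + 1])
  structure(
    list(
      p = p, T = LT %*% t(LT), S = LS %*% t(LS), kappa = kappa,
      phi = phi, nugget_zero = nugget_zero
    ),
    class = "se_coreg"
  )
}

# Stagewise moment-based starting values: per-variable OLS residuals give
# empirical variograms whose WLS nugget+Matern fits supply the variance
# split and phi; cross terms start at the empirical residual correlations
# shrunk toward zero, which keeps the start strictly inside the PSD cone.
moment_init <- function(stack, X, p, kappa, nugget_zero) {
  beta0 <- tryCatch(qr.coef(qr(X), stack$value), error = function(e) NULL)
  resid <- if (is.null(beta0) || anyNA(beta0)) {
    stack$value - stats::ave(stack$value, stack$var)
  } else {
    stack$value - drop(X %*% beta0)
  }
  tau0 <- sig0 <- numeric(p)
  phis <- numeric(p)
  for (u in seq_len(p)) {
    ru <- resid[stack$var == u]
    vu <- max(var(ru), 1e-6)
    co <- cbind(stack$x_km, stack$y_km)[stack$var == u, , drop = FALSE]
    maxd <- max(dist(co))
    # cheap bin reading of the variogram: nugget from the first populated
    # bin, sill from the far bins, range from the 63%-rise lag
    est <- tryCatch({
      ev <- empirical_variogram(ru, co)
      ev <- ev[ev$npairs > 0 & is.finite(ev$gamma), ]
      g <- ev$gamma
      lg <- ev$lag
      c0 <- max(min(g[1], vu), 1e-3 * vu)
      sill <- max(mean(g[lg >= stats::quantile(lg, 2 / 3)]), c0 * 1.05)
      rise <- which(g >= c0 + 0.63 * (sill - c0))
      c(c0, sill - c0, if (length(rise)) lg[rise[1]] / 2 else maxd / 6)
    }, error = function(e) NULL)
    if (is.null(est) || est[2] < 1e-8) est <- c(vu / 2, vu / 2, maxd / 6)
    # rescale to the residual variance to damp variogram bias
    sc <- vu / (est[1] + est[2])
    tau0[u] <- max(est[1] * sc, 0.05 * vu)
    sig0[u] <- max(est[2] * sc, 0.05 * vu)
    phis[u] <- min(max(est[3], 1e-2), maxd)
  }
  Tm <- diag(tau0, p)
  Sm <- diag(sig0, p)
  if (p > 1) {
    masked <- lower_mask(p) & !lower_mask(p, nugget_zero)
    for (u in 2:p) {
      for (v in seq_len(u - 1)) {
        su <- stack$site_id[stack$var == u]
        sv <- stack$site_id[stack$var == v]
        shared <- intersect(su, sv)
        r_emp <- if (length(shared) > 5) {
          suppressWarnings(cor(
            resid[stack$var == u][match(shared, su)],
            resid[stack$var == v][match(shared, sv)]
          ))
        } else {
          0.3 # co-varying by design; a modest interior start
        }
        if (!is.finite(r_emp)) r_emp <- 0
        r_emp <- max(min(r_emp, 0.8), -0.8) * 0.7
        Sm[u, v] <- Sm[v, u] <- r_emp * sqrt(sig0[u] * sig0[v])
        if (!masked[u, v]) {
          Tm[u, v] <- Tm[v, u] <- r_emp * sqrt(tau0[u] * tau0[v])
        }
      }
    }
  }
  # project to the strict interior of the PSD cone
  fix_psd <- function(M) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    lo <- 0.01 * max(e$values)
    e$vectors %*% (pmax(e$values, lo) * t(e$vectors))
  }
  Tm <- fix_psd(Tm)
  Sm <- fix_psd(Sm)
  if (!is.null(nugget_zero)) {
    nz <- as.matrix(nugget_zero)
    for (k in seq_len(nrow(nz))) Tm[nz[k, 1], nz[k, 2]] <- 0
  }
  structure(
    list(
      p = p, T = Tm, S = Sm, kappa = kappa, phi = stats::median(phis),
      nugget_zero = nugget_zero
    ),
    class = "se_coreg"
  )
}

#' Fit the spatial linear mixed model
#'
#' Likelihood-based estimation of the (possibly multivariate) spatial
#' linear mixed model with a Matern linear model of coregionalization:
#' variances, cross-correlations and the distance parameter phi are
#' estimated by ML or REML over a PSD-guaranteed parameterization
#' (Cholesky factors, log variances, log phi) with a multi-start
#' derivative-free simplex search and a quasi-Newton polish; the
#' fixed-effect coefficients and their standard errors follow by
#' generalized least squares at the optimum.  The Matern smoothness kappa
#' is never estimated jointly — fix it here or profile it with
#' [profile_kappa()].
#'
#' @param stack An observation stack.
#' @param fixed Fixed-effect spec (see [negloglik()]).
#' @param method "REML" (default, for final predictive fits) or "ML" (for
#'   fixed-effect testing).
#' @param kappa Fixed Matern smoothness.
#' @param starts Number of dispersed optimizer starts.
#' @param init Optional `se_coreg` used as the central start.
#' @param nugget_zero Structural-zero pairs of the nugget matrix (defaults
#'   to the teff--wheat pair (1,2) for multivariate stacks, which are never
#'   co-located).
#' @param maxit Simplex iteration cap per start.
#' @param polish Run a BFGS polish from the best simplex solution?
#' @return An object of class `se_lmm`: coefficient table, fitted
#'   `se_coreg`, log-likelihood, convergence record and the stack.
#' @export
fit_lmm <- function(stack, fixed = NULL, method = c("REML", "ML"),
                    kappa = 0.5, starts = 5, init = NULL,
                    nugget_zero = NULL, maxit = 500, polish = TRUE) {
  method <- match.arg(method)
  stack <- as_obs_stack(stack)
  p <- max(stack$var)
  if (is.null(nugget_zero) && p >= 2) nugget_zero <- cbind(c(1, 2), c(2, 1))
  X <- build_design(stack, fixed)
  y <- stack$value
  if (length(unique(stack$site_id)) < 2) abort("need >= 2 distinct sites")
  if (nrow(stack) <= ncol(X)) abort("stack is degenerate: n <= fixed-effect columns")

  vidx <- stack$var
  sid <- match(stack$site_id, unique(stack$site_id))
  ucoords <- cbind(stack$x_km, stack$y_km)[!duplicated(sid), , drop = FALSE]
  D <- as.matrix(dist(ucoords))
  same_site <- outer(sid, sid, "==")
  reml <- method == "REML"

  # correlation over the lower triangle only (D is symmetric, zero diag);
  # non-half-integer smoothness goes through a cubic-spline interpolant of
  # the Bessel form (absolute error < 1e-6), rebuilt once per fit
  nu <- nrow(D)
  lowtri <- lower.tri(D)
  lowD <- D[lowtri]
  rho_fun <- matern_evaluator(kappa)
  build_R <- function(phi) {
    Rm <- matrix(0, nu, nu)
    Rm[lowtri] <- rho_fun(lowD / phi)
    Rm <- Rm + t(Rm)
    diag(Rm) <- 1
    Rm
  }
  build_V <- function(cg) {
    cg$S[vidx, vidx, drop = FALSE] *
      build_R(cg$phi)[sid, sid, drop = FALSE] +
      cg$T[vidx, vidx, drop = FALSE] * same_site
  }
  objective <- function(par) {
    cg <- unpack_coreg(par, p, kappa, nugget_zero)
    if (!is.finite(cg$phi) || cg$phi <= 0 || cg$phi > 1e4) return(1e10)
    out <- tryCatch(
      -gls_loglik(y, X, build_V(cg), reml = reml)$ll,
      error = function(e) NA_real_
    )
    if (!is.finite(out)) 1e10 else out
  }

  # stagewise central start: per-variable variogram-based moment estimates
  # of the nugget/spatial split and phi, with modest cross-correlations
  if (is.null(init)) {
    init <- moment_init(stack, X, p, kappa, nugget_zero)
  }
  par0 <- pack_coreg(init)
  nv <- length(par0)
  disp <- list(numeric(nv)) # centre
  if (starts > 1) {
    set_fac <- list(
      c(var = log(3), phi = log(0.3)),
      c(var = log(1 / 3), phi = log(3)),
      c(var = log(2), phi = log(1)),
      c(var = log(1 / 2), phi = log(0.5))
    )
    diag_pos <- c(seq_len(p), p + sum(lower_mask(p, nugget_zero)) + seq_len(p))
    for (k in seq_len(min(starts - 1, length(set_fac)))) {
      d <- numeric(nv)
      d[diag_pos] <- set_fac[[k]]["var"] / 2 # factors act on sd scale
      d[nv] <- set_fac[[k]]["phi"]
      disp[[k + 1]] <- d
    }
  }

  runs <- purrr::map_dfr(seq_along(disp), function(k) {
    fit <- tryCatch(
      optim(par0 + disp[[k]], objective,
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-6)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble(start = k, value = NA_real_, convergence = NA_integer_,
                    par = list(NULL)))
    }
    tibble(
      start = k, value = fit$value, convergence = fit$convergence,
      par = list(fit$par)
    )
  })
  ok <- which(is.finite(runs$value) & runs$value < 1e9)
  if (length(ok) == 0) {
    abort("all optimizer starts failed; see per-start diagnostics")
  }
  best <- ok[which.min(runs$value[ok])]
  par_best <- runs$par[[best]]
  val_best <- runs$value[best]
  if (polish) {
    pol <- tryCatch(
      optim(par_best, objective,
        method = "BFGS",
        control = list(maxit = 60, reltol = 1e-8)
      ),
      error = function(e) NULL
    )
    if (!is.null(pol) && is.finite(pol$value) && pol$value < val_best) {
      par_best <- pol$par
      val_best <- pol$value
    }
  }

  cg <- unpack_coreg(par_best, p, kappa, nugget_zero)
  fit_g <- gls_loglik(y, X, build_V(cg), reml = reml)
  beta_tbl <- tibble(
    term = colnames(X),
    var = as.integer(sub("^y(\\d+):.*$", "\\1", colnames(X))),
    estimate = unname(fit_g$beta),
    std_error = sqrt(pmax(diag(fit_g$cov_beta), 0))
  )
  structure(
    list(
      beta = beta_tbl, coreg = cg, logLik = fit_g$ll, method = method,
      kappa = kappa,
      convergence = dplyr::select(runs, "start", "value", "convergence"),
      fixed = normalize_fixed(fixed, p), stack = stack, X = X
    ),
    class = "se_lmm"
  )
}

#' @export
print.se_lmm <- function(x, ...) {
  cat(
    "Spatial LMM (", x$method, "), ", max(x$stack$var), " variable(s), ",
    nrow(x$stack), " observations\n",
    sep = ""
  )
  cat("log-likelihood:", format(x$logLik, digits = 6), "\n")
  cat("kappa =", x$coreg$kappa, " phi =", round(x$coreg$phi, 3), "km\n")
  cat("Coefficients:\n")
  print(as.data.frame(x$beta[, c("term", "estimate", "std_error")]),
    row.names = FALSE, digits = 4
  )
  invisible(x)
}

#' @rdname fit_lmm
#' @param x An `se_lmm` fit.
#' @param ... Ignored.
#' @export
tidy.se_lmm <- function(x, ...) {
  mutate(x$beta,
    statistic = .data$estimate / .data$std_error,
    .after = "std_error"
  )
}

#' @rdname fit_lmm
#' @export
glance.se_lmm <- function(x, ...) {
  tibble(
    logLik = x$logLik, method = x$method, kappa = x$coreg$kappa,
    phi = x$coreg$phi, nobs = nrow(x$stack), n_coef = nrow(x$beta),
    r2_adj = tryCatch(adjusted_r2(x), error = function(e) NA_real_)
  )
}

#' Log-likelihood ratio test of nested fixed-effect specifications
#'
#' `D = 2(l1 - l0)` (clamped at zero, with a warning when the optimizer
#' noise makes it negative) referred to a chi-square with as many degrees
#' of freedom as added fixed-effect columns.  Both fits must be ML on the
#' same stack; REML likelihoods are not comparable across fixed-effect
#' specifications.
#'
#' @param fit0,fit1 Nested `se_lmm` fits (fit0's design columns a subset
#'   of fit1's).
#' @return One-row tibble (statistic, df, p_value).
#' @export
lr_test <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "se_lmm"), inherits(fit1, "se_lmm"))
  if (fit0$method != "ML" || fit1$method != "ML") {
    abort("likelihood ratio tests of fixed effects require ML fits")
  }
  l0 <- colnames(fit0$X)
  l1 <- colnames(fit1$X)
  if (!all(l0 %in% l1) || length(l1) <= length(l0)) {
    abort("fit0 must be strictly nested in fit1")
  }
  if (nrow(fit0$stack) != nrow(fit1$stack)) abort("fits use different stacks")
  D <- 2 * (fit1$logLik - fit0$logLik)
  if (D < 0) {
    warn(paste0("negative deviance (", format(D), ") clamped to 0"))
    D <- 0
  }
  df <- length(l1) - length(l0)
  tibble(statistic = D, df = df, p_value = pchisq(D, df, lower.tail = FALSE))
}

#' Profile likelihood for the Matern smoothness parameter
#'
#' Fits the model at each fixed kappa of a grid and returns the grid value
#' maximizing the log-likelihood, with the full profile table.  Default
#' grid \{0.25, 0.5, 1, 1.5, 2, 3\}.
#'
#' @param stack,fixed,method,... Passed to [fit_lmm()].
#' @param kappa_grid Candidate smoothness values.
#' @return List: `best_kappa`, `profile` (tibble kappa/logLik/ok), `fits`.
#' @export
profile_kappa <- function(stack, fixed = NULL,
                          kappa_grid = c(0.25, 0.5, 1, 1.5, 2, 3),
                          method = "ML", ...) {
  stopifnot(length(kappa_grid) >= 1)
  fits <- purrr::map(kappa_grid, function(k) {
    tryCatch(fit_lmm(stack, fixed, method = method, kappa = k, ...),
      error = function(e) e
    )
  })
  prof <- tibble(
    kappa = kappa_grid,
    logLik = vapply(fits, function(f) {
      if (inherits(f, "se_lmm")) f$logLik else NA_real_
    }, 0),
    ok = vapply(fits, inherits, TRUE, "se_lmm")
  )
  if (!any(prof$ok)) abort("all kappa-profile fits failed")
  list(
    best_kappa = prof$kappa[which.max(ifelse(prof$ok, prof$logLik, -Inf))],
    profile = prof,
    fits = fits
  )
}

#' Adjusted R-squared of the fixed effects for the target variable
#'
#' `1 - [RSS/(n-p)] / [TSS/(n-1)]` computed on fixed-effects-only
#' predictions of the target (variable 1) rows; returns 0 by convention
#' for a constant-only model.
#'
#' @param fit An `se_lmm`.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(fit) {
  stopifnot(inherits(fit, "se_lmm"))
  rows <- fit$stack$var == 1
  cols <- fit$beta$var == 1
  np <- sum(cols)
  if (np <= 1) return(0)
  y <- fit$stack$value[rows]
  n <- length(y)
  if (n <= np) abort("adjusted R-squared undefined: n <= p")
  yhat <- drop(fit$X[rows, cols, drop = FALSE] %*% fit$beta$estimate[cols])
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  1 - (rss / (n - np)) / (tss / (n - 1))
}
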