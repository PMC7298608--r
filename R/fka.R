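# Correlation-variogram of one nested structure, g in [0, 1].
structure_gamma <- function(h, family, range) {
  switch(family,
    exponential = 1 - exp(-h / range),
    spherical = ifelse(h < range,
      1.5 * h / range - 0.5 * (h / range)^3, 1
    ),
    matern = 1 - matern_corr(h, 2, range),
    abort("unknown structure family")
  )
}

#' Nested variogram model
#'
#' Semivariance \eqn{\gamma(h) = c_0 1\{h>0\} + \sum_k c_k g_k(h/a_k)}
#' with non-negative nugget `c0` and structure sills `c_k`, and strictly
#' increasing distance parameters `a_k` (short-range structures before
#' long-range).  `nested_gamma()` evaluates the semivariance,
#' `nested_cov()` the corresponding covariance
#' \eqn{C(h) = c_0 1\{h=0\} + \sum_k c_k (1 - g_k(h/a_k))}.
#'
#' @param c0 Nugget variance.
#' @param sills Structure sills (short to long).
#' @param ranges Structure distance parameters (km), strictly increasing.
#' @param families Correlation families per structure
#'   ("exponential", "spherical" or "matern").
#' @return An object of class `se_nested_vgm`.
#' @export
nested_variogram <- function(c0, sills, ranges,
                             families = rep("exponential", length(sills))) {
  stopifnot(
    c0 >= 0, all(sills >= 0), all(ranges > 0),
    length(sills) == length(ranges),
    length(families) == length(sills),
    length(ranges) < 2 || all(diff(ranges) > 0)
  )
  structure(
    list(
      c0 = c0,
      structures = tibble(sill = sills, family = families, range = ranges)
    ),
    class = "se_nested_vgm"
  )
}

#' @rdname nested_variogram
#' @param model An `se_nested_vgm`.
#' @param h Distances (km).
#' @export
nested_gamma <- function(model, h) {
  g <- model$c0 * (h > 0)
  for (k in seq_len(nrow(model$structures))) {
    s <- model$structures[k, ]
    g <- g + s$sill * structure_gamma(h, s$family, s$range)
  }
  g
}

#' @rdname nested_variogram
#' @export
nested_cov <- function(model, h) {
  cv <- model$c0 * (h == 0)
  for (k in seq_len(nrow(model$structures))) {
    s <- model$structures[k, ]
    cv <- cv + s$sill * (1 - structure_gamma(h, s$family, s$range))
  }
  cv
}

#' @export
print.se_nested_vgm <- function(x, ...) {
  cat("Nested variogram model: nugget c0 =", signif(x$c0, 4), "\n")
  print(as.data.frame(x$structures), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit a nested variogram by weighted least squares
#'
#' Minimizes the pair-count-weighted squared deviation between the model
#' and an empirical variogram, with Cressie-style weights
#' \eqn{N(h)/\gamma_{model}(h)^2} refreshed over a few re-weighting
#' passes.  Non-negativity of sills and the ordering of ranges are imposed
#' through the parameterization.  A degenerate (flat) empirical variogram
#' yields a pure-nugget model with a warning.
#'
#' @param ev An [empirical_variogram()] with at least 5 populated bins.
#' @param n_structures Number of nested structures (default 2:
#'   short-range + long-range).
#' @param families Correlation families per structure.
#' @return An `se_nested_vgm` with a `fit` attribute recording the WLS
#'   objective and convergence.
#' @export
fit_nested_variogram <- function(ev, n_structures = 2,
                                 families = rep("exponential", n_structures)) {
  dat <- ev[ev$npairs > 0 & is.finite(ev$gamma), ]
  if (nrow(dat) < 5) abort("need at least 5 populated variogram bins")
  h <- dat$lag
  g <- dat$gamma
  np <- dat$npairs
  sill_tot <- mean(g[h >= stats::quantile(h, 0.5)])
  if (sd(g) < 0.02 * max(mean(g), 1e-12)) {
    warn("flat empirical variogram: returning a pure-nugget model")
    out <- nested_variogram(mean(g), rep(0, n_structures),
      ranges = seq_len(n_structures) * max(h) / 4, families = families
    )
    attr(out, "fit") <- list(objective = NA_real_, convergence = NA_integer_)
    return(out)
  }
  # par: log c0, log sills, log a1, log increments of further ranges
  unpack <- function(par) {
    c0 <- exp(par[1])
    sills <- exp(par[1 + seq_len(n_structures)])
    ranges <- cumsum(exp(par[1 + n_structures + seq_len(n_structures)]))
    nested_variogram(c0, sills, ranges, families)
  }
  obj_w <- function(par, w) {
    m <- tryCatch(unpack(par), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    sum(w * (g - nested_gamma(m, h))^2)
  }
  hmax <- max(h)
  starts <- list(
    c(log(sill_tot / 4), rep(log(sill_tot / 2), n_structures),
      log(hmax / 10), rep(log(hmax / 3), n_structures - 1)),
    c(log(sill_tot / 10), rep(log(sill_tot / 2), n_structures),
      log(hmax / 20), rep(log(hmax / 2), n_structures - 1)),
    c(log(sill_tot / 2), rep(log(sill_tot / 3), n_structures),
      log(hmax / 5), rep(log(hmax), n_structures - 1))
  )
  best <- NULL
  for (p0 in starts) {
    w <- np # first pass: pair-count weights
    fit <- NULL
    for (pass in 1:3) { # Cressie re-weighting
      fit <- tryCatch(
        optim(if (is.null(fit)) p0 else fit$par, obj_w,
          w = w, method = "Nelder-Mead",
          control = list(maxit = 800, reltol = 1e-10)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) break
      gm <- nested_gamma(unpack(fit$par), h)
      w <- np / pmax(gm, 1e-8)^2
    }
    if (is.null(fit)) next
    # compare starts on the final Cressie-weighted objective
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("nested variogram fit failed from all starts")
  out <- unpack(best$par)
  attr(out, "fit") <- list(objective = best$value, convergence = best$convergence)
  out
}

#' Factorial kriging of one spatial component
#'
#' Ordinary-kriging estimate of a single additive component of a variable
#' under a nested variogram model: the kriging system uses the full model
#' covariance on the left side and the chosen component's covariance on
#' the right.  Components (`"nugget"`, structure index or `"short"` /
#' `"long"` with two structures) are estimated with sum-to-zero weights;
#' the local `"mean"` with sum-to-one weights and a zero right side; and
#' `"ok"` gives the ordinary-kriging estimate of the full variable.  By
#' linearity of the kriging system, mean + nugget + all structure
#' components equals the ordinary-kriging estimate exactly.
#'
#' @param values,coords Data values and their coordinates (two columns, km).
#' @param model An `se_nested_vgm`.
#' @param targets Two-column matrix/data frame of target coordinates.
#' @param component `"nugget"`, `"mean"`, `"ok"`, a structure index, or
#'   `"short"` / `"long"` (structures 1 and 2).
#' @param max_data Size guard: above this many data the system is built on
#'   an evenly thinned subset.
#' @return Numeric vector of component estimates at the targets.
#' @export
krige_component <- function(values, coords, model, targets,
                            component = "long", max_data = 2000) {
  coords <- as.matrix(coords)
  targets <- as.matrix(targets)
  n <- length(values)
  stopifnot(nrow(coords) == n)
  if (n > max_data) {
    keep <- unique(round(seq(1, n, length.out = max_data)))
    values <- values[keep]
    coords <- coords[keep, , drop = FALSE]
    n <- length(values)
  }
  D <- as.matrix(dist(coords))
  A <- rbind(
    cbind(nested_cov(model, D), 1),
    c(rep(1, n), 0)
  )
  # cross-distances data -> targets
  Dt <- sqrt(
    outer(coords[, 1], targets[, 1], "-")^2 +
      outer(coords[, 2], targets[, 2], "-")^2
  )
  ns <- nrow(model$structures)
  comp_rhs <- function(comp) {
    if (identical(comp, "mean")) {
      return(rbind(matrix(0, n, ncol(Dt)), 1))
    }
    if (identical(comp, "ok")) {
      return(rbind(nested_cov(model, Dt), 1))
    }
    if (identical(comp, "nugget")) {
      return(rbind(model$c0 * (Dt == 0), 0))
    }
    k <- if (identical(comp, "short")) {
      1L
    } else if (identical(comp, "long")) {
      if (ns < 2) abort("'long' needs two structures") else 2L
    } else {
      as.integer(comp)
    }
    stopifnot(k >= 1, k <= ns)
    s <- model$structures[k, ]
    rbind(s$sill * (1 - structure_gamma(Dt, s$family, s$range)), 0)
  }
  B <- comp_rhs(component)
  sol <- tryCatch(solve(A, B), error = function(e) {
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-10
    solve(A, B)
  })
  drop(crossprod(sol[seq_len(n), , drop = FALSE], values))
}

#' Factorial-kriging decomposition of a covariate grid
#'
#' Fits a two-structure nested variogram to the grid's empirical variogram
#' and kriges the short-range and long-range components at every cell.
#' The estimated local mean is folded into the long-range surface, so
#' `short + long + nugget-component` reproduces the ordinary-kriging
#' estimate of the covariate.
#'
#' @param grid An `se_grid`.
#' @param model Optional pre-fitted `se_nested_vgm`; fitted from the grid
#'   when NULL.
#' @param max_data Passed to [krige_component()].
#' @return List: `model`, `long` and `short` (`se_grid` components),
#'   `variogram` (the empirical variogram used).
#' @export
fka_decompose <- function(grid, model = NULL, max_data = 2000) {
  gt <- grid_to_tibble(grid)
  ev <- empirical_variogram(gt$value, cbind(gt$x_km, gt$y_km))
  if (is.null(model)) model <- fit_nested_variogram(ev, n_structures = 2)
  tg <- cbind(gt$x_km, gt$y_km)
  short_v <- krige_component(gt$value, tg, model, tg, "short", max_data)
  long_v <- krige_component(gt$value, tg, model, tg, "long", max_data) +
    krige_component(gt$value, tg, model, tg, "mean", max_data)
  shape <- function(v, suffix) {
    m <- matrix(v, nrow = nrow(grid$values), ncol = ncol(grid$values))
    se_grid(m,
      xll = grid$xll, yll = grid$yll, cellsize = grid$cellsize,
      name = paste0(grid$name, suffix)
    )
  }
  # grid_to_tibble unrolls column-major with row 1 = north, so reshape back
  list(
    model = model,
    short = shape(short_v, "__short"),
    long = shape(long_v, "__long"),
    variogram = ev
  )
}

#' Filter fixed-effect components by standardized coefficient
#'
#' Fits the model with all candidate component columns as fixed effects of
#' the target variable and retains those whose standardized coefficient
#' (estimate / standard error) falls outside [-2, 2]; then refits with the
#' retained set.
#'
#' @param stack Observation stack containing the candidate columns.
#' @param candidates Candidate component column names (for variable 1).
#' @param base_fixed Fixed-effect spec kept regardless of filtering.
#' @param threshold Retention threshold on |standardized coefficient|.
#' @param ... Passed to [fit_lmm()] (method defaults to ML).
#' @return List: `retained` labels, `fit` (refit with retained set),
#'   `coefficients` (tibble of the all-candidates fit).
#' @export
filter_components <- function(stack, candidates, base_fixed = NULL,
                              threshold = 2, ...) {
  stack <- as_obs_stack(stack)
  p <- max(stack$var)
  base_fixed <- normalize_fixed(base_fixed, p)
  if (length(candidates) == 0) {
    fit <- fit_lmm(stack, base_fixed, method = "ML", ...)
    return(list(retained = character(0), fit = fit, coefficients = tidy(fit)))
  }
  full <- base_fixed
  full[["1"]] <- c(full[["1"]], candidates)
  fit_all <- fit_lmm(stack, full, method = "ML", ...)
  tt <- tidy(fit_all)
  cand_rows <- tt$term %in% paste0("y1:", candidates)
  retained <- sub("^y1:", "", tt$term[cand_rows & abs(tt$statistic) > threshold])
  kept <- base_fixed
  kept[["1"]] <- c(kept[["1"]], retained)
  fit <- fit_lmm(stack, kept, method = "ML", init = fit_all$coreg, ...)
  list(retained = retained, fit = fit, coefficients = tt)
}
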