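# Incremental alpha-investing engine.  Rule: with wealth W(j-1) and k_j the
# index of the most recent rejection (0 initially), spend
# alpha_j = W(j-1) / (1 + j - k_j); reject iff p <= alpha_j; wealth update
# W(j) = W(j-1) - alpha_j/(1-alpha_j) + payout * 1{reject}.
new_investor <- function(w0 = 0.05, payout = 0.05) {
  env <- new.env()
  env$wealth <- w0
  env$j <- 0L
  env$last_rej <- 0L
  env$rows <- list()
  env$next_alpha <- function() {
    if (env$wealth <= 1e-12) return(NA_real_)
    env$wealth / (1 + (env$j + 1L) - env$last_rej)
  }
  env$record <- function(label, p) {
    if (!is.finite(p) || p < 0 || p > 1) abort("p-value outside [0, 1]")
    a <- env$next_alpha()
    if (is.na(a) || a <= 0) return(NA) # wealth exhausted
    env$j <- env$j + 1L
    reject <- p <= a
    env$wealth <- env$wealth - a / (1 - a) + if (reject) payout else 0
    if (reject) env$last_rej <- env$j
    env$rows[[env$j]] <- tibble(
      order = env$j, label = label, p_value = p, alpha = a,
      decision = if (reject) "reject" else "accept", wealth = env$wealth
    )
    reject
  }
  env
}

ledger_from_investor <- function(env, w0, payout) {
  led <- if (length(env$rows)) bind_rows(env$rows) else tibble(
    order = integer(), label = character(), p_value = numeric(),
    alpha = numeric(), decision = character(), wealth = numeric()
  )
  attr(led, "w0") <- w0
  attr(led, "payout") <- payout
  class(led) <- unique(c("se_ledger", class(led)))
  led
}

#' Sequential testing with alpha-investing
#'
#' Runs an a-priori-ordered sequence of hypothesis tests under marginal
#' false-discovery-rate control by alpha-investing.  A wealth of type-I
#' error (initially `w0`) is spent on each test at rate
#' `alpha_j = W(j-1)/(1 + j - k_j)` (`k_j` the index of the latest
#' rejection); each test costs `alpha_j/(1-alpha_j)` and each rejection
#' pays back `payout`.  Testing stops when the wealth is exhausted or the
#' sequence ends.  The ordering affects power only, never the validity of
#' the FDR control.
#'
#' @param labels Ordered hypothesis labels.
#' @param p_values Either a numeric vector of p-values aligned with
#'   `labels`, or a function `label -> p-value` called lazily in order.
#' @param w0 Initial alpha-wealth.
#' @param payout Wealth earned per rejection.
#' @return A ledger tibble of class `se_ledger`: order, label, p_value,
#'   alpha (threshold), decision, wealth (after the test).
#' @export
alpha_investing <- function(labels, p_values, w0 = 0.05, payout = 0.05) {
  stopifnot(length(labels) >= 1, !anyDuplicated(labels))
  p_fun <- if (is.function(p_values)) {
    p_values
  } else {
    stopifnot(length(p_values) == length(labels))
    pv <- setNames(as.numeric(p_values), labels)
    function(lab) pv[[lab]]
  }
  inv <- new_investor(w0, payout)
  for (lab in labels) {
    res <- inv$record(lab, p_fun(lab))
    if (is.na(res)) break
  }
  ledger_from_investor(inv, w0, payout)
}

#' @rdname alpha_investing
#' @param object An `se_ledger`.
#' @param ... Ignored.
#' @export
autoplot.se_ledger <- function(object, ...) {
  w0 <- attr(object, "w0") %||% 0.05
  wl <- bind_rows(
    tibble(order = 0, wealth = w0),
    object[, c("order", "wealth")]
  )
  p1 <- ggplot2::ggplot(wl, ggplot2::aes(.data$order, .data$wealth)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression(alpha ~ "-wealth")) +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(object, ggplot2::aes(x = .data$order)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_value), shape = 1, size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$alpha), shape = 16, size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_x_continuous(
      breaks = object$order, labels = object$label
    ) +
    ggplot2::labs(
      x = "test", y = "p-value (open) / threshold (solid)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  patchwork::wrap_plots(p1, p2, ncol = 1)
}

#' Forward predictor selection under marginal FDR control
#'
#' Starting from a constant-mean null model, candidate predictors are added
#' one by one in the configured a-priori order; each addition is judged by
#' a log-likelihood ratio test (ML) whose p-value is fed to the
#' alpha-investing rule.  Rejected nulls (selected predictors) stay in the
#' model; a predictor once passed over is never revisited.
#'
#' With `refit_each = TRUE` (the default) the covariance parameters are
#' re-estimated by ML at every step.  With `refit_each = FALSE` they are
#' estimated once under the null model and the sequential tests are GLS
#' likelihood-ratio tests at that fixed covariance — a fast variant used
#' for large replicate simulations; mFDR control holds for either, since
#' it only requires valid p-values.
#'
#' @param stack Observation stack (the target grain's rows, or a
#'   multivariate stack; candidate columns must be present).
#' @param labels Ordered candidate predictor columns.
#' @param w0,payout Alpha-investing parameters.
#' @param refit_each Re-estimate covariance parameters at every step?
#' @param final_fit Fit and return the final model for the selected set?
#' @param kappa,starts,maxit,polish Passed to [fit_lmm()].
#' @return List of class `se_selection`: `selected` labels, `ledger`
#'   (`se_ledger`), `fit` (final `se_lmm` or NULL).
#' @export
select_predictors <- function(stack, labels, w0 = 0.05, payout = 0.05,
                              refit_each = TRUE, final_fit = TRUE,
                              kappa = 0.5, starts = 3, maxit = 400,
                              polish = TRUE) {
  stack <- as_obs_stack(stack)
  if (length(labels) > 0 && !all(labels %in% names(stack))) {
    abort(paste(
      "candidate predictors missing from stack:",
      paste(setdiff(labels, names(stack)), collapse = ", ")
    ))
  }
  fit_args <- list(
    method = "ML", kappa = kappa, starts = starts, maxit = maxit,
    polish = polish
  )
  fit0 <- do.call(fit_lmm, c(list(stack, fixed = NULL), fit_args))
  inv <- new_investor(w0, payout)
  selected <- character(0)
  if (length(labels) == 0) {
    return(structure(
      list(
        selected = selected, ledger = ledger_from_investor(inv, w0, payout),
        fit = if (final_fit) fit0 else NULL
      ),
      class = "se_selection"
    ))
  }

  if (refit_each) {
    for (lab in labels) {
      cand <- c(selected, lab)
      fit1 <- do.call(fit_lmm, c(
        list(stack, fixed = cand, init = fit0$coreg), fit_args
      ))
      p <- lr_test(fit0, fit1)$p_value
      res <- inv$record(lab, p)
      if (is.na(res)) break
      if (res) {
        selected <- cand
        fit0 <- fit1
      }
    }
    fit_final <- if (final_fit) fit0 else NULL
  } else {
    V0 <- build_joint_cov(stack, fit0$coreg)
    y <- stack$value
    ll_at <- function(fx) gls_loglik(y, build_design(stack, fx), V0)$ll
    ll_sel <- ll_at(NULL)
    for (lab in labels) {
      cand <- c(selected, lab)
      ll1 <- ll_at(cand)
      D <- max(0, 2 * (ll1 - ll_sel))
      p <- pchisq(D, df = 1, lower.tail = FALSE)
      res <- inv$record(lab, p)
      if (is.na(res)) break
      if (res) {
        selected <- cand
        ll_sel <- ll1
      }
    }
    fit_final <- if (final_fit) {
      do.call(fit_lmm, c(
        list(stack, fixed = selected, init = fit0$coreg), fit_args
      ))
    } else {
      NULL
    }
  }
  structure(
    list(
      selected = selected, ledger = ledger_from_investor(inv, w0, payout),
      fit = fit_final
    ),
    class = "se_selection"
  )
}

#' @export
print.se_selection <- function(x, ...) {
  cat("Sequential selection under marginal FDR control\n")
  cat(
    "selected:",
    if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
    "\n"
  )
  print(as.data.frame(x$ledger), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Soil-based prediction of grain Se at every site
#'
#' Fixed-effects-only prediction `X tau-hat` (log scale) of the target
#' grain's Se concentration from the soil model, computable at every site
#' — including those growing the other crop — because soil is measured
#' everywhere.  This constructs the third variable of the trivariate model.
#'
#' @param fit The final soil `se_lmm` (variable 1 = target grain).
#' @param data Sample table (transformed scale) with all selected soil
#'   predictor columns at every site.
#' @return Numeric vector of predictions, one per row of `data`.
#' @export
predict_from_soil <- function(fit, data) {
  stopifnot(inherits(fit, "se_lmm"))
  b <- fit$beta[fit$beta$var == 1, ]
  terms <- sub("^y1:", "", b$term)
  pred <- rep(0, nrow(data))
  for (k in seq_along(terms)) {
    if (terms[k] == "(Intercept)") {
      pred <- pred + b$estimate[k]
    } else {
      if (!terms[k] %in% names(data)) {
        abort(paste0("soil predictor '", terms[k], "' missing from data"))
      }
      x <- data[[terms[k]]]
      if (anyNA(x)) {
        bad <- which(is.na(x))
        abort(paste0(
          "soil predictor '", terms[k], "' missing at rows: ",
          paste(head(bad, 10), collapse = ", ")
        ))
      }
      pred <- pred + b$estimate[k] * x
    }
  }
  pred
}
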