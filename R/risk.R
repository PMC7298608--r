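#' Probability that the true concentration falls below a threshold
#'
#' Assuming normal prediction errors on the log scale,
#' \eqn{P(Z < t) = \Phi((\ln t - \hat z)/\sqrt{PEV})}.  With `pev = 0`
#' the probability degenerates to the indicator `pred_log < log(threshold)`.
#'
#' @param pred_log Log-scale prediction(s).
#' @param pev Prediction error variance(s), >= 0 (log scale).
#' @param threshold Concentration threshold (mg/kg), > 0.
#' @return Probabilities in [0, 1]; vectorised.
#' @export
prob_below <- function(pred_log, pev, threshold) {
  if (any(threshold <= 0)) abort("threshold must be positive")
  stopifnot(all(pev >= 0))
  z <- log(threshold) - pred_log
  out <- ifelse(pev > 0, pnorm(z / sqrt(pev)), as.numeric(z > 0))
  out
}

#' Calibrated verbal probability scale
#'
#' Ordered probability bins with calibrated likelihood phrases.  The
#' default scale: < 0.01 "exceptionally unlikely"; < 0.10 "very unlikely";
#' < 0.33 "unlikely"; 0.33--0.66 "about as likely as not"; > 0.66
#' "likely"; > 0.90 "very likely"; > 0.99 "virtually certain".  Bins are
#' half-open [lower, upper) except the final bin, which is closed at 1.
#'
#' @param upper Strictly increasing upper bounds, last equal to 1.
#' @param phrases Unique phrase per bin.
#' @return Tibble of class `se_verbal_scale` (lower, upper, phrase).
#' @export
verbal_scale <- function(upper = c(0.01, 0.10, 0.33, 0.66, 0.90, 0.99, 1),
                         phrases = c(
                           "exceptionally unlikely", "very unlikely",
                           "unlikely", "about as likely as not", "likely",
                           "very likely", "virtually certain"
                         )) {
  stopifnot(
    length(upper) == length(phrases), all(diff(upper) > 0),
    upper[length(upper)] == 1, !anyDuplicated(phrases)
  )
  out <- tibble(
    lower = c(0, upper[-length(upper)]), upper = upper, phrase = phrases
  )
  class(out) <- unique(c("se_verbal_scale", class(out)))
  out
}

#' @rdname verbal_scale
#' @param p Probabilities in [0, 1].
#' @param scale A [verbal_scale()].
#' @return Phrases (character), one per probability.
#' @export
verbal_category <- function(p, scale = verbal_scale()) {
  stopifnot(all(p >= 0), all(p <= 1))
  idx <- findInterval(p, scale$lower, left.open = FALSE)
  scale$phrase[pmin(idx, nrow(scale))]
}

#' Threshold-shortfall risk surface
#'
#' Converts aligned prediction and PEV grids into the probability that the
#' grain Se concentration falls below the serving-based threshold
#' [rda_threshold()], and codes each cell on the calibrated verbal scale.
#'
#' @param pred_grid `se_grid` of log-scale E-BLUPs.
#' @param pev_grid `se_grid` of log-scale PEVs (same geometry).
#' @param rda Recommended daily allowance (ug/day).
#' @param serving Daily grain serving (g/day).
#' @param scale A [verbal_scale()].
#' @return List of class `se_risk`: `prob` (`se_grid` of probabilities),
#'   `category` (`se_grid` of integer bin codes), `legend` (tibble code /
#'   phrase / bounds), `threshold_mg_kg`, `rda`, `serving`.
#' @export
build_risk_surface <- function(pred_grid, pev_grid, rda = 55, serving = 300,
                               scale = verbal_scale()) {
  if (!grid_same_geometry(pred_grid, pev_grid)) {
    abort("prediction and PEV grids have mismatched geometry")
  }
  thr <- rda_threshold(rda, serving)
  pr <- prob_below(pred_grid$values, pev_grid$values, thr)
  code <- matrix(
    findInterval(pr, scale$lower, left.open = FALSE),
    nrow = nrow(pr)
  )
  code[code > nrow(scale)] <- nrow(scale)
  structure(
    list(
      prob = se_grid(pr, pred_grid$xll, pred_grid$yll, pred_grid$cellsize,
        name = "prob_below_threshold"
      ),
      category = se_grid(code, pred_grid$xll, pred_grid$yll,
        pred_grid$cellsize,
        name = "verbal_category"
      ),
      legend = mutate(scale, code = dplyr::row_number(), .before = 1),
      threshold_mg_kg = thr, rda = rda, serving = serving
    ),
    class = "se_risk"
  )
}

#' @export
print.se_risk <- function(x, ...) {
  cat(
    "Risk surface: P(grain Se <", x$threshold_mg_kg, "mg/kg ) from RDA",
    x$rda, "ug/day over a", x$serving, "g serving\n"
  )
  print(x$prob)
  invisible(x)
}

#' @rdname build_risk_surface
#' @param object An `se_risk`.
#' @param ... Ignored.
#' @export
autoplot.se_risk <- function(object, ...) {
  gt <- grid_to_tibble(object$prob)
  gt$phrase <- factor(
    verbal_category(gt$value, object$legend[, c("lower", "upper", "phrase")]),
    levels = object$legend$phrase
  )
  p1 <- autoplot(object$prob) +
    ggplot2::scale_fill_viridis_c(
      name = "P(below)", limits = c(0, 1), option = "inferno"
    )
  p2 <- ggplot2::ggplot(gt, ggplot2::aes(.data$x_km, .data$y_km,
    fill = .data$phrase
  )) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_d(name = NULL, drop = FALSE) +
    ggplot2::labs(x = "Easting / km", y = "Northing / km") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, ncol = 2)
}
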