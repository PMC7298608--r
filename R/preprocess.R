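#' Moment coefficient of skewness
#'
#' Population (biased, 1/n) moment estimator \eqn{m_3 / m_2^{3/2}}; no
#' small-sample adjustment.
#'
#' @param values Numeric vector, n >= 3, finite, non-constant.
#' @return The skewness coefficient (dimensionless).
#' @examples
#' skewness(c(0, 0, 0, 1)) # 1.155
#' @export
skewness <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 3, all(is.finite(values)))
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) abort("skewness undefined: zero variance")
  mean((values - m)^3) / m2^1.5
}

# Soil properties measured by the survey, in the order they are tabulated.
soil_property_names <- function() {
  c(
    "se_nit", "se_pho", "se_tmah", "ph", "total_oxides", "s_nit",
    "s_tmah", "i_pho", "soc", "oxalate_p", "pbi"
  )
}

# Environmental covariates, in the a-priori testing order.
covariate_names <- function() {
  c(
    "precipitation", "temperature", "slope", "topographic_index", "evi",
    "modis_b7", "modis_b1", "modis_b2", "modis_b4"
  )
}

#' Apply the skewness-based log-transform rule
#'
#' Soil properties whose moment skewness exceeds `threshold` (default 1) are
#' replaced by their natural logarithms; grain Se is always log-transformed.
#' Single pass: a transformed variable is never re-examined or re-logged.
#'
#' @param data Sample table containing the soil property columns (and
#'   optionally `grain_se_mg_kg`).
#' @param properties Columns to examine; defaults to the 11 measured soil
#'   properties present in `data`.
#' @param threshold Skewness above which a property is logged.
#' @return The transformed table, with a `transform_report` attribute (also
#'   retrievable with [transform_report()]): a tibble (variable, skewness,
#'   transformed, transform).
#' @export
apply_transform_rule <- function(data, properties = NULL, threshold = 1) {
  if (is.null(properties)) {
    properties <- intersect(soil_property_names(), names(data))
  }
  stopifnot(all(properties %in% names(data)))
  report <- purrr::map_dfr(properties, function(v) {
    sk <- skewness(data[[v]])
    tibble(
      variable = v, skewness = sk, transformed = sk > threshold,
      transform = if (sk > threshold) "natural log" else "none"
    )
  })
  out <- data
  for (v in report$variable[report$transformed]) {
    if (any(out[[v]] <= 0)) {
      abort(paste0(
        "variable '", v, "' selected for log transform has non-positive values"
      ))
    }
    out[[v]] <- log(out[[v]])
  }
  if ("grain_se_mg_kg" %in% names(out)) {
    if (any(out$grain_se_mg_kg <= 0, na.rm = TRUE)) {
      abort("grain Se must be positive for the log transform")
    }
    out$log_grain_se <- log(out$grain_se_mg_kg)
    report <- bind_rows(report, tibble(
      variable = "grain_se_mg_kg",
      skewness = skewness(out$grain_se_mg_kg[is.finite(out$grain_se_mg_kg)]),
      transformed = TRUE, transform = "natural log"
    ))
  }
  attr(out, "transform_report") <- report
  out
}

#' @rdname apply_transform_rule
#' @export
transform_report <- function(data) {
  rep <- attr(data, "transform_report")
  if (is.null(rep)) abort("no transform report attached; run apply_transform_rule()")
  rep
}

#' Phosphorus buffer index
#'
#' Single-addition phosphorus buffer index
#' \deqn{PBI = (P_s + 4.59\,P_{Olsen}) / P_c^{0.41},}
#' where \eqn{P_s} is sorbed P (mg P/kg soil), \eqn{P_{Olsen}} the
#' bicarbonate-extractable P (mg P/kg) and \eqn{P_c} the final solution P
#' concentration (mg P/L).
#'
#' @param p_sorbed,p_olsen Non-negative, mg P/kg.
#' @param p_solution Positive, mg P/L.
#' @return PBI (dimensionless); vectorised.
#' @export
pbi <- function(p_sorbed, p_olsen, p_solution) {
  if (any(p_solution <= 0)) abort("p_solution must be positive")
  stopifnot(all(p_sorbed >= 0), all(p_olsen >= 0))
  (p_sorbed + 4.59 * p_olsen) / p_solution^0.41
}

#' Grain-concentration threshold equivalent to a daily allowance
#'
#' The grain Se concentration below which a fixed daily serving fails to
#' supply the recommended daily allowance: `rda / serving`, converted to
#' mg/kg and reported to 3 decimal places.  The defaults (55 ug/day from a
#' 300 g serving) give the 0.183 mg/kg threshold used for the risk maps.
#'
#' @param rda Recommended daily allowance, ug/day.
#' @param serving Daily serving, g/day (> 0).
#' @return Threshold concentration in mg/kg.
#' @examples
#' rda_threshold(55, 300) # 0.183
#' @export
rda_threshold <- function(rda = 55, serving = 300) {
  if (any(serving <= 0)) abort("serving must be positive")
  stopifnot(all(rda >= 0))
  # ug/day over g/day is ug/g == mg/kg
  round(rda / serving, 3)
}
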