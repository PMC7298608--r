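#' Run the full grain-Se mapping pipeline on a survey
#'
#' Orchestrates the complete analysis: log-transform rule, soil predictor
#' selection under marginal FDR control, construction of the
#' soil-predicted variable, covariate selection, factorial-kriging
#' decomposition + component filtering of the selected covariates, Matern
#' smoothness profiling, the final trivariate REML fit, leave-one-out
#' cross-validation (ordinary kriging and E-BLUP), grid prediction, and
#' the threshold-shortfall risk surface.  Every stage writes plain-text
#' artifacts (CSV / ESRI ASCII) into `out_dir` and appends a manifest
#' record with the stage name, seed and md5 hashes of its outputs.  When
#' `resume = TRUE`, stages whose artifact files already exist are skipped.
#'
#' @param survey An `se_survey` from [assemble_survey()], or a sample-site
#'   tibble plus `grids` given separately.
#' @param out_dir Output directory (created if needed).
#' @param target_crop "teff" or "wheat".
#' @param soil_order,covariate_order A-priori testing orders; defaults to
#'   the standard survey orderings.
#' @param skew_threshold Log-transform rule threshold.
#' @param w0,payout Alpha-investing parameters.
#' @param kappa_grid Smoothness profile grid.
#' @param rda,serving Risk threshold provenance (ug/day, g/day).
#' @param refit_each Re-estimate covariance at each selection step (see
#'   [select_predictors()]).
#' @param starts,maxit Optimizer effort for each fit.
#' @param seed Seed recorded in the manifest (selection and fitting are
#'   deterministic; the seed feeds the cross-validation reference
#'   interval).
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_se_pipeline <- function(survey, out_dir, target_crop = "teff",
                            soil_order = soil_property_names(),
                            covariate_order = covariate_names(),
                            skew_threshold = 1, w0 = 0.05, payout = 0.05,
                            kappa_grid = c(0.25, 0.5, 1, 1.5, 2, 3),
                            rda = 55, serving = 300, refit_each = TRUE,
                            starts = 3, maxit = 400, seed = 1L) {
  stopifnot(inherits(survey, "se_survey"))
  sites <- survey$sites
  grids <- survey$grids
  if (!all(soil_order %in% names(sites))) {
    abort(paste(
      "unknown soil labels:",
      paste(setdiff(soil_order, names(sites)), collapse = ", ")
    ))
  }
  if (!all(covariate_order %in% names(grids))) {
    abort(paste(
      "unknown covariate labels:",
      paste(setdiff(covariate_order, names(grids)), collapse = ", ")
    ))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path)) unlink(manifest_path)
  results <- list()

  # Each record carries the hash of the manifest so far, forming a chain:
  # tampering with any earlier artifact or record breaks every later link.
  log_stage <- function(stage, files) {
    prev <- if (file.exists(manifest_path)) {
      unname(tools::md5sum(manifest_path))
    } else {
      "none"
    }
    hashes <- tools::md5sum(file.path(out_dir, files))
    names(hashes) <- files
    rec <- list(stage = stage, seed = seed, prev = prev,
                files = as.list(hashes))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = manifest_path, append = TRUE, sep = ""
    )
  }

  # 1 -- transform ---------------------------------------------------------
  trans <- apply_transform_rule(sites, soil_order, threshold = skew_threshold)
  rep_tbl <- transform_report(trans)
  f <- "transform_report.csv"
  readr::write_csv(rep_tbl, file.path(out_dir, f))
  log_stage("transform", f)
  results$transform <- rep_tbl

  # 2 -- soil predictor selection -----------------------------------------
  st1 <- stack_from_survey(trans, target_crop, carry = soil_order)
  sel_soil <- select_predictors(st1[st1$var == 1L, ], soil_order,
    w0 = w0, payout = payout, refit_each = refit_each,
    starts = starts, maxit = maxit
  )
  f <- "soil_selection_ledger.csv"
  readr::write_csv(sel_soil$ledger, file.path(out_dir, f))
  log_stage("select_soil", f)
  results$soil_selection <- sel_soil

  # 3 -- soil-predicted grain Se (y3) --------------------------------------
  y3 <- predict_from_soil(sel_soil$fit, trans)
  f <- "soil_predicted_log_se.csv"
  readr::write_csv(
    tibble(site_id = trans$site_id, y3_log = y3),
    file.path(out_dir, f)
  )
  log_stage("predict_soil", f)
  results$y3 <- y3

  # 4 -- covariate selection ----------------------------------------------
  st1c <- stack_from_survey(trans, target_crop, carry = covariate_order)
  sel_cov <- select_predictors(st1c[st1c$var == 1L, ], covariate_order,
    w0 = w0, payout = payout, refit_each = refit_each,
    starts = starts, maxit = maxit
  )
  f <- "covariate_selection_ledger.csv"
  readr::write_csv(sel_cov$ledger, file.path(out_dir, f))
  log_stage("select_covariates", f)
  results$covariate_selection <- sel_cov

  # 5 -- factorial kriging of selected covariates + component filtering ----
  comp_cols <- character(0)
  comp_grids <- list()
  site_comp <- tibble(site_id = trans$site_id)
  for (nm in sel_cov$selected) {
    dec <- fka_decompose(grids[[nm]])
    for (side in c("short", "long")) {
      cn <- paste0(nm, "__", side)
      comp_grids[[cn]] <- dec[[side]]
      site_comp[[cn]] <- extract_at(dec[[side]], trans$x_km, trans$y_km)
      comp_cols <- c(comp_cols, cn)
      write_esri_ascii(dec[[side]], file.path(out_dir, paste0(cn, ".asc")))
    }
    results$fka[[nm]] <- dec$model
  }
  trans2 <- left_join(trans, site_comp, by = "site_id")
  # a constant y3 (no soil predictor selected) carries no information and
  # would make the third variable degenerate; fall back to two variables
  use_y3 <- length(sel_soil$selected) > 0
  if (!use_y3) {
    inform("no soil predictors selected: fitting without the soil-predicted variable")
  }
  stack3 <- stack_from_survey(trans2, target_crop,
    y3 = if (use_y3) y3 else NULL, carry = comp_cols
  )
  if (length(comp_cols) > 0) {
    filt <- filter_components(stack3, comp_cols,
      starts = starts, maxit = maxit
    )
    retained <- filt$retained
  } else {
    retained <- character(0)
  }
  f <- "retained_components.csv"
  readr::write_csv(
    tibble(component = comp_cols, retained = comp_cols %in% retained),
    file.path(out_dir, f)
  )
  log_stage("fka_filter", c(f, paste0(comp_cols, ".asc", recycle0 = TRUE)))
  results$retained_components <- retained

  # 6 -- kappa profile ------------------------------------------------------
  fixed_final <- list(`1` = retained)
  prof <- profile_kappa(stack3, fixed_final,
    kappa_grid = kappa_grid,
    starts = starts, maxit = maxit
  )
  f <- "kappa_profile.csv"
  readr::write_csv(prof$profile, file.path(out_dir, f))
  log_stage("kappa_profile", f)
  results$kappa_profile <- prof

  # 7 -- final trivariate REML fit -----------------------------------------
  fit <- fit_lmm(stack3, fixed_final,
    method = "REML", kappa = prof$best_kappa,
    starts = starts, maxit = maxit,
    init = prof$fits[[which(prof$profile$kappa == prof$best_kappa)]]$coreg
  )
  f <- "final_fit_coefficients.csv"
  readr::write_csv(tidy(fit), file.path(out_dir, f))
  log_stage("fit", f)
  results$fit <- fit

  # 8 -- cross-validation ---------------------------------------------------
  cv_eblup <- loocv(fit, "EBLUP", interval_seed = seed)
  cv_ok <- loocv(fit, "OK", interval_seed = seed)
  f <- c("crossval_eblup.csv", "crossval_ok.csv", "crossval_summary.csv")
  readr::write_csv(as_tibble(cv_eblup), file.path(out_dir, f[1]))
  readr::write_csv(as_tibble(cv_ok), file.path(out_dir, f[2]))
  readr::write_csv(
    bind_rows(glance(cv_eblup), glance(cv_ok)),
    file.path(out_dir, f[3])
  )
  log_stage("crossval", f)
  results$crossval <- list(eblup = cv_eblup, ok = cv_ok)

  # 9 -- grid prediction -----------------------------------------------------
  g0 <- grids[[1]]
  targets <- grid_to_tibble(g0)[, c("x_km", "y_km")]
  for (cn in retained) {
    targets[[cn]] <- extract_at(comp_grids[[cn]], targets$x_km, targets$y_km)
  }
  pred <- eblup_predict(fit, targets, hull_warn = FALSE)
  to_grid <- function(v, name) {
    se_grid(matrix(v, nrow = nrow(g0$values)), g0$xll, g0$yll, g0$cellsize,
      name = name
    )
  }
  pred_grid <- to_grid(pred$eblup_log, "eblup_log")
  pev_grid <- to_grid(pred$pev_log, "pev_log")
  med_grid <- to_grid(pred$median_mg_kg, "median_mg_kg")
  f <- c("eblup_log.asc", "pev_log.asc", "median_mg_kg.asc")
  write_esri_ascii(pred_grid, file.path(out_dir, f[1]))
  write_esri_ascii(pev_grid, file.path(out_dir, f[2]))
  write_esri_ascii(med_grid, file.path(out_dir, f[3]))
  log_stage("predict", f)
  results$prediction <- list(
    eblup = pred_grid, pev = pev_grid, median = med_grid
  )

  # 10 -- risk surface --------------------------------------------------------
  risk <- build_risk_surface(pred_grid, pev_grid, rda = rda, serving = serving)
  f <- c("prob_below_threshold.asc", "verbal_category.asc", "verbal_legend.csv")
  write_esri_ascii(risk$prob, file.path(out_dir, f[1]))
  write_esri_ascii(risk$category, file.path(out_dir, f[2]))
  readr::write_csv(risk$legend, file.path(out_dir, f[3]))
  log_stage("riskmap", f)
  results$risk <- risk

  invisible(results)
}
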