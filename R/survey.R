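#' Configuration of a synthetic soil--crop survey
#'
#' Bundles every knob of the synthetic survey generator.  The defaults are
#' the study conditions the analysis is exercised under: 475 primary sites
#' spread over a 400 x 300 km frame of 0.5-km grid nodes (the scale of a
#' regional soil-crop survey), 25 close-pair
#' sites 100--1000 m from spread primaries, one crop (teff or wheat)
#' observed per site with equal probability, log-normal right-skewed soil
#' properties, crop grain Se generated from a handful of true soil
#' predictors plus the long-range component of precipitation, and
#' mutually correlated Matern (kappa = 2, phi = 15 km) spatial crop
#' effects with structurally uncorrelated nuggets.
#'
#' @param frame_km Width and height of the rectangular frame (km).
#' @param spacing_km Sampling-frame grid node spacing (km).
#' @param n_primary Number of primary sites.
#' @param n_close_pairs Number of close-pair augmentation sites.
#' @param pair_bounds_m Lower/upper close-pair distance bounds (m).
#' @param teff_fraction Probability a site grows teff (otherwise wheat).
#' @param kappa,phi True Matern parameters of all spatial components.
#' @param coreg True crop-effect coregionalization (2 variables:
#'   teff, wheat).  Defaults to [default_survey_coreg()].
#' @param soil True soil-property generative parameters (see
#'   [default_soil_params()]).
#' @param soil_coef True fixed-effect coefficients per crop, on the
#'   analysis (transformed) scale; unlisted properties are null predictors.
#' @param covariates True covariate generative parameters (see
#'   [default_covariate_params()]).
#' @param covariate_coef True coefficients per crop applied to the
#'   *long-range component* of the named covariates.
#' @param grid_cell_km Covariate grid cell size (km).
#' @param seed Integer seed; every random draw in the generator flows
#'   from it.
#' @return A `se_survey_config` list.
#' @export
survey_config <- function(frame_km = c(400, 300),
                          spacing_km = 0.5,
                          n_primary = 475,
                          n_close_pairs = 25,
                          pair_bounds_m = c(100, 1000),
                          teff_fraction = 0.5,
                          kappa = 2,
                          phi = 15,
                          coreg = default_survey_coreg(),
                          soil = default_soil_params(),
                          soil_coef = default_soil_coef(),
                          covariates = default_covariate_params(),
                          covariate_coef = default_covariate_coef(),
                          grid_cell_km = 10,
                          seed = 1L) {
  stopifnot(
    length(frame_km) == 2, all(frame_km > 0), spacing_km > 0,
    n_primary > 0, n_close_pairs >= 0,
    length(pair_bounds_m) == 2, pair_bounds_m[1] > 0,
    pair_bounds_m[1] < pair_bounds_m[2],
    teff_fraction > 0, teff_fraction < 1,
    kappa > 0, phi > 0, grid_cell_km > 0
  )
  structure(
    list(
      frame_km = frame_km, spacing_km = spacing_km, n_primary = n_primary,
      n_close_pairs = n_close_pairs, pair_bounds_m = pair_bounds_m,
      teff_fraction = teff_fraction, kappa = kappa, phi = phi,
      coreg = coreg, soil = soil, soil_coef = soil_coef,
      covariates = covariates, covariate_coef = covariate_coef,
      grid_cell_km = grid_cell_km, seed = as.integer(seed)
    ),
    class = "se_survey_config"
  )
}

#' Default coregionalization truths of the synthetic survey
#'
#' The bivariate form (default) drives the crop spatial effects of the
#' generator; the trivariate form adds a third, soil-predicted, variable
#' and is the truth used for multivariate parameter-recovery experiments.
#' Correlation structure: nugget correlations 0 (teff--wheat, structural:
#' the crops are never co-located), 0.43 and 0.20; spatially correlated
#' correlations 0.44, 0.52, 0.42; nugget variances 0.62, 0.92, 0.21 and
#' correlated variances 0.39, 0.54, 0.25 on the log scale.
#'
#' @param trivariate Include the third (soil-prediction) variable?
#' @param kappa,phi Matern parameters.
#' @return An `se_coreg`.
#' @export
default_survey_coreg <- function(trivariate = FALSE, kappa = 2, phi = 15) {
  if (!trivariate) {
    return(coregionalization(
      T = diag(c(0.62, 0.92)),
      S = outer(sqrt(c(0.39, 0.54)), sqrt(c(0.39, 0.54))) *
        matrix(c(1, 0.44, 0.44, 1), 2),
      kappa = kappa, phi = phi,
      nugget_zero = cbind(c(1, 2), c(2, 1))
    ))
  }
  tau <- sqrt(c(0.62, 0.92, 0.21))
  sig <- sqrt(c(0.39, 0.54, 0.25))
  Rt <- matrix(c(
    1, 0, 0.43,
    0, 1, 0.20,
    0.43, 0.20, 1
  ), 3, byrow = TRUE)
  Rs <- matrix(c(
    1, 0.44, 0.52,
    0.44, 1, 0.42,
    0.52, 0.42, 1
  ), 3, byrow = TRUE)
  coregionalization(
    T = outer(tau, tau) * Rt,
    S = outer(sig, sig) * Rs,
    kappa = kappa, phi = phi,
    nugget_zero = cbind(c(1, 2), c(2, 1))
  )
}

#' @rdname survey_config
#' @export
default_soil_params <- function() {
  # dist: generation scale; spatial_share: fraction of (log-scale) variance
  # carried by a Matern spatial component.  Log-normal properties are the
  # ones whose marginal skewness exceeds 1, so the transform rule has true
  # positives; the remainder are near-symmetric.
  list(
    se_nit = list(dist = "lognormal", meanlog = 0.77, sdlog = 0.55, spatial_share = 0.5),
    se_pho = list(dist = "lognormal", meanlog = 1.61, sdlog = 0.44, spatial_share = 0.5),
    se_tmah = list(dist = "normal", mean = 272.9, sd = 100, floor = 5, spatial_share = 0.3),
    ph = list(dist = "normal", mean = 6.74, sd = 0.92, spatial_share = 0.5),
    total_oxides = list(dist = "normal", mean = 13470, sd = 4500, floor = 100, spatial_share = 0.3),
    s_nit = list(dist = "normal", mean = 37.9, sd = 11, floor = 0.5, spatial_share = 0.3),
    s_tmah = list(dist = "lognormal", meanlog = 1.56, sdlog = 0.63, spatial_share = 0.3),
    i_pho = list(dist = "lognormal", meanlog = 4.94, sdlog = 0.75, spatial_share = 0.5),
    soc = list(dist = "normal", mean = 1.46, sd = 0.55, floor = 0.05, spatial_share = 0.3),
    oxalate_p = list(dist = "lognormal", meanlog = 5.85, sdlog = 1.14, spatial_share = 0.3),
    pbi = list(dist = "lognormal", meanlog = 3.66, sdlog = 0.59, spatial_share = 0.3)
  )
}

#' @rdname survey_config
#' @export
default_soil_coef <- function() {
  # Coefficients on the analysis scale (log for the log-normal properties).
  # Properties absent from a crop's list are true nulls for that crop.
  list(
    teff = c(
      `(Intercept)` = -2.82, se_nit = 0.924, se_pho = -0.221,
      ph = 0.316, i_pho = -0.496
    ),
    wheat = c(`(Intercept)` = -6.66, se_tmah = -0.001, ph = 0.546)
  )
}

#' @rdname survey_config
#' @export
default_covariate_params <- function() {
  base <- function(mean, sd) {
    list(
      mean = mean, sd = sd, share_long = 0.6, share_short = 0.3,
      range_long = 30, range_short = 3, family = "exponential"
    )
  }
  list(
    precipitation = base(1100, 150),
    temperature = base(18, 2),
    slope = base(5, 2.5),
    topographic_index = base(8, 2),
    evi = base(0.35, 0.08),
    modis_b7 = base(0.25, 0.05),
    modis_b1 = base(0.12, 0.04),
    modis_b2 = base(0.3, 0.06),
    modis_b4 = base(0.1, 0.03)
  )
}

#' @rdname survey_config
#' @export
default_covariate_coef <- function() {
  # Applied to the zero-mean long-range component of each named covariate;
  # covariates absent from a crop's list are true nulls (the wheat model
  # mirrors the no-covariates-selected outcome).
  list(teff = c(precipitation = -0.0037), wheat = numeric(0))
}

#' Spatially stratified survey design with close pairs
#'
#' Approximates a spatially balanced design: the frame's grid nodes are
#' stratified into `n_primary` roughly equal-area cells and one node is
#' drawn uniformly per cell.  `n_close_pairs` primaries, themselves chosen
#' for spread, each receive a companion site placed uniformly at random in
#' the annulus between the configured distance bounds.
#'
#' @param config A [survey_config()].
#' @return Tibble (site_id, x_km, y_km, is_close_pair, pair_of);
#'   deterministic given `config$seed`.
#' @export
draw_design <- function(config) {
  stopifnot(inherits(config, "se_survey_config"))
  W <- config$frame_km[1]
  H <- config$frame_km[2]
  sp <- config$spacing_km
  nx <- floor(W / sp)
  ny <- floor(H / sp)
  if (nx * ny < config$n_primary) {
    abort("frame too small: fewer grid nodes than primary sites requested")
  }
  with_seed(config$seed, {
    # stratification into ~equal-area cells, row-major from the south-west
    ncell_x <- max(1, round(sqrt(config$n_primary * W / H)))
    ncell_y <- ceiling(config$n_primary / ncell_x)
    total <- ncell_x * ncell_y
    drop_k <- total - config$n_primary
    keep <- rep(TRUE, total)
    if (drop_k > 0) {
      # drop surplus cells evenly across the row-major order to keep spread
      keep[round(seq(1, total, length.out = drop_k + 2))[2:(drop_k + 1)]] <- FALSE
    }
    cw <- W / ncell_x
    ch <- H / ncell_y
    pts <- matrix(NA_real_, config$n_primary, 2)
    j <- 0
    for (cell in seq_len(total)) {
      if (!keep[cell]) next
      cy <- (cell - 1) %/% ncell_x
      cx <- (cell - 1) %% ncell_x
      # grid nodes (cell-centre registered at spacing sp) inside this cell
      ix_lo <- ceiling(cx * cw / sp + 0.5)
      ix_hi <- floor((cx + 1) * cw / sp + 0.5)
      iy_lo <- ceiling(cy * ch / sp + 0.5)
      iy_hi <- floor((cy + 1) * ch / sp + 0.5)
      ix_hi <- min(ix_hi, nx)
      iy_hi <- min(iy_hi, ny)
      if (ix_hi < ix_lo || iy_hi < iy_lo) {
        abort("frame too small: a stratum contains no grid node")
      }
      ix <- if (ix_hi > ix_lo) sample(ix_lo:ix_hi, 1) else ix_lo
      iy <- if (iy_hi > iy_lo) sample(iy_lo:iy_hi, 1) else iy_lo
      j <- j + 1
      pts[j, ] <- c((ix - 0.5) * sp, (iy - 0.5) * sp)
    }
    primary <- tibble(
      site_id = sprintf("P%03d", seq_len(config$n_primary)),
      x_km = pts[, 1], y_km = pts[, 2],
      is_close_pair = FALSE, pair_of = NA_character_
    )
    if (config$n_close_pairs == 0) {
      return(primary)
    }
    # spread subset of primaries gets a close companion
    anchor_idx <- unique(round(seq(1, config$n_primary,
      length.out = config$n_close_pairs
    )))
    k <- 1
    while (length(anchor_idx) < config$n_close_pairs) {
      anchor_idx <- union(anchor_idx, k)
      k <- k + 1
    }
    anchor_idx <- sort(anchor_idx)[seq_len(config$n_close_pairs)]
    lo <- config$pair_bounds_m[1] / 1000
    up <- config$pair_bounds_m[2] / 1000
    cp <- purrr::map_dfr(seq_along(anchor_idx), function(i) {
      a <- primary[anchor_idx[i], ]
      repeat {
        r <- sqrt(runif(1, lo^2, up^2)) # uniform over the annulus area
        th <- runif(1, 0, 2 * pi)
        x <- a$x_km + r * cos(th)
        y <- a$y_km + r * sin(th)
        if (x >= 0 && x <= W && y >= 0 && y <= H) break
      }
      tibble(
        site_id = sprintf("C%03d", i), x_km = x, y_km = y,
        is_close_pair = TRUE, pair_of = a$site_id
      )
    })
    bind_rows(primary, cp)
  })
}

#' Within-plot sub-sample layout
#'
#' Offsets (m) of the five sub-sample points of the 100-m2 circular field
#' plot: the plot centre, two points on the long axis (along the crop
#' rows) on the circumferences of the 100-m2 and 75-m2 concentric
#' subplots, and two on the orthogonal short axis on the 25-m2 and 50-m2
#' circumferences.  Radii are reported to 2 decimal places (5.64, 4.89,
#' 2.82, 3.99 m).
#'
#' @return Tibble (point, axis, dx_m, dy_m, radius_m).
#' @export
plot_layout <- function() {
  r100 <- round(sqrt(100 / pi), 2)
  r75 <- round(sqrt(75 / pi), 2)
  r25 <- round(sqrt(25 / pi), 2)
  r50 <- round(sqrt(50 / pi), 2)
  tibble(
    point = c("centre", "long_outer", "long_inner", "short_inner", "short_outer"),
    axis = c("none", "long", "long", "short", "short"),
    dx_m = c(0, r100, -r75, 0, 0),
    dy_m = c(0, 0, 0, r25, -r50),
    radius_m = c(0, r100, r75, r25, r50)
  )
}

#' Draw correlated multivariate Gaussian fields at point locations
#'
#' One joint draw of the `p` zero-mean variables of a coregionalization at
#' `n` locations, with covariance exactly as assembled by
#' [build_joint_cov()] (each location is treated as a distinct site, so
#' nugget components are shared across variables within a location but not
#' between locations).
#'
#' @param coords Two-column matrix/data frame of coordinates (km).
#' @param coreg An `se_coreg`.
#' @param seed Optional integer seed.
#' @return n x p matrix of field values.
#' @export
simulate_fields <- function(coords, coreg, seed = NULL) {
  validate_coreg(coreg)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  p <- coreg$p
  with_seed(seed, {
    out <- matrix(0, n, p)
    if (any(coreg$S != 0)) {
      R <- matern_corr(as.matrix(dist(coords)), coreg$kappa, coreg$phi)
      Lr <- t(chol_jitter(R))
      out <- out + Lr %*% matrix(rnorm(n * p), n, p) %*% mat_sqrt(coreg$S)
    }
    if (any(coreg$T != 0)) {
      out <- out + matrix(rnorm(n * p), n, p) %*% mat_sqrt(coreg$T)
    }
    out
  })
}

# Zero-mean Gaussian field with unit variance and the given correlation
# family, drawn jointly at `coords`; a plain workhorse for grids.
sim_unit_field <- function(coords, range_km, family = "exponential",
                           kappa = 2, chol_cache = NULL) {
  key <- paste(family, range_km, kappa, sep = "_")
  if (!is.null(chol_cache) && !is.null(chol_cache[[key]])) {
    Lr <- chol_cache[[key]]
  } else {
    D <- as.matrix(dist(coords))
    R <- switch(family,
      exponential = exp(-D / range_km),
      spherical = ifelse(D < range_km,
        1 - 1.5 * D / range_km + 0.5 * (D / range_km)^3, 0
      ),
      matern = matern_corr(D, kappa, range_km),
      abort("unknown correlation family")
    )
    Lr <- t(chol_jitter(R))
    if (!is.null(chol_cache)) chol_cache[[key]] <- Lr
  }
  as.vector(Lr %*% rnorm(nrow(Lr)))
}

#' Assemble a complete synthetic survey
#'
#' Composes the design, soil-property fields, covariate grids and grain Se
#' responses into one coherent synthetic survey.  Each site observes one
#' crop; its log grain Se is a linear function of the true (transformed)
#' soil predictors and of the long-range components of the true covariates,
#' plus the crop's spatially correlated effect and nugget.  Soil properties
#' and covariates with zero true coefficient are included so downstream
#' selection faces genuine null hypotheses.
#'
#' @param config A [survey_config()].
#' @return An `se_survey` list: `sites` (tibble: site_id, x_km, y_km, crop,
#'   close_pair, grain_se_mg_kg, 11 soil columns, covariate columns),
#'   `grids` (named list of `se_grid` covariate surfaces), `components`
#'   (named list with true `long`/`short` component grids per covariate)
#'   and `truth` (all generating parameters).
#' @export
assemble_survey <- function(config = survey_config()) {
  stopifnot(inherits(config, "se_survey_config"))
  design <- draw_design(config)
  n <- nrow(design)
  coords <- cbind(design$x_km, design$y_km)

  with_seed(config$seed + 1000L, {
    crop <- ifelse(runif(n) < config$teff_fraction, "teff", "wheat")
  })

  # --- covariate grids: mean + long-range + short-range + white noise ----
  nxc <- max(1, round(config$frame_km[1] / config$grid_cell_km))
  nyc <- max(1, round(config$frame_km[2] / config$grid_cell_km))
  gx <- (rep(seq_len(nxc), each = nyc) - 0.5) * config$grid_cell_km
  gy <- (rep(seq_len(nyc), times = nxc) - 0.5) * config$grid_cell_km
  gcoords <- cbind(gx, gy)
  to_grid <- function(v, name) {
    m <- matrix(v, nrow = nyc, ncol = nxc) # column-major: south-up
    se_grid(m[nyc:1, , drop = FALSE],
      xll = 0, yll = 0,
      cellsize = config$grid_cell_km, name = name
    )
  }
  chol_cache <- new.env()
  grids <- list()
  components <- list()
  cov_site <- list()
  cov_long_site <- list()
  for (ci in seq_along(config$covariates)) {
    nm <- names(config$covariates)[ci]
    cp <- config$covariates[[nm]]
    with_seed(config$seed + 2000L + ci, {
      f_long <- sim_unit_field(gcoords, cp$range_long, cp$family,
        chol_cache = chol_cache
      )
      f_short <- sim_unit_field(gcoords, cp$range_short, cp$family,
        chol_cache = chol_cache
      )
      noise <- rnorm(nrow(gcoords))
    })
    share_noise <- max(0, 1 - cp$share_long - cp$share_short)
    long_v <- cp$sd * sqrt(cp$share_long) * f_long
    short_v <- cp$sd * sqrt(cp$share_short) * f_short
    full_v <- cp$mean + long_v + short_v + cp$sd * sqrt(share_noise) * noise
    grids[[nm]] <- to_grid(full_v, nm)
    components[[nm]] <- list(
      long = to_grid(long_v, paste0(nm, "__long")),
      short = to_grid(short_v, paste0(nm, "__short"))
    )
    cov_site[[nm]] <- extract_at(grids[[nm]], design$x_km, design$y_km)
    cov_long_site[[nm]] <- extract_at(
      components[[nm]]$long, design$x_km, design$y_km
    )
  }

  # --- soil properties: spatial + independent parts on generation scale --
  log_props <- names(which(vapply(
    config$soil, function(s) s$dist == "lognormal", TRUE
  )))
  soil_vals <- list()
  for (si in seq_along(config$soil)) {
    nm <- names(config$soil)[si]
    sp <- config$soil[[nm]]
    with_seed(config$seed + 3000L + si, {
      f <- sim_unit_field(coords, config$phi, "matern", kappa = config$kappa)
      e <- rnorm(n)
    })
    z <- sqrt(sp$spatial_share) * f + sqrt(1 - sp$spatial_share) * e
    soil_vals[[nm]] <- if (sp$dist == "lognormal") {
      exp(sp$meanlog + sp$sdlog * z)
    } else {
      v <- sp$mean + sp$sd * z
      if (!is.null(sp$floor)) v <- pmax(v, sp$floor)
      v
    }
  }

  # --- crop effects and responses -----------------------------------------
  eff <- simulate_fields(coords, config$coreg, seed = config$seed + 4000L)
  lp <- numeric(n)
  for (cr in c("teff", "wheat")) {
    idx <- crop == cr
    co <- config$soil_coef[[cr]]
    v <- rep(unname(co["(Intercept)"]), sum(idx))
    for (nm in setdiff(names(co), "(Intercept)")) {
      x <- soil_vals[[nm]][idx]
      if (nm %in% log_props) x <- log(x)
      v <- v + co[[nm]] * x
    }
    cc <- config$covariate_coef[[cr]]
    for (nm in names(cc)) {
      v <- v + cc[[nm]] * cov_long_site[[nm]][idx]
    }
    vi <- if (cr == "teff") 1 else 2
    lp[idx] <- v + eff[idx, vi]
  }

  sites <- dplyr::bind_cols(
    tibble(
      site_id = design$site_id, x_km = design$x_km, y_km = design$y_km,
      crop = crop, close_pair = design$is_close_pair,
      grain_se_mg_kg = exp(lp)
    ),
    as_tibble(soil_vals),
    as_tibble(cov_site)
  )

  structure(
    list(
      sites = sites, grids = grids, components = components,
      truth = list(
        coreg = config$coreg, soil_coef = config$soil_coef,
        covariate_coef = config$covariate_coef, kappa = config$kappa,
        phi = config$phi, log_soil_properties = log_props,
        crop_effects = eff, linear_predictor = lp,
        pair_of = design$pair_of
      ),
      config = config
    ),
    class = "se_survey"
  )
}

#' @export
print.se_survey <- function(x, ...) {
  cat(
    "Synthetic soil-crop survey:", nrow(x$sites), "sites (",
    sum(!x$sites$close_pair), "primary +", sum(x$sites$close_pair),
    "close pairs ),", length(x$grids), "covariate grids\n"
  )
  invisible(x)
}
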