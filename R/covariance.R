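#' Matern spatial correlation
#'
#' The two-parameter Matern correlation function
#' \deqn{\rho(h) = \frac{2^{1-\kappa}}{\Gamma(\kappa)}
#'   \left(\frac{h}{\phi}\right)^{\kappa} K_\kappa(h/\phi),}
#' where \eqn{K_\kappa} is the modified Bessel function of the second kind.
#' \eqn{\kappa} controls smoothness of the underlying spatial process and
#' \eqn{\phi} (in km) its distance scale.  Distance enters as \eqn{h/\phi}
#' with no \eqn{\sqrt{2\kappa}} rescaling, so fitted \eqn{\phi} values are
#' comparable across \eqn{\kappa} only qualitatively.
#'
#' @param h Non-negative distances (km); vectorised.
#' @param kappa Smoothness parameter, > 0.
#' @param phi Distance parameter (km), > 0.
#' @return Correlations in (0, 1]; exactly 1 at `h = 0`.
#' @examples
#' matern_corr(15, kappa = 0.5, phi = 15) # exp(-1)
#' @export
matern_corr <- function(h, kappa, phi) {
  stopifnot(kappa > 0, phi > 0, all(h >= 0))
  u <- h / phi
  out <- numeric(length(u))
  # Bessel underflow guard: treat tiny scaled distances as zero lag.
  tiny <- u < 1e-10
  out[tiny] <- 1
  if (any(!tiny)) {
    uu <- u[!tiny]
    # closed forms at half-integer smoothness (identical to the Bessel
    # expression, but much cheaper)
    v <- if (kappa == 0.5) {
      exp(-uu)
    } else if (kappa == 1.5) {
      (1 + uu) * exp(-uu)
    } else if (kappa == 2.5) {
      (1 + uu + uu^2 / 3) * exp(-uu)
    } else {
      2^(1 - kappa) / gamma(kappa) * uu^kappa * besselK(uu, kappa)
    }
    v[!is.finite(v)] <- 0 # far beyond the range K_kappa underflows to 0
    out[!tiny] <- v
  }
  dim(out) <- dim(h)
  out
}

#' Linear model of coregionalization
#'
#' Bundle the covariance structure shared by `p` co-varying variables: a
#' nugget covariance matrix `T` (spatially uncorrelated components, possibly
#' mutually correlated), a spatially correlated covariance matrix `S`, and a
#' single shared Matern correlation.  Pairs of variables that are never
#' co-located (e.g. Se in teff and in wheat grain, observed on disjoint
#' sites) can carry a structural zero in `T` via `nugget_zero`.
#'
#' @param T Nugget covariance matrix (p x p, symmetric PSD).
#' @param S Spatially correlated covariance matrix (p x p, symmetric PSD).
#' @param kappa,phi Matern parameters shared by all variables.
#' @param nugget_zero Two-column matrix (or NULL) of variable-index pairs
#'   whose nugget covariance is structurally zero.
#' @return An object of class `se_coreg`.
#' @export
coregionalization <- function(T, S, kappa, phi, nugget_zero = NULL) {
  T <- as.matrix(T)
  S <- as.matrix(S)
  obj <- structure(
    list(
      p = nrow(T), T = T, S = S, kappa = kappa, phi = phi,
      nugget_zero = nugget_zero
    ),
    class = "se_coreg"
  )
  validate_coreg(obj)
  obj
}

validate_coreg <- function(cg, tol = 1e-10) {
  if (!inherits(cg, "se_coreg")) abort("not a coregionalization object")
  p <- cg$p
  for (nm in c("T", "S")) {
    M <- cg[[nm]]
    if (!is.matrix(M) || any(dim(M) != p)) {
      abort(paste0("matrix ", nm, " must be ", p, " x ", p))
    }
    if (max(abs(M - t(M))) > 1e-8) abort(paste0(nm, " is not symmetric"))
    if (any(diag(M) < 0)) abort(paste0(nm, " has a negative variance"))
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -tol) {
      abort(paste0(nm, " is not positive semi-definite"))
    }
  }
  if (!is.null(cg$nugget_zero)) {
    nz <- as.matrix(cg$nugget_zero)
    for (k in seq_len(nrow(nz))) {
      if (abs(cg$T[nz[k, 1], nz[k, 2]]) > 0) {
        abort("structurally zero nugget entry is non-zero")
      }
    }
  }
  stopifnot(cg$kappa > 0, cg$phi > 0)
  invisible(cg)
}

#' @export
print.se_coreg <- function(x, ...) {
  cat("Linear model of coregionalization (", x$p, " variables)\n", sep = "")
  cat("Matern kappa =", x$kappa, ", phi =", x$phi, "km\n")
  cat("Nugget covariance T:\n")
  print(round(x$T, 4))
  cat("Spatially correlated covariance S:\n")
  print(round(x$S, 4))
  invisible(x)
}

#' Assemble the joint covariance matrix of a multivariate observation stack
#'
#' For rows (u, i) and (v, j) — variable u at site i, variable v at site j —
#' the covariance is `T[u,v] * 1{i == j} + S[u,v] * rho(||x_i - x_j||)` with
#' the coregionalization's shared Matern correlation rho.
#'
#' @param rows Data frame with columns `var` (variable index), `site_id`,
#'   `x_km`, `y_km` (one row per observation).
#' @param coreg An `se_coreg` object.
#' @return An n x n symmetric PSD covariance matrix.
#' @export
build_joint_cov <- function(rows, coreg) {
  validate_coreg(coreg)
  vidx <- as.integer(rows$var)
  stopifnot(all(vidx >= 1), all(vidx <= coreg$p))
  sid <- match(rows$site_id, unique(rows$site_id))
  coords <- cbind(rows$x_km, rows$y_km)[!duplicated(sid), , drop = FALSE]
  D <- as.matrix(dist(coords))
  R <- matern_corr(D, coreg$kappa, coreg$phi)
  V <- coreg$S[vidx, vidx, drop = FALSE] * R[sid, sid, drop = FALSE] +
    coreg$T[vidx, vidx, drop = FALSE] * outer(sid, sid, "==")
  (V + t(V)) / 2
}

# Fast evaluator of the Matern correlation in scaled distance u = h/phi.
# Half-integer smoothness uses the closed form; otherwise a natural cubic
# spline through the Bessel form on a log-spaced grid (|error| < 1e-6),
# which avoids millions of besselK calls inside optimization loops.
matern_evaluator <- function(kappa) {
  if (kappa %in% c(0.5, 1.5, 2.5)) {
    return(function(u) matern_corr(u, kappa, 1))
  }
  ug <- exp(seq(log(1e-8), log(60), length.out = 3000))
  sp <- stats::splinefun(ug, matern_corr(ug, kappa, 1), method = "natural")
  function(u) {
    out <- numeric(length(u))
    out[u <= 1e-8] <- 1
    mid <- u > 1e-8 & u < 60
    out[mid] <- pmin(pmax(sp(u[mid]), 0), 1)
    out
  }
}

# Cholesky with escalating jitter, for covariance factorization.
chol_jitter <- function(V, jitter = 1e-10, tries = 4) {
  for (k in 0:tries) {
    U <- tryCatch(chol(V + diag(jitter * 10^k * (k > 0), nrow(V))),
      error = function(e) NULL
    )
    if (!is.null(U)) return(U)
  }
  abort("covariance matrix could not be factorized even with jitter")
}

# Symmetric PSD square root (eigen based; negative eigenvalues clipped at 0).
mat_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Empirical (Matheron) variogram
#'
#' Method-of-moments semivariance estimator
#' \eqn{\hat\gamma(h) = \frac{1}{2N(h)}\sum (z_i - z_j)^2} over pairs whose
#' separation falls in each lag bin.  Bins are left-closed, right-open.
#' Empty bins are reported with `npairs = 0` and `gamma = NA`, never dropped.
#'
#' @param values Numeric vector of observations.
#' @param coords Two-column matrix/data frame of coordinates (km).
#' @param bin_edges Strictly increasing lag-bin edges (km); default 15 bins
#'   up to half the maximum pairwise distance.
#' @return A tibble of class `se_variogram` with columns `lag` (bin
#'   midpoint), `gamma`, `npairs`.
#' @export
empirical_variogram <- function(values, coords, bin_edges = NULL) {
  coords <- as.matrix(coords)
  stopifnot(length(values) >= 2, nrow(coords) == length(values))
  D <- dist(coords)
  if (is.null(bin_edges)) {
    bin_edges <- seq(0, max(D) / 2, length.out = 16)
    bin_edges[1] <- 1e-12 # exclude zero-lag duplicates from the first bin
  }
  stopifnot(all(diff(bin_edges) > 0))
  dv <- as.vector(D)
  sq <- as.vector(dist(values))^2 / 2
  bin <- findInterval(dv, bin_edges, left.open = FALSE, rightmost.closed = FALSE)
  nb <- length(bin_edges) - 1
  keep <- bin >= 1 & bin <= nb
  gamma <- rep(NA_real_, nb)
  np <- integer(nb)
  if (any(keep)) {
    agg_n <- tabulate(bin[keep], nbins = nb)
    agg_s <- vapply(seq_len(nb), function(b) sum(sq[keep][bin[keep] == b]), 0)
    np <- agg_n
    gamma[agg_n > 0] <- agg_s[agg_n > 0] / agg_n[agg_n > 0]
  }
  out <- tibble(
    lag = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
    gamma = gamma,
    npairs = np
  )
  class(out) <- c("se_variogram", class(out))
  out
}

#' @rdname empirical_variogram
#' @param object An `se_variogram`.
#' @param ... Ignored.
#' @export
autoplot.se_variogram <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, .data$npairs > 0),
    ggplot2::aes(x = .data$lag, y = .data$gamma)
  ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$npairs), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(
      x = "lag distance / km", y = "semivariance",
      size = "pairs"
    ) +
    ggplot2::theme_minimal()
}
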