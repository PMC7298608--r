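# Shared fixture builders: every fixture is generated in code at test time.

# Single-variable observation stack at random coordinates.
make_stack1 <- function(n, seed, frame = 60, value_fun = NULL) {
  set.seed(seed)
  co <- cbind(runif(n, 0, frame), runif(n, 0, frame))
  vals <- if (is.null(value_fun)) rnorm(n) else value_fun(co)
  as_obs_stack(tibble::tibble(
    var = 1L, site_id = sprintf("s%04d", seq_len(n)),
    x_km = co[, 1], y_km = co[, 2], value = vals
  ))
}

# Trivariate stack with the survey's collocation pattern: each site grows
# one crop (alternating), variable 3 observed everywhere.
make_stack3 <- function(ns, coreg, seed, frame = 100) {
  set.seed(seed)
  co <- cbind(runif(ns, 0, frame), runif(ns, 0, frame))
  z <- simulate_fields(co, coreg, seed = seed + 1)
  crop <- rep(c(1L, 2L), length.out = ns)
  rows <- lapply(seq_len(ns), function(i) {
    dplyr::bind_rows(
      tibble::tibble(
        var = crop[i], site_id = sprintf("s%04d", i),
        x_km = co[i, 1], y_km = co[i, 2], value = z[i, crop[i]]
      ),
      tibble::tibble(
        var = 3L, site_id = sprintf("s%04d", i),
        x_km = co[i, 1], y_km = co[i, 2], value = z[i, 3]
      )
    )
  })
  as_obs_stack(dplyr::bind_rows(rows))
}

# A small survey configuration that keeps simulation-heavy tests fast.
small_survey_config <- function(seed = 1L, ...) {
  survey_config(
    frame_km = c(40, 40), n_primary = 60, n_close_pairs = 6,
    grid_cell_km = 4, seed = seed, ...
  )
}
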