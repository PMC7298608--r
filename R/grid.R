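#' Regular grid surface
#'
#' A minimal in-memory container for a single-band, north-up, cell-centre
#' registered regular grid: a values matrix whose first row is the
#' northernmost row, with the lower-left corner of the grid and the square
#' cell size in km.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param xll,yll Lower-left *corner* coordinates (km).
#' @param cellsize Cell size (km), > 0.
#' @param name Optional layer name.
#' @return An object of class `se_grid`.
#' @export
se_grid <- function(values, xll = 0, yll = 0, cellsize = 1, name = "layer") {
  values <- as.matrix(values)
  stopifnot(cellsize > 0, all(is.finite(values)))
  structure(
    list(
      values = values, xll = xll, yll = yll, cellsize = cellsize,
      name = name
    ),
    class = "se_grid"
  )
}

#' @export
print.se_grid <- function(x, ...) {
  cat(
    "se_grid '", x$name, "': ", nrow(x$values), " x ", ncol(x$values),
    " cells of ", x$cellsize, " km (xll=", x$xll, ", yll=", x$yll, ")\n",
    sep = ""
  )
  invisible(x)
}

grid_same_geometry <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(
      c(a$xll, a$yll, a$cellsize),
      c(b$xll, b$yll, b$cellsize)
    ))
}

#' Cell-centre coordinates and values of a grid as a tibble
#'
#' @param grid An `se_grid`.
#' @return Tibble with `x_km`, `y_km`, `value` (one row per cell).
#' @export
grid_to_tibble <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  xs <- grid$xll + (seq_len(nc) - 0.5) * grid$cellsize
  ys <- grid$yll + (nr - seq_len(nr) + 0.5) * grid$cellsize # row 1 = north
  tibble(
    x_km = rep(xs, each = nr),
    y_km = rep(ys, times = nc),
    value = as.vector(grid$values)
  )
}

#' Extract grid values at point locations (containing cell)
#'
#' @param grid An `se_grid`.
#' @param x,y Point coordinates (km).
#' @return Values of the cell containing each point.
#' @export
extract_at <- function(grid, x, y) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  row_from_s <- floor((y - grid$yll) / grid$cellsize) + 1
  row <- nr - row_from_s + 1
  col <- pmin(pmax(col, 1), nc)
  row <- pmin(pmax(row, 1), nr)
  grid$values[cbind(row, col)]
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange.  Written cell-centre registered
#' via `xllcorner`/`yllcorner`; values serialized row-wise from the north.
#'
#' @param grid An `se_grid`.
#' @param path File path.
#' @param digits Significant digits written.
#' @return `read_esri_ascii()` returns an `se_grid`; the writer returns the
#'   path invisibly.
#' @export
write_esri_ascii <- function(grid, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid$values)),
    paste("nrows", nrow(grid$values)),
    paste("xllcorner", format(grid$xll, digits = 15)),
    paste("yllcorner", format(grid$yll, digits = 15)),
    paste("cellsize", format(grid$cellsize, digits = 15)),
    paste("NODATA_value", -9999)
  ), con)
  apply(grid$values, 1, function(r) {
    writeLines(paste(signif(r, digits), collapse = " "), con)
  })
  invisible(path)
}

#' @rdname write_esri_ascii
#' @param name Layer name given to the grid read back.
#' @export
read_esri_ascii <- function(path, name = basename(path)) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- hdr$nrows
  nc <- hdr$ncols
  stopifnot(length(vals) == nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  se_grid(m, xll = xll, yll = yll, cellsize = hdr$cellsize, name = name)
}

#' @rdname se_grid
#' @param object An `se_grid`.
#' @param ... Ignored.
#' @export
autoplot.se_grid <- function(object, ...) {
  ggplot2::ggplot(
    grid_to_tibble(object),
    ggplot2::aes(x = .data$x_km, y = .data$y_km, fill = .data$value)
  ) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$name) +
    ggplot2::labs(x = "Easting / km", y = "Northing / km") +
    ggplot2::theme_minimal()
}
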