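#' Gridded multi-variable climate layers
#'
#' A `climate_grid` holds one 2-D layer per climate variable on a shared
#' lon/lat rectangle, together with a land mask, an elevation surface and a
#' scenario label.  Rows index latitude (row 1 at the southern edge) and
#' columns index longitude; all layers share shape, extent and resolution.
#' Cells outside the land mask are `NA` in every layer.
#'
#' The five default variables mirror the bioclimatic set most used for
#' plant distribution modelling: annual mean temperature (degC), mean
#' diurnal temperature range (degC), temperature seasonality (SD x 100,
#' unitless), annual precipitation (mm) and precipitation seasonality
#' (CV, %).
#'
#' @param values named list of numeric matrices, one per variable.
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in decimal degrees.
#' @param resolution cell size in degrees (single positive number).
#' @param scenario scenario label, e.g. "present", "future_moderate",
#'   "future_severe".
#' @param elevation numeric matrix of elevation (m) with the same shape.
#' @param mask logical matrix; TRUE for land cells.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(values, extent, resolution, scenario = "present",
                         elevation = NULL, mask = NULL) {
  stopifnot(is.list(values), length(values) >= 1, !is.null(names(values)))
  check_scalar(resolution = resolution)
  if (resolution <= 0) stop("resolution must be positive")
  dims <- dim(values[[1]])
  for (v in values) {
    if (!is.matrix(v) || !identical(dim(v), dims)) {
      stop("all variable layers must be matrices of identical shape")
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  if (is.null(elevation)) elevation <- matrix(0, dims[1], dims[2])
  stopifnot(identical(dim(mask), dims), identical(dim(elevation), dims))
  for (nm in names(values)) values[[nm]][!mask] <- NA_real_
  elevation[!mask] <- NA_real_
  g <- structure(list(
    variables = names(values),
    values = values,
    extent = as.numeric(extent),
    resolution = as.numeric(resolution),
    scenario = scenario,
    elevation = elevation,
    mask = mask
  ), class = "climate_grid")
  validate_climate_grid(g)
  g
}

validate_climate_grid <- function(g) {
  stopifnot(inherits(g, "climate_grid"))
  e <- g$extent
  if (length(e) != 4 || e[3] <= e[1] || e[4] <= e[2]) {
    stop("extent must be c(xmin, ymin, xmax, ymax) with positive spans")
  }
  for (nm in g$variables) {
    if (anyNA(g$values[[nm]][g$mask])) {
      stop(sprintf("variable '%s' has missing values inside the land mask", nm))
    }
  }
  invisible(g)
}

#' @export
print.climate_grid <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<climate_grid> %s: %d x %d cells at %g deg, %d variables\n",
              x$scenario, d[1], d[2], x$resolution, length(x$variables)))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  cat(sprintf("  land cells: %d of %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Grid binning specification
#'
#' Extracts origin/resolution/shape from a `climate_grid` (or builds one from
#' scratch) for coordinate-to-cell binning.  Cells are half-open
#' `[lower, upper)` intervals; coordinates exactly on the upper extent edge
#' fall in the last cell.
#'
#' @param x a `climate_grid`, or NULL to build from the other arguments.
#' @param extent,resolution used when `x` is NULL.
#' @return list with `origin`, `resolution`, `nx`, `ny`, `extent`.
#' @export
grid_spec <- function(x = NULL, extent = NULL, resolution = NULL) {
  if (!is.null(x)) {
    stopifnot(inherits(x, "climate_grid"))
    extent <- x$extent
    resolution <- x$resolution
  }
  nx <- as.integer(round((extent[3] - extent[1]) / resolution))
  ny <- as.integer(round((extent[4] - extent[2]) / resolution))
  list(origin = c(extent[1], extent[2]), resolution = resolution,
       nx = nx, ny = ny, extent = extent)
}

#' Map lon/lat coordinates to grid row/column
#'
#' @param spec a [grid_spec()].
#' @param lon,lat numeric vectors of coordinates.
#' @return data.frame with `row`, `col` (NA for points outside the extent).
#' @export
coord_to_cell <- function(spec, lon, lat) {
  col <- floor((lon - spec$origin[1]) / spec$resolution) + 1
  row <- floor((lat - spec$origin[2]) / spec$resolution) + 1
  # upper-edge convention: points exactly on the max edge belong to last cell
  col[lon == spec$extent[3]] <- spec$nx
  row[lat == spec$extent[4]] <- spec$ny
  bad <- lon < spec$extent[1] | lon > spec$extent[3] |
    lat < spec$extent[2] | lat > spec$extent[4]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates for grid rows/columns
#'
#' @param spec a [grid_spec()].
#' @param row,col integer vectors of cell indices.
#' @return data.frame with `lon`, `lat` of cell centers.
#' @export
cell_to_coord <- function(spec, row, col) {
  data.frame(lon = spec$origin[1] + (col - 0.5) * spec$resolution,
             lat = spec$origin[2] + (row - 0.5) * spec$resolution)
}

#' Linear indices of land cells
#' @param grid a `climate_grid`.
#' @return integer vector of linear (column-major) cell indices.
#' @export
land_cells <- function(grid) which(grid$mask)

#' Climate values at a set of cells
#'
#' @param grid a `climate_grid`.
#' @param cells linear cell indices (default: all land cells).
#' @return numeric matrix, one column per variable.
#' @export
climate_values <- function(grid, cells = land_cells(grid)) {
  out <- vapply(grid$variables, function(v) grid$values[[v]][cells],
                numeric(length(cells)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(cells),
                                       dimnames = list(NULL, grid$variables))
  out
}

#' @export
as.data.frame.climate_grid <- function(x, ...) {
  sp <- grid_spec(x)
  cells <- land_cells(x)
  rc <- arrayInd(cells, dim(x$mask))
  xy <- cell_to_coord(sp, rc[, 1], rc[, 2])
  cbind(data.frame(cell = cells, row = rc[, 1], col = rc[, 2]),
        xy, as.data.frame(climate_values(x, cells)),
        elevation = x$elevation[cells])
}

#' Write a climate grid to disk
#'
#' Writes one band per variable as a 32-bit multi-band TIFF (band order =
#' variable order).  TIFF floats are stored on a 0-1 scale, so each band is
#' min-max normalised and the offsets/ranges are recorded, together with
#' variables, extent, resolution and scenario, in a JSON sidecar
#' (`<path>.json`).  Requires the `tiff` and `jsonlite` packages.  Cells
#' outside the land mask are written as `NaN`.
#'
#' @param grid a `climate_grid`.
#' @param path output file path (".tif").
#' @return `path`, invisibly.
#' @export
write_grid_tiff <- function(grid, path) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE)) {
    stop("packages 'tiff' and 'jsonlite' are required for TIFF export")
  }
  offsets <- ranges <- stats::setNames(numeric(length(grid$variables)),
                                       grid$variables)
  # row 1 of the stored matrix is the southern edge; TIFF rows start at the top
  bands <- lapply(grid$variables, function(v) {
    m <- grid$values[[v]]
    lo <- min(m, na.rm = TRUE)
    rg <- max(m, na.rm = TRUE) - lo
    if (rg == 0) rg <- 1
    offsets[[v]] <<- lo
    ranges[[v]] <<- rg
    m <- (m - lo) / rg
    m[is.na(m)] <- NaN
    m[rev(seq_len(nrow(m))), , drop = FALSE]
  })
  tiff::writeTIFF(bands, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(variables = grid$variables, extent = grid$extent,
               resolution = grid$resolution, scenario = grid$scenario,
               offsets = as.list(offsets), ranges = as.list(ranges))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a climate grid written by [write_grid_tiff()]
#'
#' @param path path to the ".tif" file (sidecar `<path>.json` must exist).
#' @return a `climate_grid`.
#' @export
read_grid_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("jsonlite", quietly = TRUE)) {
    stop("packages 'tiff' and 'jsonlite' are required for TIFF import")
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bands <- tiff::readTIFF(path, all = TRUE)
  vals <- lapply(seq_along(bands), function(i) {
    m <- bands[[i]][rev(seq_len(nrow(bands[[i]]))), , drop = FALSE]
    m[is.nan(m)] <- NA_real_
    v <- meta$variables[i]
    m * meta$ranges[[v]] + meta$offsets[[v]]
  })
  names(vals) <- meta$variables
  mask <- !is.na(vals[[1]])
  climate_grid(vals, extent = meta$extent, resolution = meta$resolution,
               scenario = meta$scenario, mask = mask)
}
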