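# Dispersal-limited projection: damp future suitability by an exponential
# decay of distance from known presences before binarisation.

#' Distance of every land cell to the nearest presence cell
#'
#' Grid Euclidean distance between cell centers, converted to km with a
#' fixed km-per-cell factor (the grid is an abstract lon/lat rectangle; no
#' great-circle correction is applied).
#'
#' @param presence_cells linear cell indices of presences (>= 1 cell), or a
#'   logical matrix.
#' @param grid a `climate_grid`.
#' @param km_per_cell km spanned by one cell; default
#'   `resolution * 111.32` (km per degree at the equator).
#' @return numeric matrix of distances (km); NA outside the land mask.
#' @export
distance_to_presence <- function(presence_cells, grid, km_per_cell = NULL) {
  if (is.matrix(presence_cells)) presence_cells <- which(presence_cells)
  if (length(presence_cells) == 0) stop("at least one presence cell required")
  if (is.null(km_per_cell)) km_per_cell <- grid$resolution * 111.32
  dims <- dim(grid$mask)
  cells <- land_cells(grid)
  rc <- arrayInd(cells, dims)
  pc <- arrayInd(presence_cells, dims)
  # min over presence cells, blocked to bound memory on large grids
  dmin <- rep(Inf, length(cells))
  block <- 500L
  for (start in seq(1, nrow(pc), by = block)) {
    idx <- start:min(start + block - 1L, nrow(pc))
    d2 <- outer(rc[, 1], pc[idx, 1], "-")^2 + outer(rc[, 2], pc[idx, 2], "-")^2
    dmin <- pmin(dmin, sqrt(.rowMins(d2)))
  }
  out <- matrix(NA_real_, dims[1], dims[2])
  out[cells] <- dmin * km_per_cell
  out
}

.rowMins <- function(m) {
  if (ncol(m) == 1) return(m[, 1])
  do.call(pmin, asplit(m, 2))
}

#' Damp suitability by exponential distance decay
#'
#' `s' = s * exp(-d / alpha)`: suitability is unchanged where distance is
#' zero and shrinks with the e-folding scale `alpha` (km).  Applying the
#' decay before binarisation with an unchanged threshold yields the
#' limited-dispersal projection; since the decay can only shrink
#' suitability, the limited-dispersal range is always a subset of the
#' unlimited one.
#'
#' @param suitability numeric matrix in `[0, 1]`.
#' @param distance_map matrix of non-negative distances (km), same shape.
#' @param alpha e-folding distance in km (> 0); as `alpha -> Inf` the
#'   damped map converges to the input.
#' @return damped suitability matrix.
#' @export
apply_decay <- function(suitability, distance_map, alpha = 100) {
  check_scalar(alpha = alpha)
  if (alpha <= 0) stop("alpha must be positive")
  stopifnot(identical(dim(suitability), dim(distance_map)))
  if (any(distance_map < 0, na.rm = TRUE)) {
    stop("distances must be non-negative")
  }
  suitability * exp(-distance_map / alpha)
}
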