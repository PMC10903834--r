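# Collinearity-based climate variable selection on random points.

#' Sample random points over the land mask
#'
#' Uniform sample of land cells (without replacement when possible; with
#' replacement plus a warning when `n` exceeds the number of land cells),
#' with the climate values extracted at each point.
#'
#' @param climate a `climate_grid`.
#' @param n number of points (default 10000).
#' @param seed integer seed.
#' @return data.frame with `cell`, `lon`, `lat` and one column per
#'   variable.
#' @export
sample_random_points <- function(climate, n = 10000, seed = 1) {
  stopifnot(inherits(climate, "climate_grid"), n >= 1)
  cells <- land_cells(climate)
  if (length(cells) == 0) stop("land mask is empty")
  with_seed(seed, {
    if (n > length(cells)) {
      warning("n exceeds the number of land cells; sampling with replacement")
      pick <- sample(cells, n, replace = TRUE)
    } else {
      pick <- sample(cells, n)
    }
    rc <- arrayInd(pick, dim(climate$mask))
    xy <- cell_to_coord(grid_spec(climate), rc[, 1], rc[, 2])
    cbind(data.frame(cell = pick, lon = xy$lon, lat = xy$lat),
          as.data.frame(climate_values(climate, pick)))
  })
}

#' Default priority order for climate variables
#'
#' Total order encoding how frequently each variable is used in plant
#' distribution modelling; when two variables are collinear the
#' lower-priority one is dropped.
#'
#' @return character vector, most-preferred first.
#' @export
default_priority <- function() {
  c("annual_mean_temp", "annual_precip", "diurnal_range",
    "temp_seasonality", "precip_seasonality")
}

#' Select a mutually low-correlated variable subset
#'
#' Pearson correlations are computed between all variable pairs on the
#' supplied points.  Variables are scanned in priority order; a variable is
#' retained only if its absolute correlation with every already-retained
#' variable is below `threshold`, otherwise it is dropped citing the
#' retained partner that triggered the drop.  Absolute correlation is used:
#' strong negative correlations count as collinear too.
#'
#' @param points data.frame of sampled points (from
#'   [sample_random_points()]); only the columns named in `priority` are
#'   used.
#' @param threshold collinearity cutoff on `|r|` (default 0.7); pairs with
#'   `|r| >=` threshold are collinear.
#' @param priority character vector: total order over the variables, most
#'   preferred first.  Must cover every variable considered.
#' @return object of class `correlation_report`: `pairs` (var1, var2, r),
#'   `retained`, `dropped` (variable, due_to, r), `threshold`.
#' @export
select_variables <- function(points, threshold = 0.7,
                             priority = default_priority()) {
  miss <- setdiff(priority, names(points))
  if (length(miss) > 0) {
    stop(sprintf("points are missing variables: %s",
                 paste(miss, collapse = ", ")))
  }
  X <- as.matrix(points[, priority, drop = FALSE])
  cm <- stats::cor(X)
  retained <- character(0)
  dropped <- data.frame(variable = character(0), due_to = character(0),
                        r = numeric(0))
  for (v in priority) {
    if (length(retained) > 0) {
      rr <- abs(cm[v, retained])
      if (any(rr >= threshold)) {
        culprit <- retained[which.max(rr)]
        dropped <- rbind(dropped, data.frame(
          variable = v, due_to = culprit, r = cm[v, culprit]))
        next
      }
    }
    retained <- c(retained, v)
  }
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(var1 = rownames(cm)[idx[, 1]],
                      var2 = colnames(cm)[idx[, 2]],
                      r = cm[idx])
  structure(list(pairs = pairs, retained = retained, dropped = dropped,
                 threshold = threshold), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> threshold |r| >= %g\n", x$threshold))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped) > 0) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  dropped %s (r = %.2f with %s)\n", x$dropped$variable[i],
                  x$dropped$r[i], x$dropped$due_to[i]))
    }
  } else cat("  dropped: none\n")
  invisible(x)
}
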