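# Virtual landscape generator: correlated climate layers on an elevation
# gradient, for present and two future scenarios of differing severity.

#' Smooth Gaussian random field on a grid
#'
#' Bilinear interpolation of coarse iid normal noise; cheap, seedable and
#' smooth at the scale of `range_cells`.  Standardised to mean 0, sd 1.
#' Uses the current RNG stream (callers seed it).
#'
#' @param nr,nc grid dimensions.
#' @param range_cells correlation range in cells.
#' @return numeric `nr x nc` matrix.
#' @keywords internal
smooth_field <- function(nr, nc, range_cells = 25) {
  cr <- max(2L, ceiling(nr / range_cells) + 1L)
  cc <- max(2L, ceiling(nc / range_cells) + 1L)
  coarse <- matrix(stats::rnorm(cr * cc), cr, cc)
  # interpolate columns, then rows
  xi <- seq(1, cc, length.out = nc)
  yi <- seq(1, cr, length.out = nr)
  tmp <- t(apply(coarse, 1, function(z) stats::approx(seq_len(cc), z, xi)$y))
  out <- apply(tmp, 2, function(z) stats::approx(seq_len(cr), z, yi)$y)
  (out - mean(out)) / stats::sd(out)
}

#' Default future-scenario climate shifts
#'
#' Per-variable mean shifts for a moderate and a severe emissions pathway,
#' in each variable's own units (degC, degC, SD x 100, mm, CV%), the severe
#' pathway about 1.45x the moderate one, mirroring the end-of-century
#' contrast between a moderate and a severe concentration pathway.
#' `elevation_gradient` scales the shift by `1 + g * (1 - elev_norm)` so
#' that (for positive g) lowlands shift more than mountaintops and montane
#' species can partially track conditions uphill.
#'
#' `spatial_sd` adds a smooth random spatial pattern to each variable's
#' shift (sd in the variable's units); one pattern field per variable is
#' shared by all scenarios and scaled by each scenario's `spatial_sd`, the
#' way a downscaled circulation-model anomaly keeps its geography across
#' emission pathways.  Spatially varying shifts are what make the
#' driver-importance analysis identifiable.
#'
#' @return nested list: per scenario, `mean_shift` (named numeric over the 5
#'   variables), `elevation_gradient` (named numeric, 0 = uniform shift)
#'   and `spatial_sd` (named numeric, 0 = spatially uniform shift).
#' @export
default_deltas <- function() {
  vars <- c("annual_mean_temp", "diurnal_range", "temp_seasonality",
            "annual_precip", "precip_seasonality")
  grad <- stats::setNames(c(0.8, 0, 0, 0, 0), vars)
  list(
    future_moderate = list(
      mean_shift = stats::setNames(c(1.8, 0.15, 2, -150, 2), vars),
      elevation_gradient = grad,
      spatial_sd = stats::setNames(c(0.3, 0.1, 1, 50, 1), vars)
    ),
    future_severe = list(
      mean_shift = stats::setNames(c(2.6, 0.25, 3, -250, 3), vars),
      elevation_gradient = grad,
      spatial_sd = stats::setNames(c(0.45, 0.15, 1.5, 75, 1.5), vars)
    )
  )
}

#' Generate present and future virtual climate grids
#'
#' Builds an elevation surface from a smooth random field, derives five
#' weakly collinear climate variables from it (temperature decreases with
#' elevation at a fixed lapse rate; precipitation increases orographically),
#' then applies per-scenario shifts to produce two future grids.  An
#' optional `cor_spec` re-mixes one variable against another so that their
#' empirical Pearson correlation over land cells equals a requested value
#' (used to exercise collinearity filtering).
#'
#' @param grid_shape integer `c(nrows, ncols)`, at least 20 x 20.
#' @param seed integer seed; identical seeds give bit-identical grids.
#' @param scenario_deltas per-scenario shift spec as in [default_deltas()];
#'   every variable must be present in each scenario's `mean_shift`.
#' @param extent,resolution spatial metadata (degrees).  Default 0.05 deg
#'   cells anchored at (-100, 5).
#' @param ocean_fraction fraction of cells masked out as non-land.
#' @param cor_spec optional list of `list(a=, b=, r=)` entries; variable `b`
#'   is re-mixed so that cor(a, b) = r over land cells.
#' @return named list of `climate_grid` objects: `present` plus one per
#'   future scenario.
#' @export
generate_climate <- function(grid_shape = c(100, 100), seed = 1,
                             scenario_deltas = default_deltas(),
                             extent = NULL, resolution = 0.05,
                             ocean_fraction = 0.08, cor_spec = NULL) {
  stopifnot(length(grid_shape) == 2)
  if (any(grid_shape < 20)) stop("grid_shape must be at least 20 x 20")
  check_scalar(resolution = resolution)
  if (resolution <= 0) stop("resolution must be positive")
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  if (is.null(extent)) {
    extent <- c(-100, 5, -100 + nc * resolution, 5 + nr * resolution)
  }
  vars <- names(default_deltas()$future_moderate$mean_shift)
  for (sc in names(scenario_deltas)) {
    miss <- setdiff(vars, names(scenario_deltas[[sc]]$mean_shift))
    if (length(miss) > 0) {
      stop(sprintf("scenario '%s' is missing mean_shift for: %s",
                   sc, paste(miss, collapse = ", ")))
    }
  }

  with_seed(seed, {
    relief <- smooth_field(nr, nc, range_cells = 30) +
      0.5 * smooth_field(nr, nc, range_cells = 8)
    mask <- relief > stats::quantile(relief, ocean_fraction)
    rl <- relief[mask]
    elev <- matrix(NA_real_, nr, nc)
    elev[mask] <- 2800 * (relief[mask] - min(rl)) / (max(rl) - min(rl))
    ez <- elev / 1000  # km

    n1 <- smooth_field(nr, nc, 20); n2 <- smooth_field(nr, nc, 20)
    n3 <- smooth_field(nr, nc, 20); n4 <- smooth_field(nr, nc, 20)
    n5 <- smooth_field(nr, nc, 20)
    v <- list(
      annual_mean_temp = 27 - 5.5 * ez + 0.7 * n1,
      diurnal_range = 9 + 1.2 * ez + 1.2 * n2,
      temp_seasonality = 90 + 10 * ez + 25 * n3,
      annual_precip = pmax(1600 + 350 * ez + 550 * n4, 0),
      precip_seasonality = pmax(55 + 18 * n5, 0)
    )

    if (!is.null(cor_spec)) {
      for (cs in cor_spec) {
        stopifnot(all(c("a", "b", "r") %in% names(cs)))
        if (!cs$a %in% vars || !cs$b %in% vars) {
          stop("cor_spec names unknown variables")
        }
        a <- v[[cs$a]][mask]; b <- v[[cs$b]][mask]
        za <- (a - mean(a)) / stats::sd(a)
        res <- stats::residuals(stats::lm(b ~ a))
        zr <- res / stats::sd(res)
        bn <- cs$r * za + sqrt(max(0, 1 - cs$r^2)) * zr
        v[[cs$b]][mask] <- mean(b) + stats::sd(b) * bn
        if (cs$b %in% c("annual_precip", "precip_seasonality")) {
          v[[cs$b]][mask] <- pmax(0, v[[cs$b]][mask])
        }
      }
    }

    grids <- list(present = climate_grid(v, extent, resolution,
                                         scenario = "present",
                                         elevation = elev, mask = mask))
    ez_norm <- (elev - min(elev, na.rm = TRUE)) /
      max(1e-9, diff(range(elev, na.rm = TRUE)))
    # one anomaly pattern per variable, shared across scenarios
    pattern <- stats::setNames(
      lapply(vars, function(nm) smooth_field(nr, nc, 25)), vars)
    for (sc in names(scenario_deltas)) {
      sh <- scenario_deltas[[sc]]$mean_shift
      gr <- scenario_deltas[[sc]]$elevation_gradient
      ssd <- scenario_deltas[[sc]]$spatial_sd
      if (is.null(gr)) gr <- stats::setNames(rep(0, length(vars)), vars)
      if (is.null(ssd)) ssd <- stats::setNames(rep(0, length(vars)), vars)
      vf <- v
      for (nm in vars) {
        gg <- if (nm %in% names(gr)) gr[[nm]] else 0
        ss <- if (nm %in% names(ssd)) ssd[[nm]] else 0
        vf[[nm]] <- v[[nm]] + sh[[nm]] * (1 + gg * (1 - ez_norm)) +
          ss * pattern[[nm]]
        if (nm %in% c("annual_precip", "precip_seasonality")) {
          vf[[nm]] <- pmax(vf[[nm]], 0)
        }
      }
      grids[[sc]] <- climate_grid(vf, extent, resolution, scenario = sc,
                                  elevation = elev, mask = mask)
    }
    grids
  })
}
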