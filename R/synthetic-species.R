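# Virtual species with known climatic niches, known true ranges under each
# scenario, presence-only samplers and synthetic ecoregions.  These provide
# ground truth against which the modelling pipeline can be validated.

#' Niche specification for virtual species
#'
#' Controls where species' climatic optima are placed and how broad their
#' niches are.  Montane specialists draw their optima from cells above the
#' `montane_quantile` of elevation and get narrow niches; lowland species
#' draw from the rest with broader niches.  Breadths are expressed as
#' multiples of each variable's land-wide standard deviation.
#'
#' @param montane_fraction fraction of species that are montane specialists.
#' @param montane_quantile elevation quantile separating montane from
#'   lowland optima source cells.
#' @param breadth_montane,breadth_lowland niche breadth factors (x sd).
#' @param truth_threshold suitability cutoff defining the true range.
#' @param n_families number of synthetic family labels.
#' @param edge_buffer quantile width trimmed from the extremes of the
#'   elevation distribution when placing optima (0 = none).  With a
#'   positive buffer every species' climatic optimum lies interior to the
#'   observed climate domain, so both flanks of its response are in
#'   principle identifiable from occurrence data.
#' @return list of class `niche_spec`.
#' @export
niche_spec <- function(montane_fraction = 0.5, montane_quantile = 0.7,
                       breadth_montane = 0.9, breadth_lowland = 1.4,
                       truth_threshold = 0.5, n_families = 10,
                       edge_buffer = 0) {
  stopifnot(montane_fraction >= 0, montane_fraction <= 1,
            breadth_montane > 0, breadth_lowland > 0,
            truth_threshold > 0, truth_threshold < 1, n_families >= 1,
            edge_buffer >= 0, edge_buffer < 0.5)
  structure(list(montane_fraction = montane_fraction,
                 montane_quantile = montane_quantile,
                 breadth_montane = breadth_montane,
                 breadth_lowland = breadth_lowland,
                 truth_threshold = truth_threshold,
                 n_families = n_families,
                 edge_buffer = edge_buffer), class = "niche_spec")
}

# Gaussian product suitability of one species over the cells of a grid.
suitability_map <- function(grid, optima, breadth) {
  m <- matrix(NA_real_, nrow(grid$mask), ncol(grid$mask))
  cells <- land_cells(grid)
  X <- climate_values(grid, cells)
  s <- rep(1, length(cells))
  for (nm in names(optima)) {
    s <- s * exp(-((X[, nm] - optima[[nm]])^2) / (2 * breadth[[nm]]^2))
  }
  m[cells] <- s
  m
}

#' Generate virtual species with known true ranges and range changes
#'
#' Each species has a unimodal (Gaussian-product) suitability response to
#' the climate variables.  Suitability is evaluated under every scenario;
#' the binary true range is `suitability >= truth_threshold`, and the true
#' range change for a future scenario is
#' `(future cells - present cells) / present cells`.  Species whose present
#' true range is empty are regenerated (fresh optima) so that every species
#' has ground truth.  Family (and genus) labels are assigned by k-means
#' clustering of niche optima, so related species share climatic
#' preferences and family-level vulnerability contrasts exist.
#'
#' @param n_species number of species (>= 1).
#' @param climate named list of `climate_grid`s including `present`.
#' @param spec a [niche_spec()].
#' @param seed integer seed.
#' @return list of `virtual_species` objects, each with `species_id`,
#'   `genus`, `family`, `optima`, `breadth`, `montane`, `suitability`
#'   (matrix per scenario), `range` (logical matrix per scenario) and
#'   `range_change` (named numeric per future scenario).
#' @export
generate_virtual_species <- function(n_species, climate, spec = niche_spec(),
                                     seed = 1) {
  if (n_species < 1) stop("n_species must be >= 1")
  stopifnot(inherits(spec, "niche_spec"), "present" %in% names(climate))
  present <- climate$present
  cells <- land_cells(present)
  elev <- present$elevation[cells]
  eb <- if (is.null(spec$edge_buffer)) 0 else spec$edge_buffer
  qmont <- stats::quantile(elev, spec$montane_quantile)
  qlo <- stats::quantile(elev, eb)
  qhi <- stats::quantile(elev, 1 - eb)
  hi <- cells[elev >= qmont & elev <= qhi]
  lo <- cells[elev < qmont & elev >= qlo]
  X <- climate_values(present, cells)
  sds <- apply(X, 2, stats::sd)
  future_names <- setdiff(names(climate), "present")

  with_seed(seed, {
    n_mont <- round(n_species * spec$montane_fraction)
    is_mont <- c(rep(TRUE, n_mont), rep(FALSE, n_species - n_mont))
    out <- vector("list", n_species)
    for (i in seq_len(n_species)) {
      for (attempt in 1:100) {
        pool <- if (is_mont[i]) hi else lo
        home <- sample(pool, 1)
        bf <- if (is_mont[i]) spec$breadth_montane else spec$breadth_lowland
        optima <- stats::setNames(as.list(
          climate_values(present, home)[1, ]), present$variables)
        breadth <- stats::setNames(as.list(bf * sds), present$variables)
        suit <- lapply(climate, suitability_map, optima = optima,
                       breadth = breadth)
        rng <- lapply(suit, function(m) {
          r <- m >= spec$truth_threshold
          r[is.na(m)] <- FALSE
          r
        })
        if (sum(rng$present) > 0) break
      }
      if (sum(rng$present) == 0) {
        stop("failed to generate a species with a non-empty present range")
      }
      chg <- vapply(future_names, function(sc) {
        (sum(rng[[sc]]) - sum(rng$present)) / sum(rng$present)
      }, 0)
      out[[i]] <- structure(list(
        species_id = sprintf("VS%04d", i),
        montane = is_mont[i],
        optima = optima, breadth = breadth,
        suitability = suit, range = rng, range_change = chg
      ), class = "virtual_species")
    }
    # family/genus labels by clustering optima in standardised niche space
    # (hierarchical: deterministic and safe for any k <= n)
    opt <- t(vapply(out, function(s) unlist(s$optima), numeric(ncol(X))))
    optz <- scale(opt)
    optz[!is.finite(optz)] <- 0
    hc <- if (n_species > 1) stats::hclust(stats::dist(optz), "ward.D2")
    kf <- min(spec$n_families, n_species)
    fam <- if (n_species == 1) 1L else stats::cutree(hc, k = kf)
    kg <- min(3L * kf, n_species)
    gen <- if (n_species == 1) 1L else stats::cutree(hc, k = kg)
    for (i in seq_len(n_species)) {
      out[[i]]$family <- sprintf("Fam%02d", fam[i])
      out[[i]]$genus <- sprintf("Gen%03d", gen[i])
    }
    out
  })
}

#' True IUCN category implied by a species' known range change
#'
#' Category oracle used in truth-recovery checks: applies [classify_iucn()]
#' to the generator's true range change, independently of any fitted model.
#'
#' @param species list of `virtual_species`.
#' @param scenario future scenario name.
#' @param thresholds see [classify_iucn()].
#' @return factor of categories, named by species id.
#' @export
true_categories <- function(species, scenario = "future_severe",
                            thresholds = iucn_thresholds()) {
  chg <- vapply(species, function(s) s$range_change[[scenario]], 0)
  stats::setNames(classify_iucn(chg, thresholds),
                  vapply(species, `[[`, "", "species_id"))
}

#' Sample presence-only occurrence records from virtual species
#'
#' Presences are drawn (with replacement, so duplicate cell draws occur and
#' downstream deduplication is exercised) from each species' present true
#' range with probability proportional to suitability times a sampling
#' effort surface.  The effort surface is a smooth random field raised to
#' `bias_strength` (0 = uniform effort).  Coordinates are cell centers.
#'
#' @param species list of `virtual_species` from
#'   [generate_virtual_species()].
#' @param climate named list of climate grids (present grid used).
#' @param n_per_species number of records per species (>= 1).
#' @param bias_strength non-negative sampling bias exponent.
#' @param seed integer seed.
#' @return data.frame with columns `species`, `genus`, `family`,
#'   `longitude`, `latitude`, `source`, `is_morphospecies`.
#' @export
sample_occurrences <- function(species, climate, n_per_species = 100,
                               bias_strength = 0, seed = 1) {
  stopifnot(n_per_species >= 1, bias_strength >= 0)
  present <- climate$present
  sp_grid <- grid_spec(present)
  with_seed(seed, {
    eff <- exp(smooth_field(nrow(present$mask), ncol(present$mask), 20))
    effort <- eff^bias_strength
    recs <- lapply(species, function(s) {
      cells <- which(s$range$present)
      if (length(cells) == 0) {
        stop(sprintf("species '%s' has an empty present range", s$species_id))
      }
      w <- s$suitability$present[cells] * effort[cells]
      draw <- if (length(cells) == 1) rep(cells, n_per_species) else
        sample(cells, n_per_species, replace = TRUE, prob = w)
      rc <- arrayInd(draw, dim(present$mask))
      xy <- cell_to_coord(sp_grid, rc[, 1], rc[, 2])
      data.frame(species = s$species_id, genus = s$genus, family = s$family,
                 longitude = xy$lon, latitude = xy$lat,
                 source = "synthetic", is_morphospecies = FALSE)
    })
    do.call(rbind, recs)
  })
}

#' Partition the land mask into contiguous synthetic ecoregions
#'
#' Grid Voronoi regions around randomly placed seed cells: every land cell
#' is assigned to its nearest seed, giving a contiguous partition.  A
#' region is flagged montane when its mean elevation exceeds the
#' `montane_quantile` of the per-cell region-mean elevation distribution, so
#' the flagged fraction of land is about `1 - montane_quantile`.
#'
#' @param climate a `climate_grid` (or list containing `present`).
#' @param n_regions number of regions (>= 1, <= number of land cells).
#' @param seed integer seed.
#' @param montane_quantile quantile in `[0, 1)` above which regions are
#'   flagged montane; 0 flags every region.
#' @return object of class `ecoregion_map`: `region` (integer matrix, NA
#'   off-land), `names`, `montane` (logical per region).
#' @export
generate_ecoregions <- function(climate, n_regions, seed = 1,
                                montane_quantile = 0.75) {
  grid <- if (inherits(climate, "climate_grid")) climate else climate$present
  cells <- land_cells(grid)
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (n_regions > length(cells)) {
    stop("n_regions exceeds the number of land cells")
  }
  with_seed(seed, {
    seeds <- sample(cells, n_regions)
    rc <- arrayInd(cells, dim(grid$mask))
    sc <- arrayInd(seeds, dim(grid$mask))
    # nearest seed per land cell (grid Euclidean distance)
    d2 <- outer(rc[, 1], sc[, 1], "-")^2 + outer(rc[, 2], sc[, 2], "-")^2
    assign_id <- max.col(-d2, ties.method = "first")
    region <- matrix(NA_integer_, nrow(grid$mask), ncol(grid$mask))
    region[cells] <- assign_id
    mean_elev <- tapply(grid$elevation[cells], assign_id, mean)
    ids <- sort(unique(assign_id))
    # quantile over cells of their region's mean elevation
    cell_region_elev <- mean_elev[as.character(assign_id)]
    thr <- stats::quantile(cell_region_elev, montane_quantile)
    montane <- stats::setNames(as.vector(mean_elev[as.character(ids)]) >= thr,
                               sprintf("ER%03d", ids))
    if (montane_quantile == 0) montane[] <- TRUE
    structure(list(region = region,
                   names = stats::setNames(sprintf("ER%03d", ids), ids),
                   montane = montane), class = "ecoregion_map")
  })
}
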