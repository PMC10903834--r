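# IUCN criterion A3 threat classification from projected range change, and
# spatial / taxonomic / ecoregional vulnerability summaries.

#' Range change between present and future binary maps
#'
#' @param present_binary,future_binary logical matrices of equal shape.
#' @return list with `present_cells`, `future_cells`, `gained`, `lost` and
#'   `change_fraction` = (future - present) / present (can exceed 0 for
#'   expansions).
#' @export
range_change <- function(present_binary, future_binary) {
  stopifnot(identical(dim(present_binary), dim(future_binary)))
  p <- sum(present_binary, na.rm = TRUE)
  f <- sum(future_binary, na.rm = TRUE)
  if (p == 0) stop("empty present range")
  gained <- sum(future_binary & !present_binary, na.rm = TRUE)
  lost <- sum(present_binary & !future_binary, na.rm = TRUE)
  list(present_cells = p, future_cells = f, gained = gained, lost = lost,
       change_fraction = (f - p) / p)
}

#' Default IUCN criterion A3 loss thresholds
#'
#' Projected range loss of at least 30% classifies a species Vulnerable,
#' 50% Endangered, 80% Critically Endangered; total loss (100%) is treated
#' as Extinct.  Standard A3 values; fully configurable.
#'
#' @return named numeric vector of loss fractions.
#' @export
iucn_thresholds <- function() c(VU = 0.30, EN = 0.50, CR = 0.80)

#' Severity-ordered IUCN category levels
#' @return character vector LC < VU < EN < CR < EX.
#' @export
iucn_levels <- function() c("LC", "VU", "EN", "CR", "EX")

#' Classify range change into IUCN A3 categories
#'
#' `change_fraction` is (future - present) / present; losses are negative.
#' Boundaries are inclusive at each threshold (a 30% loss is VU).
#' Expansions and losses below the VU threshold are Least Concern; a
#' species is Extinct only when its future range is empty
#' (change = -1).
#'
#' @param change_fraction numeric vector in `[-1, Inf)`.
#' @param thresholds named loss thresholds as in [iucn_thresholds()].
#' @return factor with levels [iucn_levels()].
#' @export
classify_iucn <- function(change_fraction, thresholds = iucn_thresholds()) {
  if (any(change_fraction < -1, na.rm = TRUE)) {
    stop("change_fraction below -1 is impossible")
  }
  loss <- -change_fraction
  out <- rep("LC", length(loss))
  out[loss >= thresholds[["VU"]]] <- "VU"
  out[loss >= thresholds[["EN"]]] <- "EN"
  out[loss >= thresholds[["CR"]]] <- "CR"
  out[loss >= 1] <- "EX"
  factor(out, levels = iucn_levels())
}

#' Assess range change and threat category across scenarios
#'
#' For each species ensemble and each experimental scenario (future
#' scenario x dispersal assumption) computes the binary range change at
#' the species' stored threshold and the implied IUCN A3 category.  Under
#' limited dispersal, future suitability is damped by [apply_decay()] with
#' distance measured from the species' occurrence cells before the
#' (unchanged) threshold is applied.
#'
#' @param ensembles list of fitted `sdm_ensemble` objects (unmodeled ones
#'   are skipped and reported in the `excluded` attribute).
#' @param climate named list of climate grids (`present` + futures).
#' @param presence_cells named list (by species id) of occurrence cell
#'   indices, used for the dispersal distance; required when `alpha` is
#'   finite.
#' @param alpha dispersal decay scale in km (see [apply_decay()]).
#' @param dispersal which assumptions to evaluate.
#' @param thresholds IUCN loss thresholds.
#' @return data.frame of class `threat_assessment`: species, scenario
#'   (future scenario name), dispersal, present_cells, future_cells,
#'   gained, lost, change_fraction, category.
#' @export
assess_vulnerability <- function(ensembles, climate, presence_cells = NULL,
                                 alpha = 100,
                                 dispersal = c("unlimited", "limited"),
                                 thresholds = iucn_thresholds()) {
  futures <- setdiff(names(climate), "present")
  rows <- list()
  excluded <- character(0)
  for (ens in ensembles) {
    if (!isTRUE(ens$modeled)) {
      excluded <- c(excluded, ens$species_id)
      next
    }
    present_bin <- ens$binary$present
    if (sum(present_bin, na.rm = TRUE) == 0) {
      excluded <- c(excluded, ens$species_id)
      next
    }
    dist_map <- NULL
    if ("limited" %in% dispersal) {
      pc <- presence_cells[[ens$species_id]]
      if (is.null(pc)) stop(sprintf(
        "presence cells required for limited dispersal (species '%s')",
        ens$species_id))
      dist_map <- distance_to_presence(pc, climate$present)
    }
    for (sc in futures) {
      for (disp in dispersal) {
        fut_suit <- ens$maps[[sc]]
        if (disp == "limited") {
          fut_suit <- apply_decay(fut_suit, dist_map, alpha)
        }
        fut_bin <- fut_suit >= ens$threshold
        fut_bin[is.na(fut_suit)] <- FALSE
        ch <- range_change(present_bin, fut_bin)
        rows[[length(rows) + 1]] <- data.frame(
          species = ens$species_id, scenario = sc, dispersal = disp,
          present_cells = ch$present_cells, future_cells = ch$future_cells,
          gained = ch$gained, lost = ch$lost,
          change_fraction = ch$change_fraction,
          category = as.character(classify_iucn(ch$change_fraction,
                                                thresholds)))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = iucn_levels())
  attr(out, "excluded") <- excluded
  class(out) <- c("threat_assessment", class(out))
  out
}

#' Contingency table of IUCN categories by scenario
#'
#' @param assessments a `threat_assessment` data.frame.
#' @return matrix: rows = scenario x dispersal, columns = categories.
#' @export
category_counts <- function(assessments) {
  lab <- paste(assessments$scenario, assessments$dispersal, sep = ":")
  table(scenario = lab, category = assessments$category)
}

#' Chi-squared comparison of category distributions across scenarios
#'
#' Pearson's chi-squared statistic (no continuity correction) on the
#' scenario x category contingency table, with the p-value estimated by
#' Monte-Carlo simulation under fixed margins:
#' p = (1 + #\{simulated >= observed\}) / (n_replicates + 1).
#' Rows or columns summing to zero are dropped with a warning.
#'
#' @param counts contingency matrix/table (scenarios x categories).
#' @param n_replicates Monte-Carlo replicates (default 2000).
#' @param seed integer seed.
#' @return list with `statistic`, `p_value` (Monte-Carlo) and `counts`
#'   (table actually tested).
#' @export
scenario_chisq <- function(counts, n_replicates = 2000, seed = 1) {
  m <- as.matrix(unclass(counts))
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero rows/columns from the contingency table")
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2 x 2 table")
  res <- with_seed(seed, suppressWarnings(
    stats::chisq.test(m, simulate.p.value = TRUE, B = n_replicates)))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       counts = m)
}

#' Per-pixel relative vulnerability map
#'
#' Richness is the number of species whose present-day range covers the
#' pixel; the threatened count uses species classified VU, EN or CR
#' (Extinct species are tracked separately, not counted as threatened);
#' relative vulnerability is their ratio.  Pixels with zero richness are
#' masked (NA).
#'
#' @param present_ranges named list (species id) of present-day logical
#'   range maps.
#' @param categories factor/character of IUCN categories named by species.
#' @return list of class `vulnerability_map`: `richness`, `threatened`,
#'   `extinct`, `relative` matrices.
#' @export
pixel_vulnerability <- function(present_ranges, categories) {
  stopifnot(length(present_ranges) >= 1)
  ids <- names(present_ranges)
  stopifnot(!is.null(ids), all(ids %in% names(categories)))
  threatened_set <- c("VU", "EN", "CR")
  dims <- dim(present_ranges[[1]])
  rich <- thr <- ext <- matrix(0, dims[1], dims[2])
  for (id in ids) {
    r <- present_ranges[[id]]
    rich <- rich + r
    cat_i <- as.character(categories[[id]])
    if (cat_i %in% threatened_set) thr <- thr + r
    if (cat_i == "EX") ext <- ext + r
  }
  rel <- thr / rich
  rel[rich == 0] <- NA_real_
  structure(list(richness = rich, threatened = thr, extinct = ext,
                 relative = rel), class = "vulnerability_map")
}

#' Percentage of threatened species by family
#'
#' @param categories factor/character of categories named by species id.
#' @param family_lookup named character vector: species id -> family.
#' @param min_species families with more than this many modeled species
#'   form the `diverse` subset (default 30, strict).
#' @return list with `all` and `diverse` data.frames (family, n_modeled,
#'   n_threatened, pct_threatened), sorted by descending percentage.
#' @export
family_vulnerability <- function(categories, family_lookup,
                                 min_species = 30) {
  ids <- names(categories)
  stopifnot(!is.null(ids), all(ids %in% names(family_lookup)))
  fam <- family_lookup[ids]
  thr <- as.character(categories) %in% c("VU", "EN", "CR")
  agg <- data.frame(
    family = names(tapply(thr, fam, length)),
    n_modeled = as.vector(tapply(thr, fam, length)),
    n_threatened = as.vector(tapply(thr, fam, sum))
  )
  agg$pct_threatened <- 100 * agg$n_threatened / agg$n_modeled
  agg <- agg[order(-agg$pct_threatened, agg$family), ]
  rownames(agg) <- NULL
  diverse <- agg[agg$n_modeled > min_species, , drop = FALSE]
  rownames(diverse) <- NULL
  list(all = agg, diverse = diverse)
}

#' Ecoregion vulnerability summary
#'
#' Mean and standard deviation of per-pixel relative vulnerability, and
#' mean species richness, across the occupied pixels of each ecoregion.
#' Regions with fewer occupied pixels than `min_pixels` are discarded; the
#' result is sorted by descending mean proportion (the top rows mirror a
#' "most vulnerable ecoregions" table).
#'
#' @param vmap a `vulnerability_map`.
#' @param ecoregions an `ecoregion_map`.
#' @param min_pixels minimum occupied pixels for a region to be reported.
#' @return data.frame: region, montane, mean_proportion, sd, richness, n.
#' @export
ecoregion_summary <- function(vmap, ecoregions, min_pixels = 30) {
  stopifnot(inherits(vmap, "vulnerability_map"),
            inherits(ecoregions, "ecoregion_map"))
  ok <- !is.na(vmap$relative) & !is.na(ecoregions$region)
  reg <- ecoregions$region[ok]
  rel <- vmap$relative[ok]
  rich <- vmap$richness[ok]
  ids <- sort(unique(reg))
  out <- data.frame(
    region = ecoregions$names[as.character(ids)],
    montane = unname(ecoregions$montane[ecoregions$names[as.character(ids)]]),
    mean_proportion = as.vector(tapply(rel, reg, mean)[as.character(ids)]),
    sd = as.vector(tapply(rel, reg, stats::sd)[as.character(ids)]),
    richness = as.vector(tapply(rich, reg, mean)[as.character(ids)]),
    n = as.vector(tapply(rel, reg, length)[as.character(ids)])
  )
  out$sd[is.na(out$sd)] <- 0
  out <- out[out$n >= min_pixels, , drop = FALSE]
  out <- out[order(-out$mean_proportion, out$region), ]
  rownames(out) <- NULL
  out
}

#' Category counts, percentages and headline ratios per scenario
#'
#' Summarises a scenario x category count table the way such results are
#' reported: per-scenario category counts and integer percentages (rounded
#' half-up), threatened (VU+EN+CR) counts and percentages, the EN+CR
#' percentage, the ratio of threatened counts between the severe and
#' moderate future under each dispersal assumption, and the ratio of
#' Critically Endangered counts between the worst (severe, limited) and
#' best (moderate, unlimited) scenario expressed as a percentage.
#'
#' @param counts matrix/table: rows = scenarios (named
#'   `"<future>:<dispersal>"` as from [category_counts()]), columns =
#'   categories.
#' @return list of class `category_report`: `table` (long data.frame),
#'   `threatened` (per-scenario data.frame), `ratios` (named numeric).
#' @export
category_report <- function(counts) {
  m <- as.matrix(unclass(counts))
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  totals <- rowSums(m)
  long <- do.call(rbind, lapply(rownames(m), function(sc) {
    data.frame(scenario = sc, category = colnames(m), n = as.vector(m[sc, ]),
               pct = round_half_up(100 * m[sc, ] / totals[sc]))
  }))
  rownames(long) <- NULL
  thr_cols <- intersect(c("VU", "EN", "CR"), colnames(m))
  encr_cols <- intersect(c("EN", "CR"), colnames(m))
  thr <- data.frame(
    scenario = rownames(m), n_modeled = as.vector(totals),
    n_threatened = as.vector(rowSums(m[, thr_cols, drop = FALSE])),
    pct_threatened = round_half_up(
      100 * rowSums(m[, thr_cols, drop = FALSE]) / totals),
    pct_en_cr = round_half_up(
      100 * rowSums(m[, encr_cols, drop = FALSE]) / totals)
  )
  rownames(thr) <- NULL
  ratios <- c()
  scen <- rownames(m)
  parts <- strsplit(scen, ":", fixed = TRUE)
  fut <- vapply(parts, `[`, "", 1)
  disp <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
  fut_levels <- unique(fut)
  if (length(fut_levels) == 2) {
    mod <- fut_levels[1]; sev <- fut_levels[2]
    for (d in unique(disp)) {
      i_m <- which(fut == mod & disp == d)
      i_s <- which(fut == sev & disp == d)
      if (length(i_m) == 1 && length(i_s) == 1) {
        ratios[[paste0("threatened_ratio_", d)]] <- round_half_up(
          thr$n_threatened[i_s] / thr$n_threatened[i_m], 2)
      }
    }
    if ("CR" %in% colnames(m)) {
      best <- which(fut == mod & disp == "unlimited")
      worst <- which(fut == sev & disp == "limited")
      if (length(best) == 1 && length(worst) == 1 && m[best, "CR"] > 0) {
        ratios[["cr_pct_worst_vs_best"]] <- round_half_up(
          100 * m[worst, "CR"] / m[best, "CR"])
      }
    }
  }
  structure(list(table = long, threatened = thr, ratios = unlist(ratios)),
            class = "category_report")
}

#' @export
print.category_report <- function(x, ...) {
  cat("<category_report>\n")
  print(x$threatened)
  if (length(x$ratios) > 0) {
    cat("ratios:\n")
    print(x$ratios)
  }
  invisible(x)
}
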