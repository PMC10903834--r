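# Virtual species: Gaussian-product niches, true ranges and range changes,
# occurrence sampling, ecoregion partitions.

test_that("suitability peaks at 1 where the climate matches the optimum", {
  sp <- small_species()
  for (s in sp[1:3]) {
    expect_equal(max(s$suitability$present, na.rm = TRUE), 1,
                 tolerance = 1e-12)
    expect_true(all(s$suitability$present >= 0 &
                      s$suitability$present <= 1, na.rm = TRUE))
  }
})

test_that("an unchanged future climate implies zero true range change", {
  cl <- generate_climate(c(25, 25), seed = 3, scenario_deltas = zero_deltas())
  sp <- generate_virtual_species(5, cl, seed = 2)
  for (s in sp) expect_true(all(s$range_change == 0))
})

test_that("narrow-niche montane specialists lose range under severe warming", {
  cl <- small_climate()
  sp <- generate_virtual_species(
    10, cl, niche_spec(montane_fraction = 1, breadth_montane = 0.5), seed = 4)
  chg <- vapply(sp, function(s) s$range_change[["future_severe"]], 0)
  # cell-count oracle: recompute the change directly from the truth maps
  oracle <- vapply(sp, function(s) {
    (sum(s$range$future_severe) - sum(s$range$present)) / sum(s$range$present)
  }, 0)
  expect_equal(chg, oracle)
  expect_lt(median(chg), 0)
})

test_that("every species has a non-empty present range and valid labels", {
  sp <- small_species()
  for (s in sp) {
    expect_gt(sum(s$range$present), 0)
    expect_match(s$family, "^Fam")
    expect_match(s$genus, "^Gen")
  }
  expect_error(generate_virtual_species(0, small_climate()), ">= 1")
  expect_identical(generate_virtual_species(3, small_climate(), seed = 9),
                   generate_virtual_species(3, small_climate(), seed = 9))
})

test_that("true category oracle matches manual classification", {
  sp <- small_species()
  tc <- true_categories(sp, "future_severe")
  chg <- vapply(sp, function(s) s$range_change[["future_severe"]], 0)
  expect_identical(as.character(tc),
                   as.character(classify_iucn(chg)))
})

test_that("occurrences fall inside the present true range", {
  cl <- small_climate()
  sp <- small_species()
  occ <- small_occurrences()
  spgr <- grid_spec(cl$present)
  for (s in sp) {
    rows <- occ[occ$species == s$species_id, ]
    rc <- coord_to_cell(spgr, rows$longitude, rows$latitude)
    cells <- (rc$col - 1L) * nrow(cl$present$mask) + rc$row
    expect_true(all(s$range$present[cells]))
  }
})

test_that("one record per species when n_per_species = 1", {
  occ <- sample_occurrences(small_species(), small_climate(),
                            n_per_species = 1, seed = 3)
  expect_equal(nrow(occ), length(small_species()))
  expect_equal(as.vector(table(occ$species)), rep(1L, length(small_species())))
})

test_that("unbiased sampling frequencies track suitability", {
  cl <- small_climate()
  sp <- small_species()[1]
  occ <- sample_occurrences(sp, cl, n_per_species = 6000, bias_strength = 0,
                            seed = 11)
  s <- sp[[1]]
  spgr <- grid_spec(cl$present)
  rc <- coord_to_cell(spgr, occ$longitude, occ$latitude)
  cells <- (rc$col - 1L) * nrow(cl$present$mask) + rc$row
  range_cells <- which(s$range$present)
  suit <- s$suitability$present[range_cells]
  # chi-squared goodness of fit on suitability-quintile bins
  bins <- cut(suit, quantile(suit, seq(0, 1, 0.2)), include.lowest = TRUE)
  expected_p <- tapply(suit / sum(suit), bins, sum)
  observed <- tapply(tabulate(match(cells, range_cells),
                              length(range_cells)), bins, sum)
  gof <- chisq.test(observed, p = expected_p)
  expect_gt(gof$p.value, 0.001)
})

test_that("sampling errors and determinism behave", {
  cl <- small_climate()
  sp <- small_species()
  fake <- sp[[1]]
  fake$range$present[] <- FALSE
  expect_error(sample_occurrences(list(fake), cl, 5),
               fake$species_id)
  expect_identical(sample_occurrences(sp, cl, 10, seed = 8),
                   sample_occurrences(sp, cl, 10, seed = 8))
})

test_that("ecoregions partition the land mask", {
  cl <- small_climate()
  er <- generate_ecoregions(cl, n_regions = 12, seed = 3)
  cells <- land_cells(cl$present)
  expect_false(anyNA(er$region[cells]))
  expect_true(all(is.na(er$region[!cl$present$mask])))
  sizes <- table(er$region[cells])
  expect_equal(sum(sizes), length(cells))
  expect_equal(length(sizes), 12L)
})

test_that("single region with montane quantile 0 is flagged montane", {
  er <- generate_ecoregions(small_climate(), n_regions = 1, seed = 1,
                            montane_quantile = 0)
  expect_length(er$montane, 1)
  expect_true(all(er$montane))
})

test_that("montane-flagged fraction approximates the quantile complement", {
  cl <- generate_climate(c(60, 60), seed = 13)
  er <- generate_ecoregions(cl, n_regions = 80, seed = 5,
                            montane_quantile = 0.75)
  cells <- land_cells(cl$present)
  frac <- mean(er$montane[er$names[as.character(er$region[cells])]])
  expect_true(abs(frac - 0.25) < 0.12)
})

test_that("too many regions are rejected", {
  cl <- small_climate()
  expect_error(generate_ecoregions(cl, n_regions = 1e6), "exceeds")
})
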