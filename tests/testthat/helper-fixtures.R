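# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# memoised accessor: fixtures are deterministic, so one copy per run
fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_climate <- function() {
  fixture("small_climate", function() generate_climate(c(30, 30), seed = 42))
}

small_species <- function() {
  fixture("small_species", function() {
    generate_virtual_species(8, small_climate(), seed = 7)
  })
}

small_occurrences <- function() {
  fixture("small_occurrences", function() {
    sample_occurrences(small_species(), small_climate(), n_per_species = 60,
                       seed = 5)
  })
}

# hand-built occurrence table on a 10x10 unit grid starting at (0, 0)
toy_grid_spec <- function() {
  grid_spec(extent = c(0, 0, 10, 10), resolution = 1)
}

toy_occurrences <- function() {
  data.frame(
    species = c("sp1", "sp1", "sp1", "sp2", "sp2", "Genus sp.", "sp3", NA),
    family = c("A", "A", "A", "B", "B", "B", "C", "C"),
    longitude = c(0.5, 0.6, 3.5, 0.5, 9.5, 2.5, 10, 4.5),
    latitude = c(0.5, 0.4, 3.5, 0.5, 9.5, 2.5, 10, 4.5),
    source = "toy",
    is_morphospecies = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                         FALSE)
  )
}

# zero-shift deltas: future grids identical to the present one
zero_deltas <- function() {
  d <- default_deltas()
  for (sc in names(d)) {
    d[[sc]]$mean_shift[] <- 0
    d[[sc]]$elevation_gradient[] <- 0
    d[[sc]]$spatial_sd[] <- 0
  }
  d
}

expect_identical_matrices <- function(a, b) {
  expect_equal(a, b, tolerance = 0)
}
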