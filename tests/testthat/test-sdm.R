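# Ensemble SDM machinery: splits, learners, TSS weighting, binarisation.

make_sep_data <- function(n = 120, nbg = 300, seed = 1) {
  # presences and background perfectly separable in the first variable
  set.seed(seed)
  vars <- c("a", "b")
  pres <- data.frame(a = runif(n, 2, 3), b = rnorm(n))
  bg <- data.frame(a = runif(nbg, -3, 1), b = rnorm(nbg))
  list(presences = pres, background = bg, variables = vars)
}

test_that("70/30 split has documented sizes and is a disjoint cover", {
  d <- make_sep_data(100, 200)
  sp <- split_data(d$presences, d$background, seed = 5)
  expect_equal(nrow(sp$train$presences), 70)
  expect_equal(nrow(sp$test$presences), 30)
  expect_equal(nrow(sp$train$background), 140)
  expect_equal(nrow(sp$test$background), 60)

  d25 <- make_sep_data(25, 40)
  sp25 <- split_data(d25$presences, d25$background, seed = 5)
  expect_equal(nrow(sp25$train$presences), 17)  # floor(0.7 * 25)
  expect_equal(nrow(sp25$test$presences), 8)

  both <- rbind(sp$train$presences, sp$test$presences)
  expect_equal(nrow(both), 100)
  expect_equal(nrow(unique(both)), 100)
})

test_that("every technique reaches TSS 1 on separable data", {
  d <- make_sep_data()
  sp <- split_data(d$presences, d$background, seed = 2)
  tf_x <- as.matrix(rbind(sp$test$presences, sp$test$background))
  tf_y <- rep(1:0, c(nrow(sp$test$presences), nrow(sp$test$background)))
  for (tech in c("gbm", "rf", "maxent")) {
    fit <- fit_replicate(tech, sp$train, d$variables, seed = 3)
    pred <- predict(fit, tf_x)
    expect_true(all(pred >= 0 & pred <= 1))
    expect_equal(find_optimal_threshold(pred, tf_y)$tss, 1,
                 tolerance = 1e-9)
  }
})

test_that("degenerate training data are rejected", {
  d <- make_sep_data()
  d$presences$b <- 1
  d$background$b <- 1
  sp <- split_data(d$presences, d$background, seed = 2)
  expect_error(fit_replicate("rf", sp$train, d$variables), "constant")
})

test_that("TSS-weighted averaging follows the stated arithmetic", {
  m1 <- matrix(runif(9), 3, 3)
  m2 <- matrix(runif(9), 3, 3)
  reps <- list(list(tss = 0.8, maps = list(present = m1)),
               list(tss = 0.9, maps = list(present = m2)))
  ens <- ensemble_weighted(reps)
  expect_equal(ens$maps$present, (0.8 * m1 + 0.9 * m2) / 1.7)

  # identical replicates average to themselves
  same <- ensemble_weighted(list(list(tss = 0.8, maps = list(present = m1)),
                                 list(tss = 0.95, maps = list(present = m1))))
  expect_equal(same$maps$present, m1)
})

test_that("the TSS > 0.7 inclusion boundary is strict", {
  m <- matrix(0.5, 2, 2)
  reps <- list(list(tss = 0.69, maps = list(present = m)),
               list(tss = 0.71, maps = list(present = m + 0.1)))
  ens <- ensemble_weighted(reps)
  expect_identical(ens$included, 2L)

  none <- ensemble_weighted(list(list(tss = 0.69, maps = list(present = m)),
                                 list(tss = 0.7, maps = list(present = m))))
  expect_false(none$modeled)
})

test_that("the ensemble map is permutation-invariant and bounded", {
  set.seed(8)
  reps <- lapply(1:4, function(i) {
    list(tss = runif(1, 0.75, 0.95), maps = list(present = matrix(runif(16), 4)))
  })
  e1 <- ensemble_weighted(reps)
  e2 <- ensemble_weighted(rev(reps))
  expect_equal(e1$maps$present, e2$maps$present)
  stack <- simplify2array(lapply(reps, function(r) r$maps$present))
  expect_true(all(e1$maps$present >= apply(stack, 1:2, min) - 1e-12))
  expect_true(all(e1$maps$present <= apply(stack, 1:2, max) + 1e-12))
})

test_that("binarisation treats the threshold as inclusive", {
  ens <- structure(list(modeled = TRUE,
                        maps = list(present = matrix(c(0.4, 0.5, 0.6, NA), 2)),
                        threshold = 0.5),
                   class = "sdm_ensemble")
  b <- binarize(ens)
  expect_identical(as.vector(b$present), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("a fitted species ensemble recovers the niche ranking", {
  cl <- small_climate()
  sp <- small_species()
  # a compact range leaves enough contrast against the background for a
  # high-TSS ensemble; very widespread species cap the achievable TSS
  sizes <- vapply(sp, function(x) sum(x$range$present), 0)
  s <- sp[[which(sizes == min(sizes[sizes >= 40]))[1]]]
  occ <- sample_occurrences(list(s), cl, 200, seed = 21)
  spgr <- grid_spec(cl$present)
  rc <- coord_to_cell(spgr, occ$longitude, occ$latitude)
  cells <- unique((rc$col - 1L) * nrow(cl$present$mask) + rc$row)
  pres <- as.data.frame(climate_values(cl$present, cells))
  bg <- make_background(cl$present, 700, seed = 22)
  ens <- fit_species_ensemble(pres, bg, cl, n_replicates = 2, seed = 23,
                              species_id = s$species_id)
  expect_true(ens$modeled)
  expect_equal(ens$evaluation$species, rep(s$species_id, 6))
  land <- land_cells(cl$present)
  rho <- cor(ens$maps$present[land], s$suitability$present[land],
             method = "spearman")
  expect_gt(rho, 0.5)
  # suitability maps and threshold are valid
  expect_true(all(ens$maps$present[land] >= 0 & ens$maps$present[land] <= 1))
  expect_true(ens$threshold > 0 && ens$threshold < 1)
  # determinism of the whole ensemble fit
  ens2 <- fit_species_ensemble(pres, bg, cl, n_replicates = 2, seed = 23,
                               species_id = s$species_id)
  expect_equal(ens$maps$present, ens2$maps$present)
  expect_equal(ens$threshold, ens2$threshold)
})
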