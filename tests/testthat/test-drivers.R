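# Driver analysis: beta regression engines, all-subsets enumeration,
# Akaike-weight importance.

sim_beta_data <- function(n = 500, beta = c(0, 1.2), phi = 20, seed = 1,
                          p_extra = 0) {
  set.seed(seed)
  x <- rnorm(n)
  eta <- beta[1] + beta[2] * x
  mu <- plogis(eta)
  d <- data.frame(vulnerability = rbeta(n, mu * phi, (1 - mu) * phi),
                  delta_x = x,
                  locality = factor(sample(1:12, n, TRUE)))
  if (p_extra > 0) {
    for (j in seq_len(p_extra)) d[[paste0("delta_noise", j)]] <- rnorm(n)
  }
  d
}

test_that("the ML engine agrees with glmmTMB on a fixed-effects fit", {
  d <- sim_beta_data(n = 400, seed = 3)
  ml <- fit_beta_glmm(d, "delta_x", engine = "ml")
  tmb <- fit_beta_glmm(d, "delta_x", random = FALSE, engine = "glmmTMB")
  ml_b <- ml$coefficients$estimate[ml$coefficients$term == "delta_x"]
  tmb_b <- tmb$coefficients$estimate[tmb$coefficients$term == "delta_x"]
  expect_equal(ml_b, tmb_b, tolerance = 0.02)
  expect_equal(ml$logLik, tmb$logLik, tolerance = 0.01)
  expect_equal(ml$AIC, tmb$AIC, tolerance = 0.1)
})

test_that("a simulated slope is recovered within 2 SE in >= 90% of fits", {
  hits <- 0
  for (k in 1:100) {
    d <- sim_beta_data(n = 500, beta = c(0.2, 0.8), phi = 20, seed = 1000 + k)
    fit <- fit_beta_glmm(d, "delta_x", engine = "ml")
    cf <- fit$coefficients
    b <- cf$estimate[cf$term == "delta_x"]
    se <- cf$std_error[cf$term == "delta_x"]
    if (is.finite(se) && abs(b - 0.8) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("intercept-only fit on symmetric data is centred at zero", {
  set.seed(5)
  y <- rbeta(800, 15, 15)  # symmetric around 0.5
  d <- data.frame(vulnerability = y, locality = factor(rep(1:8, 100)))
  fit <- fit_beta_glmm(d, character(0), engine = "ml")
  expect_lt(abs(fit$coefficients$estimate[1]), 0.05)
})

test_that("adding a pure-noise variable increases AIC on average", {
  diffs <- vapply(1:40, function(k) {
    d <- sim_beta_data(n = 300, seed = 2000 + k, p_extra = 1)
    a0 <- fit_beta_glmm(d, "delta_x", engine = "ml")$AIC
    a1 <- fit_beta_glmm(d, c("delta_x", "delta_noise1"), engine = "ml")$AIC
    a1 - a0
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("glmmTMB engine fits a locality random intercept", {
  d <- sim_beta_data(n = 300, seed = 9)
  fit <- fit_beta_glmm(d, "delta_x", random = TRUE, engine = "glmmTMB")
  expect_true(fit$converged)
  expect_gt(fit$k, 3)  # beta, slope, phi, RE variance
  dd <- d
  dd$locality <- factor(seq_len(nrow(dd)))
  expect_warning(fit_beta_glmm(dd, "delta_x", random = TRUE,
                               engine = "glmmTMB"), "singleton")
})

test_that("all-subsets enumeration matches the combinatorial oracle", {
  subs <- climvuln:::all_subsets(c("a", "b", "c"))
  expect_length(subs, 8)  # 2^3 including the empty model
  oracle <- c(list(character(0)),
              unlist(lapply(1:3, combn, x = c("a", "b", "c"),
                            simplify = FALSE), recursive = FALSE))
  expect_setequal(lapply(subs, sort), lapply(oracle, sort))
})

test_that("a single candidate variable gets wg = 1 and N = n_iter", {
  d <- sim_beta_data(n = 200, beta = c(0, 1.5), seed = 7)
  imp <- iterate_importance(d, variables = "delta_x", n_iter = 5,
                            n_points = 120, seed = 1)
  expect_equal(imp$wg, 1, tolerance = 1e-6)
  expect_equal(imp$N, 5)
})

test_that("the true driver dominates the importance ranking", {
  d <- sim_beta_data(n = 900, beta = c(0, 1.2), phi = 25, seed = 17,
                     p_extra = 2)
  imp <- iterate_importance(d, n_iter = 30, n_points = 400, seed = 2)
  expect_equal(imp$variable[1], "delta_x")
  expect_gt(imp$wg[1], 0.9)
  expect_equal(imp$N[1], attr(imp, "n_iter_completed"))
  expect_true(all(imp$N[-1] < imp$N[1]))
  # positive simulated effect -> positive model-averaged coefficient
  expect_gt(imp$coefficient[1], 0)
  expect_gt(imp$z[1], 2)
})

test_that("importance is invariant to variable order and affine rescaling", {
  d <- sim_beta_data(n = 600, beta = c(0, 1), seed = 23, p_extra = 1)
  imp1 <- iterate_importance(d, variables = c("delta_x", "delta_noise1"),
                             n_iter = 8, n_points = 300, seed = 3)
  imp2 <- iterate_importance(d, variables = c("delta_noise1", "delta_x"),
                             n_iter = 8, n_points = 300, seed = 3)
  expect_equal(imp1[order(imp1$variable), c("wg", "N")],
               imp2[order(imp2$variable), c("wg", "N")],
               ignore_attr = TRUE)
  d10 <- d
  d10$delta_x <- d10$delta_x * 10
  imp3 <- iterate_importance(d10, variables = c("delta_x", "delta_noise1"),
                             n_iter = 8, n_points = 300, seed = 3)
  expect_equal(imp3$wg, imp1$wg, tolerance = 1e-4)
  expect_equal(imp3$N, imp1$N)
  b1 <- imp1$coefficient[imp1$variable == "delta_x"]
  b3 <- imp3$coefficient[imp3$variable == "delta_x"]
  expect_equal(b3, b1 / 10, tolerance = 1e-3)
})

test_that("driver datasets are built from aligned grids", {
  cl <- small_climate()
  sp <- small_species()
  ranges <- setNames(lapply(sp, function(s) s$range$present),
                     vapply(sp, `[[`, "", "species_id"))
  cats <- true_categories(sp, "future_severe")
  vm <- pixel_vulnerability(ranges, cats)
  dd <- build_driver_dataset(vm, cl$present, cl$future_severe)
  expect_equal(nrow(dd), sum(!is.na(vm$relative)))
  # spot-check deltas on random pixels
  set.seed(2)
  for (i in sample(nrow(dd), 10)) {
    cell <- dd$cell[i]
    expect_equal(dd$delta_annual_precip[i],
                 cl$future_severe$values$annual_precip[cell] -
                   cl$present$values$annual_precip[cell])
  }
  same <- build_driver_dataset(vm, cl$present, cl$present)
  delta_cols <- grep("^delta_", names(same))
  expect_true(all(as.matrix(same[, delta_cols]) == 0))
  bad <- cl$future_severe
  bad$extent <- bad$extent + 1
  expect_error(build_driver_dataset(vm, cl$present, bad), "aligned")
})
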