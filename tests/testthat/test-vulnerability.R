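# Range change, IUCN A3 classification, scenario comparison and the
# pixel/family/ecoregion vulnerability summaries.

bin <- function(v, nr = 2) matrix(as.logical(v), nr)

test_that("range change arithmetic", {
  m <- bin(c(1, 1, 0, 0))
  expect_equal(range_change(m, m)$change_fraction, 0)
  expect_equal(range_change(m, bin(c(0, 0, 0, 0)))$change_fraction, -1)
  pres <- matrix(TRUE, 10, 20)               # 200 cells
  fut <- matrix(FALSE, 10, 20); fut[1:90] <- TRUE
  ch <- range_change(pres, fut)
  expect_equal(ch$change_fraction, -0.55)
  expect_equal(ch$lost, 110)
  expect_equal(ch$gained, 0)
  expect_error(range_change(bin(c(0, 0, 0, 0)), m), "empty present")
})

test_that("IUCN A3 classification honours inclusive boundaries", {
  chg <- c(-0.2, -0.3, -0.45, -0.5, -0.55, -0.8, -0.85, -1, 0.4, 0)
  expect_identical(as.character(classify_iucn(chg)),
                   c("LC", "VU", "VU", "EN", "EN", "CR", "CR", "EX",
                     "LC", "LC"))
  expect_error(classify_iucn(-1.2), "impossible")
})

test_that("chi-squared scenario comparison matches hand computation", {
  tab <- rbind(a = c(10, 20), b = c(20, 10))
  res <- scenario_chisq(tab, n_replicates = 2000, seed = 1)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)

  same <- rbind(a = c(30, 20), b = c(30, 20))
  res2 <- scenario_chisq(same, n_replicates = 500, seed = 1)
  expect_equal(res2$statistic, 0)
  expect_gt(res2$p_value, 0.9)

  withzero <- rbind(a = c(10, 20, 0), b = c(20, 10, 0))
  expect_warning(res3 <- scenario_chisq(withzero, 200, seed = 2), "zero")
  expect_equal(ncol(res3$counts), 2)
})

test_that("Monte-Carlo p approximates the asymptotic p on large tables", {
  set.seed(7)
  tab <- matrix(c(120, 100, 95, 140, 105, 90, 130, 110, 100, 115, 95, 105,
                  100, 120, 110, 105, 95, 100, 90, 100), 4, 5)
  mc <- scenario_chisq(tab, n_replicates = 2000, seed = 11)
  asym <- suppressWarnings(chisq.test(tab))$p.value
  expect_lt(abs(mc$p_value - asym), 0.02)
})

test_that("pixel vulnerability is threatened/richness with EX separate", {
  r1 <- bin(c(1, 1, 0, 0)); r2 <- bin(c(1, 0, 1, 0)); r3 <- bin(c(1, 1, 1, 0))
  r4 <- bin(c(1, 0, 0, 0)); r5 <- bin(c(1, 0, 0, 0))
  ranges <- list(s1 = r1, s2 = r2, s3 = r3, s4 = r4, s5 = r5)
  cats <- c(s1 = "VU", s2 = "EN", s3 = "CR", s4 = "LC", s5 = "EX")
  vm <- pixel_vulnerability(ranges, cats)
  expect_equal(vm$richness[1, 1], 5)
  expect_equal(vm$threatened[1, 1], 3)
  expect_equal(vm$relative[1, 1], 0.6)
  expect_equal(vm$extinct[1, 1], 1)
  expect_true(is.na(vm$relative[2, 2]))  # richness 0 masked

  lc <- pixel_vulnerability(ranges, c(s1 = "LC", s2 = "LC", s3 = "LC",
                                      s4 = "LC", s5 = "LC"))
  expect_true(all(lc$relative[lc$richness > 0] == 0))
  allthr <- pixel_vulnerability(ranges, c(s1 = "VU", s2 = "VU", s3 = "CR",
                                          s4 = "EN", s5 = "VU"))
  expect_true(all(allthr$relative[allthr$richness > 0] == 1))
})

test_that("family vulnerability percentages and the diverse subset", {
  cats <- c(a1 = "VU", b1 = "LC", b2 = "LC")
  fam <- c(a1 = "A", b1 = "B", b2 = "B")
  fv <- family_vulnerability(cats, fam, min_species = 30)
  expect_equal(fv$all$pct_threatened[fv$all$family == "A"], 100)
  expect_equal(fv$all$pct_threatened[fv$all$family == "B"], 0)
  expect_equal(nrow(fv$diverse), 0)

  cats40 <- setNames(rep(c("EN", "LC"), c(25, 15)), paste0("x", 1:40))
  fam40 <- setNames(rep("F40", 40), paste0("x", 1:40))
  fv40 <- family_vulnerability(cats40, fam40, min_species = 30)
  expect_equal(fv40$all$pct_threatened, 62.5)
  expect_equal(nrow(fv40$diverse), 1)
  fv31 <- family_vulnerability(cats40[1:30], fam40[1:30], min_species = 30)
  expect_equal(nrow(fv31$diverse), 0)  # strictly more than min_species
})

test_that("ecoregion summary drops small regions and sorts by vulnerability", {
  region <- matrix(NA_integer_, 10, 10)
  region[1:5, ] <- 1L        # 50 pixels
  region[6:8, ] <- 2L        # 30 pixels
  region[9:10, 1:5] <- 3L    # 10 pixels (below min)
  er <- structure(list(region = region,
                       names = c(`1` = "ER001", `2` = "ER002", `3` = "ER003"),
                       montane = c(ER001 = TRUE, ER002 = FALSE,
                                   ER003 = FALSE)),
                  class = "ecoregion_map")
  rel <- matrix(NA_real_, 10, 10)
  rel[!is.na(region)] <- 0.5
  rel[1:5, ] <- 0.8
  rich <- matrix(0, 10, 10); rich[!is.na(region)] <- 4
  vm <- structure(list(relative = rel, richness = rich,
                       threatened = rich * rel, extinct = rich * 0),
                  class = "vulnerability_map")
  out <- ecoregion_summary(vm, er, min_pixels = 30)
  expect_equal(out$region, c("ER001", "ER002"))
  expect_equal(out$mean_proportion, c(0.8, 0.5))
  expect_equal(out$sd, c(0, 0))
  expect_equal(out$n, c(50, 30))
  expect_true(out$montane[1])
  # a 29-pixel region is excluded
  out29 <- ecoregion_summary(vm, er, min_pixels = 31)
  expect_false("ER002" %in% out29$region)
})

test_that("category report percentages, ratios and count conservation", {
  counts <- rbind(
    "future_moderate:unlimited" = c(LC = 50, VU = 20, EN = 15, CR = 10,
                                    EX = 5),
    "future_severe:unlimited" = c(LC = 30, VU = 20, EN = 20, CR = 25, EX = 5))
  rep <- category_report(counts)
  expect_equal(sum(rep$table$n[rep$table$scenario ==
                                 "future_moderate:unlimited"]), 100)
  expect_equal(rep$threatened$n_threatened, c(45, 65))
  expect_equal(rep$threatened$pct_threatened, c(45, 65))
  expect_equal(rep$threatened$pct_en_cr, c(25, 45))
  expect_equal(unname(rep$ratios[["threatened_ratio_unlimited"]]),
               round(65 / 45, 2))
})

test_that("assessments conserve species counts and flag extinction", {
  cl <- small_climate()
  sp <- small_species()
  # build pseudo-ensembles straight from the truth maps
  ens <- lapply(sp, function(s) {
    structure(list(modeled = TRUE, species_id = s$species_id,
                   maps = s$suitability, threshold = 0.5,
                   binary = lapply(s$suitability, function(m) {
                     b <- m >= 0.5; b[is.na(m)] <- FALSE; b
                   })),
              class = "sdm_ensemble")
  })
  asm <- assess_vulnerability(ens, cl, dispersal = "unlimited")
  cnt <- category_counts(asm)
  expect_true(all(rowSums(cnt) == length(sp)))
  expect_true(all((asm$category == "EX") == (asm$future_cells == 0)))
  expect_equal(asm$change_fraction,
               (asm$future_cells - asm$present_cells) / asm$present_cells)
})
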