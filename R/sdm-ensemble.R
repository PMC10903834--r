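# Per-species habitat suitability ensembles: three presence-background
# learners, replicate 70/30 splits, TSS evaluation, TSS-weighted averaging
# and TSS-based binarisation.

#' Sample background (pseudo-absence) points
#'
#' Uniform random cells from the occurrence-bearing region (by default the
#' whole land mask), used as pseudo-absences for presence-background
#' modelling.
#'
#' @param climate a `climate_grid`.
#' @param n number of background points (default 10000).
#' @param seed integer seed.
#' @param region_mask optional logical matrix restricting the sampled area.
#' @return data.frame as from [sample_random_points()].
#' @export
make_background <- function(climate, n = 10000, seed = 1,
                            region_mask = NULL) {
  grid <- climate
  if (!is.null(region_mask)) {
    stopifnot(identical(dim(region_mask), dim(grid$mask)))
    grid$mask <- grid$mask & region_mask
    if (!any(grid$mask)) stop("background region is empty")
  }
  sample_random_points(grid, n = n, seed = seed)
}

#' Stratified train/test split of presences and background
#'
#' Samples `floor(train_frac * n)` rows of each class into the training
#' partition (so the presence:background ratio is preserved) and the rest
#' into the test partition; the two partitions are disjoint and cover all
#' records.
#'
#' @param presences,background data.frames (one row per point).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test`, each a list of `presences` and
#'   `background` data.frames.
#' @export
split_data <- function(presences, background, train_frac = 0.7, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1)
  with_seed(seed, {
    ip <- sample(nrow(presences), floor(train_frac * nrow(presences)))
    ib <- sample(nrow(background), floor(train_frac * nrow(background)))
    list(train = list(presences = presences[ip, , drop = FALSE],
                      background = background[ib, , drop = FALSE]),
         test = list(presences = presences[-ip, , drop = FALSE],
                     background = background[-ib, , drop = FALSE]))
  })
}

# Assemble a modelling frame: covariate matrix, 0/1 labels and
# equal-total-class weights from a split half.
model_frame <- function(part, variables) {
  xp <- as.matrix(part$presences[, variables, drop = FALSE])
  xb <- as.matrix(part$background[, variables, drop = FALSE])
  y <- c(rep(1L, nrow(xp)), rep(0L, nrow(xb)))
  w <- c(rep(0.5 / nrow(xp), nrow(xp)), rep(0.5 / nrow(xb), nrow(xb)))
  list(x = rbind(xp, xb), y = y, w = w * length(y))
}

#' Fit one suitability model replicate
#'
#' Three interchangeable techniques behind one contract (climate vector in,
#' suitability in `[0, 1]` out):
#' * `"gbm"` — gradient-boosted trees (xgboost, logistic objective);
#' * `"rf"` — random forest (ranger probability forest);
#' * `"maxent"` — a lasso-regularised log-linear model on linear +
#'   quadratic climate features (glmnet), the classic approximation of
#'   Maxent as penalised logistic regression on its feature classes.
#'
#' Presences and background get equal total class weight.
#'
#' @param technique one of "gbm", "rf", "maxent".
#' @param train list with `presences` and `background` data.frames (e.g.
#'   one half of [split_data()]).
#' @param variables covariate column names.
#' @param seed integer seed for the stochastic learners.
#' @return object of class `sdm_fit`; use `predict()` to get suitability.
#' @export
fit_replicate <- function(technique = c("gbm", "rf", "maxent"), train,
                          variables, seed = 1) {
  technique <- match.arg(technique)
  mf <- model_frame(train, variables)
  if (length(unique(mf$y)) < 2) stop("training data must contain 2 classes")
  sds <- apply(mf$x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("degenerate training data: constant feature(s) %s",
                 paste(variables[sds == 0], collapse = ", ")))
  }
  model <- with_seed(seed, switch(
    technique,
    gbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                    subsample = 0.8, nthread = 1),
      data = xgboost::xgb.DMatrix(mf$x, label = mf$y, weight = mf$w),
      nrounds = 80, verbose = 0),
    rf = ranger::ranger(
      x = as.data.frame(mf$x), y = factor(mf$y, levels = c(0, 1)),
      probability = TRUE, num.trees = 150, min.node.size = 5,
      case.weights = mf$w, num.threads = 1,
      seed = derive_seed(seed, "ranger")),
    maxent = fit_maxent_like(mf)
  ))
  structure(list(technique = technique, model = model, variables = variables),
            class = "sdm_fit")
}

# Log-quadratic surrogate: penalised logistic regression on linear +
# quadratic climate features with the squared-term coefficients constrained
# to be <= 0, so the fitted response is unimodal (log-concave) in every
# variable -- the Gaussian-niche shape Maxent's quadratic feature class
# encodes.  Unlike the tree learners it keeps decaying when projected into
# novel climates, and the concavity constraint prevents runaway
# "expansion" artefacts when a niche axis is weakly identified.
fit_maxent_like <- function(mf) {
  p <- ncol(mf$x)
  feats <- cbind(mf$x, mf$x^2)
  ctr <- colMeans(feats)
  scl <- apply(feats, 2, stats::sd)
  fz <- sweep(sweep(feats, 2, ctr), 2, scl, "/")
  Z1 <- cbind(1, fz[, 1:p, drop = FALSE])   # intercept + linear
  Z2 <- fz[, p + 1:p, drop = FALSE]         # squared features
  y <- mf$y; w <- mf$w
  # parameters: beta (p+1 free), gamma (p); squared coef = -exp(gamma)
  nll <- function(th) {
    eta <- drop(Z1 %*% th[1:(p + 1)]) - drop(Z2 %*% exp(th[p + 1 + 1:p]))
    # stable log(1 + e^eta)
    lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    -sum(w * (y * eta - lse))
  }
  gr <- function(th) {
    cq <- exp(th[p + 1 + 1:p])
    eta <- drop(Z1 %*% th[1:(p + 1)]) - drop(Z2 %*% cq)
    r <- w * (y - stats::plogis(eta))
    c(-drop(crossprod(Z1, r)), drop(crossprod(Z2, r)) * cq)
  }
  start <- c(stats::qlogis(max(mean(y), 1e-3)), rep(0, p), rep(log(0.5), p))
  fit <- stats::optim(start, nll, gr, method = "BFGS",
                      control = list(maxit = 300))
  cf <- c(fit$par[1:(p + 1)], -exp(fit$par[p + 1 + 1:p]))
  list(coef = cf, center = ctr, scale = scl)
}

#' Predict suitability from a fitted replicate
#'
#' @param object an `sdm_fit`.
#' @param newdata matrix or data.frame of climate covariates.
#' @param ... unused.
#' @return numeric suitability in `[0, 1]`.
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  switch(object$technique,
    gbm = predict(object$model, xgboost::xgb.DMatrix(x)),
    rf = predict(object$model, as.data.frame(x),
                 num.threads = 1)$predictions[, "1"],
    maxent = {
      m <- object$model
      feats <- cbind(x, x^2)
      fz <- cbind(1, sweep(sweep(feats, 2, m$center), 2, m$scale, "/"))
      stats::plogis(drop(fz %*% m$coef))
    })
}

#' TSS-weighted ensemble of model replicates
#'
#' Averages replicate suitability maps cellwise with weights equal to each
#' replicate's TSS, using only replicates with TSS strictly above
#' `tss_min`.  If no replicate passes, the species is flagged as not
#' modeled (to be excluded downstream and counted in the failure log).
#'
#' @param replicates list; each element has `tss` (scalar) and `maps`
#'   (named list of suitability matrices, one per scenario).
#' @param tss_min inclusion cutoff (default 0.7, strict).
#' @return list of class `sdm_ensemble` with `modeled`, `included`
#'   (indices), `weights`, `maps` (weighted-average matrices per scenario)
#'   and `tss` (weighted mean TSS of included replicates).
#' @export
ensemble_weighted <- function(replicates, tss_min = 0.7) {
  stopifnot(length(replicates) >= 1)
  tss <- vapply(replicates, function(r) r$tss, 0)
  included <- which(tss > tss_min)
  if (length(included) == 0) {
    return(structure(list(modeled = FALSE, included = integer(0),
                          weights = numeric(0), maps = NULL, tss = NA_real_),
                     class = "sdm_ensemble"))
  }
  w <- tss[included] / sum(tss[included])
  scen <- names(replicates[[included[1]]]$maps)
  maps <- lapply(scen, function(sc) {
    acc <- 0
    for (k in seq_along(included)) {
      acc <- acc + w[k] * replicates[[included[k]]]$maps[[sc]]
    }
    acc
  })
  names(maps) <- scen
  structure(list(modeled = TRUE, included = included, weights = w,
                 maps = maps, tss = sum(w * tss[included])),
            class = "sdm_ensemble")
}

#' Binarise ensemble suitability into presence/absence maps
#'
#' Applies a single threshold (by default the ensemble's TSS-maximising
#' threshold on present-day data, stored by [fit_species_ensemble()]) to
#' every scenario's suitability map.  Cells exactly at the threshold count
#' as present.
#'
#' @param ensemble an `sdm_ensemble`.
#' @param threshold cutoff; default `ensemble$threshold`.
#' @return named list of logical matrices, one per scenario.
#' @export
binarize <- function(ensemble, threshold = NULL) {
  stopifnot(inherits(ensemble, "sdm_ensemble"), isTRUE(ensemble$modeled))
  if (is.null(threshold)) threshold <- ensemble$threshold
  lapply(ensemble$maps, function(m) {
    b <- m >= threshold
    b[is.na(m)] <- FALSE
    b
  })
}

#' Fit the full replicate ensemble for one species
#'
#' Runs `n_replicates` random 70/30 splits per technique, evaluates each
#' fitted replicate by TSS on its held-out split (threshold at the
#' TSS-maximising value), builds the TSS-weighted ensemble from replicates
#' with TSS above `tss_min`, predicts ensemble suitability over every
#' scenario grid, and stores the ensemble-level TSS-maximising threshold
#' computed on the present-day presence/background data.
#'
#' @param presences data.frame of presence points with the climate
#'   variables as columns (e.g. occurrences joined to the present grid).
#' @param background data.frame of background points (same columns).
#' @param climate named list of `climate_grid`s (must include `present`).
#' @param techniques modelling techniques to use.
#' @param n_replicates splits per technique (default 10).
#' @param tss_min ensemble inclusion cutoff (default 0.7).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer master seed (per-replicate seeds are derived).
#' @param species_id label stored on the result.
#' @return `sdm_ensemble` with, additionally, `species_id`, `threshold`,
#'   `evaluation` (data.frame: technique, replicate, tss, threshold) and
#'   `binary` (present/future logical maps at the stored threshold).
#' @export
fit_species_ensemble <- function(presences, background, climate,
                                 techniques = c("gbm", "rf", "maxent"),
                                 n_replicates = 10, tss_min = 0.7,
                                 train_frac = 0.7, seed = 1,
                                 species_id = "species") {
  stopifnot("present" %in% names(climate))
  variables <- climate$present$variables
  cells <- land_cells(climate$present)
  scen_x <- lapply(climate, climate_values, cells = cells)

  fits <- list()
  eval_rows <- list()
  for (r in seq_len(n_replicates)) {
    spl <- split_data(presences, background, train_frac,
                      seed = derive_seed(seed, species_id, "split", r))
    tf <- model_frame(spl$test, variables)
    for (tech in techniques) {
      fit <- fit_replicate(tech, spl$train, variables,
                           seed = derive_seed(seed, species_id, tech, r))
      pred <- predict(fit, tf$x)
      opt <- find_optimal_threshold(pred, tf$y)
      fits[[length(fits) + 1]] <- list(fit = fit, tss = opt$tss,
                                       threshold = opt$threshold)
      eval_rows[[length(eval_rows) + 1]] <- data.frame(
        species = species_id, technique = tech, replicate = r,
        tss = opt$tss, threshold = opt$threshold)
    }
  }
  evaluation <- do.call(rbind, eval_rows)
  tss <- vapply(fits, function(f) f$tss, 0)
  included <- which(tss > tss_min)

  if (length(included) == 0) {
    ens <- structure(list(modeled = FALSE, included = integer(0),
                          weights = numeric(0), maps = NULL, tss = NA_real_),
                     class = "sdm_ensemble")
    ens$species_id <- species_id
    ens$evaluation <- evaluation
    return(ens)
  }

  # predict scenario maps only for the included replicates
  replicates <- lapply(seq_along(fits), function(k) {
    if (!k %in% included) return(list(tss = tss[k], maps = NULL))
    maps <- lapply(names(climate), function(sc) {
      m <- matrix(NA_real_, nrow(climate$present$mask),
                  ncol(climate$present$mask))
      m[cells] <- predict(fits[[k]]$fit, scen_x[[sc]])
      m
    })
    names(maps) <- names(climate)
    list(tss = tss[k], maps = maps)
  })
  ens <- ensemble_weighted(replicates, tss_min)
  ens$species_id <- species_id
  ens$evaluation <- evaluation

  # ensemble-level binarisation threshold: TSS-maximising cutoff of the
  # ensemble's predictions over the full present-day presence/background
  # set, so the threshold is on the same score scale as the scenario maps
  full <- model_frame(list(presences = presences, background = background),
                      variables)
  acc <- 0
  for (k in seq_along(ens$included)) {
    acc <- acc + ens$weights[k] * predict(fits[[ens$included[k]]]$fit, full$x)
  }
  opt <- find_optimal_threshold(acc, full$y)
  ens$threshold <- opt$threshold
  ens$ensemble_tss <- opt$tss
  ens$binary <- binarize(ens)
  ens
}
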