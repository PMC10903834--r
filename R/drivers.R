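# Climatic drivers of relative vulnerability: resampled all-subsets beta
# regression with AIC selection and Akaike-weight importance.

#' Build the per-pixel driver dataset
#'
#' One record per occupied pixel of the vulnerability map, with the
#' relative vulnerability as response, the future-minus-present change of
#' every climate variable as candidate predictors, and a locality id (the
#' pixel's ecoregion when supplied, otherwise the pixel itself).
#'
#' @param vmap a `vulnerability_map`.
#' @param climate_present,climate_future aligned `climate_grid`s.
#' @param ecoregions optional `ecoregion_map` supplying locality blocks.
#' @return data.frame with `cell`, `vulnerability`, `locality` and one
#'   `delta_<variable>` column per climate variable.
#' @export
build_driver_dataset <- function(vmap, climate_present, climate_future,
                                 ecoregions = NULL) {
  stopifnot(inherits(vmap, "vulnerability_map"))
  if (!identical(dim(climate_present$mask), dim(climate_future$mask)) ||
      !identical(climate_present$extent, climate_future$extent) ||
      !identical(dim(vmap$relative), dim(climate_present$mask))) {
    stop("vulnerability map and climate grids are not aligned")
  }
  cells <- which(!is.na(vmap$relative))
  out <- data.frame(cell = cells, vulnerability = vmap$relative[cells])
  for (v in climate_present$variables) {
    out[[paste0("delta_", v)]] <-
      climate_future$values[[v]][cells] - climate_present$values[[v]][cells]
  }
  out$locality <- if (!is.null(ecoregions)) {
    factor(ecoregions$region[cells])
  } else {
    factor(cells)
  }
  out
}

# Shrink a [0,1] response off the boundary (Smithson-Verkuilen transform).
shrink_unit <- function(y, n = length(y)) (y * (n - 1) + 0.5) / n

# Maximum-likelihood beta regression with logit mean link, fixed effects
# only.  Analytic gradient; returns coefficients, std errors, logLik, AIC.
beta_ml <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  nll <- function(th) {
    eta <- drop(X %*% th[1:p]); phi <- exp(th[p + 1])
    mu <- stats::plogis(eta)
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  gr <- function(th) {
    eta <- drop(X %*% th[1:p]); phi <- exp(th[p + 1])
    mu <- stats::plogis(eta)
    a <- mu * phi; b <- (1 - mu) * phi
    dl_dmu <- phi * (digamma(b) - digamma(a) + log(y) - log1p(-y))
    dmu_deta <- mu * (1 - mu)
    g_beta <- -drop(crossprod(X, dl_dmu * dmu_deta))
    dl_dphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
      mu * log(y) + (1 - mu) * log1p(-y)
    c(g_beta, -phi * sum(dl_dphi))
  }
  # starting values: logit-scale least squares, moment estimate of phi
  z <- stats::qlogis(y)
  b0 <- tryCatch(stats::lm.fit(X, z)$coefficients, error = function(e) rep(0, p))
  b0[!is.finite(b0)] <- 0
  mu0 <- stats::plogis(drop(X %*% b0))
  v0 <- stats::var(y - mu0)
  phi0 <- min(500, max(1, mean(mu0 * (1 - mu0)) / max(v0, 1e-6) - 1))
  fit <- stats::optim(c(b0, log(phi0)), nll, gr, method = "BFGS",
                      control = list(maxit = 200))
  H <- stats::optimHess(fit$par, nll, gr)
  se <- rep(NA_real_, p + 1)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(vc)) {
    dg <- diag(vc)
    good <- is.finite(dg) & dg > 0
    se[good] <- sqrt(dg[good])
  }
  ok <- all(is.finite(se))
  list(coefficients = data.frame(term = c(colnames(X), "log_phi"),
                                 estimate = unname(fit$par),
                                 std_error = unname(se)),
       logLik = -fit$value, k = p + 1, AIC = 2 * (p + 1) + 2 * fit$value,
       phi = exp(fit$par[p + 1]),
       converged = fit$convergence == 0 && ok)
}

#' Fit a beta regression of relative vulnerability on climate changes
#'
#' Beta error distribution with logit mean link, fitted by maximum
#' likelihood.  The response is first shrunk off the `[0, 1]` boundary with
#' the standard transform `y' = (y (n - 1) + 0.5) / n`.  Two engines:
#'
#' * `"glmmTMB"` (default): glmmTMB with a locality random intercept
#'   (`~ ... + (1 | locality)`).  When every locality is a singleton the
#'   random intercept is unidentifiable and the model falls back to fixed
#'   effects with a warning.
#' * `"ml"`: the package's direct maximum-likelihood fit (fixed effects
#'   only, analytic gradient) — orders of magnitude faster, used by
#'   [iterate_importance()] for the all-subsets scan.
#'
#' @param data data.frame from [build_driver_dataset()] (needs
#'   `vulnerability`, `locality` and the predictor columns).
#' @param variables character vector of predictor columns (possibly empty
#'   for the intercept-only model).
#' @param random include the locality random intercept (glmmTMB engine).
#' @param engine "glmmTMB" or "ml".
#' @return list with `coefficients` (term, estimate, std_error), `logLik`,
#'   `AIC`, `k`, `converged`, `engine`.
#' @export
fit_beta_glmm <- function(data, variables = NULL, random = TRUE,
                          engine = c("glmmTMB", "ml")) {
  engine <- match.arg(engine)
  if (nrow(data) < 10) stop("need at least 10 records")
  y <- shrink_unit(data$vulnerability)
  if (engine == "ml") {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(data[, variables, drop = FALSE]))
    return(c(beta_ml(X, y), list(engine = "ml")))
  }
  df <- data
  df$.y <- y
  rhs <- if (length(variables) > 0) paste(variables, collapse = " + ") else "1"
  use_re <- random
  if (use_re && !anyDuplicated(data$locality)) {
    warning("all localities are singletons; dropping the random intercept")
    use_re <- FALSE
  }
  fml <- stats::as.formula(paste(
    ".y ~", rhs, if (use_re) "+ (1 | locality)" else ""))
  fit <- glmmTMB::glmmTMB(fml, data = df, family = glmmTMB::beta_family())
  sm <- summary(fit)$coefficients$cond
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  list(coefficients = data.frame(term = rownames(sm),
                                 estimate = unname(sm[, "Estimate"]),
                                 std_error = unname(sm[, "Std. Error"])),
       logLik = ll, AIC = 2 * k - 2 * ll, k = k,
       converged = isTRUE(fit$sdr$pdHess), engine = "glmmTMB", fit = fit)
}

# All subsets of `variables`, from the intercept-only model upward.
all_subsets <- function(variables) {
  p <- length(variables)
  subsets <- list(character(0))
  for (size in seq_len(p)) {
    cmb <- utils::combn(variables, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  subsets
}

#' Resampled all-subsets importance of vulnerability drivers
#'
#' Repeats, `n_iter` times: draw `n_points` random records without
#' replacement; fit beta regressions for every subset of the candidate
#' variables (including the intercept-only model); compute Akaike weights
#' `w_m = exp(-dAIC_m / 2) / sum(...)` over the candidate set and select
#' the best (lowest-AIC) model.  Importance of a variable is summarised
#' as:
#' * `wg` — the mean over iterations of the summed Akaike weight of all
#'   models containing the variable;
#' * `N`  — the number of iterations whose best model contains it.
#'
#' Model-averaged coefficients are conditional (averaged, with renormalised
#' weights, over the models containing the variable) with unconditional
#' standard errors that add the between-model spread, averaged over
#' iterations.
#'
#' Fits that fail to converge trigger a resample of the iteration (up to
#' `max_retry` times), after which the iteration is skipped and logged.
#'
#' @param data driver dataset (see [build_driver_dataset()]).
#' @param variables candidate predictor columns; default all `delta_*`.
#' @param n_iter iterations (default 1000).
#' @param n_points records sampled per iteration (default 500).
#' @param seed integer master seed; per-iteration seeds are derived.
#' @param engine fitting engine passed to [fit_beta_glmm()]; default the
#'   fast `"ml"` engine.
#' @param wg_mode `"summed"` (default, as defined above) or `"best_only"`
#'   (mean weight of the best model over the iterations it contains the
#'   variable).
#' @param max_retry resamples allowed per iteration on non-convergence.
#' @return data.frame of class `driver_importance`: variable, wg, N,
#'   coefficient, std_error, z, p, sorted by descending wg.  Attributes:
#'   `n_iter_completed`, `skipped`, `engine`, `n_models`.
#' @export
iterate_importance <- function(data, variables = NULL, n_iter = 1000,
                               n_points = 500, seed = 1,
                               engine = c("ml", "glmmTMB"),
                               wg_mode = c("summed", "best_only"),
                               max_retry = 3) {
  engine <- match.arg(engine)
  wg_mode <- match.arg(wg_mode)
  if (is.null(variables)) {
    variables <- grep("^delta_", names(data), value = TRUE)
  }
  if (nrow(data) < n_points) stop("dataset smaller than n_points")
  subsets <- all_subsets(variables)
  contains <- vapply(variables, function(v)
    vapply(subsets, function(s) v %in% s, TRUE), logical(length(subsets)))
  p <- length(variables)

  sum_w <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, variables))
  best_w <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, variables))
  best_contains <- matrix(FALSE, n_iter, p, dimnames = list(NULL, variables))
  coef_it <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, variables))
  se_it <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, variables))
  skipped <- integer(0)

  for (i in seq_len(n_iter)) {
    done <- FALSE
    for (try_k in 0:max_retry) {
      rows <- with_seed(derive_seed(seed, "iter", i, try_k),
                        sample(nrow(data), n_points))
      sub <- data[rows, , drop = FALSE]
      fits <- lapply(subsets, function(vs) {
        tryCatch(fit_beta_glmm(sub, vs, engine = engine),
                 error = function(e) list(converged = FALSE))
      })
      if (all(vapply(fits, function(f) isTRUE(f$converged), TRUE))) {
        done <- TRUE
        break
      }
    }
    if (!done) {
      skipped <- c(skipped, i)
      next
    }
    aic <- vapply(fits, `[[`, 0, "AIC")
    w <- exp(-(aic - min(aic)) / 2)
    w <- w / sum(w)
    best <- which.min(aic)
    for (j in seq_len(p)) {
      has <- contains[, j]
      sum_w[i, j] <- sum(w[has])
      best_contains[i, j] <- has[best]
      best_w[i, j] <- if (has[best]) w[best] else NA_real_
      wc <- w[has] / sum(w[has])
      bm <- vapply(which(has), function(m) {
        cf <- fits[[m]]$coefficients
        cf$estimate[cf$term == variables[j]]
      }, 0)
      sm <- vapply(which(has), function(m) {
        cf <- fits[[m]]$coefficients
        cf$std_error[cf$term == variables[j]]
      }, 0)
      cbar <- sum(wc * bm)
      coef_it[i, j] <- cbar
      se_it[i, j] <- sum(wc * sqrt(sm^2 + (bm - cbar)^2))
    }
  }

  ok <- setdiff(seq_len(n_iter), skipped)
  if (length(ok) == 0) stop("no iteration completed")
  wg <- if (wg_mode == "summed") {
    colMeans(sum_w[ok, , drop = FALSE])
  } else {
    apply(best_w[ok, , drop = FALSE], 2, mean, na.rm = TRUE)
  }
  wg[is.nan(wg)] <- 0
  coefficient <- colMeans(coef_it[ok, , drop = FALSE])
  std_error <- colMeans(se_it[ok, , drop = FALSE])
  z <- abs(coefficient) / std_error
  out <- data.frame(variable = variables, wg = unname(wg),
                    N = unname(colSums(best_contains[ok, , drop = FALSE])),
                    coefficient = unname(coefficient),
                    std_error = unname(std_error), z = unname(z),
                    p = unname(2 * stats::pnorm(-z)))
  out <- out[order(-out$wg, -out$N), ]
  rownames(out) <- NULL
  attr(out, "n_iter_completed") <- length(ok)
  attr(out, "skipped") <- skipped
  attr(out, "engine") <- engine
  attr(out, "n_models") <- length(subsets)
  class(out) <- c("driver_importance", class(out))
  out
}
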