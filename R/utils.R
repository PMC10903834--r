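# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions do not perturb the user's random stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps (master seed, context strings/indices) to a seed in
#' [1, 2^31 - 2], so that each species / technique / replicate / iteration
#' gets its own independent, reproducible stream.
#'
#' @param seed master integer seed.
#' @param ... context labels (coerced to character).
#' @return integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  lab <- paste(c(format(seed), vapply(list(...), paste, "", collapse = "|")),
               collapse = "|")
  h <- 0
  for (k in utf8ToInt(lab)) h <- (h * 131 + k) %% 2147483629
  as.integer((h %% 2147483645) + 1)
}

#' Round half away from zero
#'
#' Rounds .5 up (for positive values), matching how percentages are usually
#' reported in ecological papers, rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Stop unless all named arguments are single finite numbers.
check_scalar <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}
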