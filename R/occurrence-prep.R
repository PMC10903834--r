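# Occurrence cleaning with step-by-step provenance: drop records not
# identified to species, deduplicate per grid pixel, drop rare species.
# Each step appends a row to a provenance log carried on the table.

prep_counts <- function(tab) {
  data.frame(
    n_families = length(unique(tab$family[!is.na(tab$family)])),
    n_genera = if ("genus" %in% names(tab))
      length(unique(tab$genus[!is.na(tab$genus)])) else NA_integer_,
    n_species = length(unique(tab$species[!is.na(tab$species)])),
    n_records = nrow(tab)
  )
}

append_log <- function(tab, step) {
  log <- attr(tab, "prep_log")
  row <- cbind(data.frame(step = step), prep_counts(tab))
  attr(tab, "prep_log") <- if (is.null(log)) row else rbind(log, row)
  tab
}

#' Start an occurrence-prep provenance log
#'
#' Records the input table's counts as the first log row.  All prep
#' operations append further rows; retrieve the log with
#' [summarize_prep()].
#'
#' @param tab occurrence data.frame with at least `species`, `family`,
#'   `longitude`, `latitude`; optionally `genus`, `is_morphospecies`.
#' @param step label for the initial row.
#' @return the table with a `prep_log` attribute.
#' @export
start_prep <- function(tab, step = "input") {
  attr(tab, "prep_log") <- NULL
  append_log(tab, step)
}

#' Drop records not identified to species (morphospecies)
#'
#' @param tab occurrence table; records with `is_morphospecies = TRUE` (or
#'   missing species id) are discarded.
#' @return filtered table (log row appended).  Warns if nothing remains.
#' @export
drop_morphospecies <- function(tab) {
  if (nrow(tab) == 0) stop("occurrence table is empty")
  keep <- !is.na(tab$species)
  if ("is_morphospecies" %in% names(tab)) {
    keep <- keep & !tab$is_morphospecies %in% TRUE
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no records identified to species remain")
  attr(out, "prep_log") <- attr(tab, "prep_log")
  append_log(out, "drop_morphospecies")
}

#' Deduplicate occurrences within grid pixels
#'
#' Keeps one record per (species, grid cell); the first record in input
#' order wins, so the result is deterministic.  Cells are half-open
#' intervals defined by the grid origin and cell size (coordinates on the
#' upper extent edge fall in the last cell).
#'
#' @param tab occurrence table.
#' @param spec a [grid_spec()] defining the binning grid.
#' @return deduplicated table (log row appended).
#' @export
deduplicate_by_pixel <- function(tab, spec) {
  rc <- coord_to_cell(spec, tab$longitude, tab$latitude)
  bad <- which(is.na(rc$row) | is.na(rc$col))
  if (length(bad) > 0) {
    stop(sprintf("records outside the grid extent at rows: %s",
                 paste(utils::head(bad, 20), collapse = ", ")))
  }
  key <- paste(tab$species, rc$row, rc$col, sep = "\r")
  out <- tab[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "prep_log") <- attr(tab, "prep_log")
  append_log(out, "deduplicate_by_pixel")
}

#' Drop species below a minimum number of unique presences
#'
#' The boundary is inclusive: species with exactly `min_n` records are
#' retained.  Apply after [deduplicate_by_pixel()] so counts refer to
#' unique pixels.
#'
#' @param tab occurrence table.
#' @param min_n minimum records per retained species (default 25).
#' @return list with `table` (filtered, log row appended) and `dropped`
#'   (character vector of removed species).
#' @export
filter_min_occurrences <- function(tab, min_n = 25) {
  cnt <- table(tab$species)
  dropped <- names(cnt)[cnt < min_n]
  out <- tab[!tab$species %in% dropped, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "prep_log") <- attr(tab, "prep_log")
  out <- append_log(out, sprintf("filter_min_occurrences(%d)", min_n))
  list(table = out, dropped = dropped)
}

#' Provenance table of occurrence-prep steps
#'
#' One row per step with the number of families, genera, species and
#' records remaining, in the order the steps were applied.
#'
#' @param tab occurrence table carrying a prep log.
#' @return data.frame with `step`, `n_families`, `n_genera`, `n_species`,
#'   `n_records`.
#' @export
summarize_prep <- function(tab) {
  log <- attr(tab, "prep_log")
  if (is.null(log)) stop("no prep log: start with start_prep()")
  rownames(log) <- NULL
  log
}
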