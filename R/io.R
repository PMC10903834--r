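# Plain-text interchange for occurrence tables.

#' Write an occurrence table to CSV
#'
#' Columns `species,family,longitude,latitude` first (the interchange
#' format), any remaining columns after.
#'
#' @param tab occurrence data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(tab, path) {
  lead <- intersect(c("species", "family", "longitude", "latitude"),
                    names(tab))
  rest <- setdiff(names(tab), lead)
  utils::write.csv(tab[, c(lead, rest), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an occurrence table from CSV
#'
#' @param path CSV path with at least `species`, `longitude`, `latitude`.
#' @return data.frame.
#' @export
read_occurrences <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop(sprintf("occurrence CSV missing columns: %s",
                 paste(miss, collapse = ", ")))
  }
  tab
}
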