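# Bundled data and interval-CSV input/output.

#' Battery lifetime interval data
#'
#' Lifetimes (in units of 100 hours) of 23 batteries recorded as intervals
#' \code{[lower, upper]} reflecting measurement indeterminacy; the standard
#' application dataset for interval-valued lifetime models. Shipped as a
#' plain-text CSV under \code{inst/extdata/battery_lifetimes.csv}.
#'
#' @return A tibble with 23 rows and columns `lower`, `upper`.
#' @examples
#' battery_lifetimes()
#' @export
battery_lifetimes <- function() {
  path <- system.file("extdata", "battery_lifetimes.csv", package = "nnowiw",
                      mustWork = TRUE)
  read_interval_csv(path)
}

#' Read and write interval samples as CSV
#'
#' The interval CSV dialect has a header `lower,upper` and one observation
#' per row (decimal point, UTF-8). A single-column file is accepted and
#' promoted to degenerate intervals. Row order is preserved; invalid rows
#' (lower > upper, non-numeric) raise an error naming the row.
#'
#' @param path file path.
#' @return `read_interval_csv()` returns a validated interval-sample tibble;
#'   `write_interval_csv()` returns `path` invisibly.
#' @export
read_interval_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  nonnum <- names(raw)[!vapply(raw, is.numeric, logical(1))]
  if (length(nonnum)) {
    bad <- which(!stats::complete.cases(
      suppressWarnings(as.data.frame(lapply(raw, as.numeric)))))
    abort(sprintf("Non-numeric values in column(s) %s (row %s).",
                  paste(nonnum, collapse = ", "),
                  paste(bad, collapse = ", ")))
  }
  as_interval_sample(raw)
}

#' @rdname read_interval_csv
#' @param data an interval sample (see [as_interval_sample()]).
#' @export
write_interval_csv <- function(data, path) {
  data <- as_interval_sample(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
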