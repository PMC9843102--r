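#' Min-max normalize an indicator column
#'
#' Each raw shipping indicator is rescaled to \[0, 1\] by subtracting the
#' column minimum and dividing by the range. For `"lower_better"` indicators
#' (e.g. number of transshipments, where fewer transfers mean more direct
#' connectivity) the scale is flipped so that 1 is always "best". A
#' degenerate column (max = min) carries no information and maps to all
#' zeros, with a warning.
#'
#' @param values Numeric vector of raw indicator values (finite, non-empty).
#' @param orientation `"higher_better"` or `"lower_better"`.
#' @return Numeric vector in \[0, 1\], same length as `values`.
#' @export
#' @examples
#' normalize_indicator(c(2, 4, 6), "higher_better") # 0, 0.5, 1
#' normalize_indicator(c(0, 1, 2), "lower_better")  # 1, 0.5, 0
normalize_indicator <- function(values,
                                orientation = c("higher_better", "lower_better")) {
  orientation <- match.arg(orientation)
  if (length(values) == 0L) stopf("normalize_indicator: empty value vector")
  if (!is.numeric(values) || any(!is.finite(values))) {
    stopf("normalize_indicator: values must be finite numeric")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warning("degenerate indicator range (max = min); normalized to 0",
            call. = FALSE)
    return(rep(0, length(values)))
  }
  out <- (values - rng[1]) / (rng[2] - rng[1])
  if (orientation == "lower_better") out <- 1 - out
  out
}

#' Default indicator orientations
#'
#' Transshipment count is treated as `"lower_better"` (fewer cargo transfers
#' indicate a more direct connection); the remaining four indicators —
#' common direct connections, common one-transshipment connections, carrier
#' competition, and largest-ship size — are `"higher_better"`.
#'
#' @return Named character vector mapping indicator name to orientation.
#' @export
default_orientations <- function() {
  c(transshipments = "lower_better",
    common_direct = "higher_better",
    common_one_tranship = "higher_better",
    competition = "higher_better",
    max_ship_size = "higher_better")
}

#' Compute the Liner Shipping Bilateral Connectivity Index
#'
#' The LSBCI of a country pair is the simple average of five min-max
#' normalized shipping indicators: minimum transshipments between the pair,
#' countries with direct routes to both, common one-transshipment
#' connections, carrier competition on the route, and the size of the
#' largest ship on the route with the fewest carriers. Each indicator is
#' normalized across *all* pairs in the supplied table (the table is the
#' normalization population), then the five normalized values are averaged.
#'
#' @param table Indicator pair table from
#'   `read_pair_table(kind = "indicators")`: columns `origin`, `partner`,
#'   and the five indicators.
#' @param orientations Named character map of indicator name to
#'   `"higher_better"` / `"lower_better"`; defaults to
#'   [default_orientations()].
#' @return A symmetric connectivity matrix (see [pairs_to_matrix()]) with
#'   all values in \[0, 1\].
#' @export
compute_lsbci <- function(table, orientations = default_orientations()) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stopf("compute_lsbci: empty indicator table")
  ind <- indicator_names()
  missing_cols <- setdiff(ind, names(table))
  if (length(missing_cols)) {
    stopf("compute_lsbci: missing indicator column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(ind, names(orientations))
  if (length(bad)) {
    stopf("compute_lsbci: no orientation given for: %s",
          paste(bad, collapse = ", "))
  }
  norm <- vapply(ind, function(col) {
    normalize_indicator(table[[col]], orientations[[col]])
  }, numeric(nrow(table)))
  norm <- matrix(norm, nrow = nrow(table))
  lsbci <- rowMeans(norm)
  pairs_to_matrix(data.frame(origin = table$origin, partner = table$partner,
                             value = lsbci, stringsAsFactors = FALSE))
}
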