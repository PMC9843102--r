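#' Likelihood of introduction through maritime trade for one country pair
#'
#' The LASIMTI of a pair is its bilateral connectivity (LSBCI) divided by
#' the days at sea between the two countries' principal ports: strong,
#' fast connections score high; weak or slow ones score low.
#'
#' @param lsbci Connectivity value(s) in \[0, 1\].
#' @param days Days at sea, strictly positive.
#' @return `lsbci / days`, vectorized.
#' @export
#' @examples
#' compute_lasimti(0.4, 2) # 0.2
compute_lasimti <- function(lsbci, days) {
  if (any(!is.finite(lsbci)) || any(lsbci < 0 | lsbci > 1)) {
    stopf("compute_lasimti: lsbci must lie in [0, 1]")
  }
  if (any(!is.finite(days)) || any(days <= 0)) {
    stopf("compute_lasimti: days must be strictly positive")
  }
  lsbci / days
}

#' Sum LASIMTI from a target country over all source populations
#'
#' Adds up `lsbci(target, s) / days(target, s)` over every source country
#' `s` for which *both* the connectivity and the transit-time matrix record
#' the pair. Pairs absent from either matrix contribute zero (real bilateral
#' trade data is sparse) and are reported via [message()]; if no source pair
#' exists at all the sum is zero with a warning.
#'
#' @param target Alpha-3 code of the country being scored.
#' @param sources Character vector of source-population codes (must not
#'   contain `target`).
#' @param conn Symmetric connectivity matrix (`NA` = no recorded pair).
#' @param times Symmetric days-at-sea matrix (`NA` = no recorded pair).
#' @return The LASIMTI sum, a non-negative scalar.
#' @export
sum_lasimti <- function(target, sources, conn, times) {
  target <- to_country_code(target)
  sources <- to_country_code(sources)
  if (target %in% sources) {
    stopf("sum_lasimti: target %s is itself a source population", target)
  }
  total <- 0
  n_used <- 0L
  for (s in sources) {
    l <- lookup_pair(conn, target, s)
    d <- lookup_pair(times, target, s)
    if (is.na(l) || is.na(d)) {
      message(sprintf("no %s pair recorded for %s-%s; contributes 0",
                      if (is.na(l)) "connectivity" else "transit-time",
                      target, s))
      next
    }
    total <- total + compute_lasimti(l, d)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    warning(sprintf("%s has no recorded pair with any source; LASIMTI sum is 0",
                    target), call. = FALSE)
  }
  total
}

lookup_pair <- function(m, a, b) {
  if (!(a %in% rownames(m)) || !(b %in% colnames(m))) return(NA_real_)
  m[a, b]
}

#' Rank target countries by their LASIMTI sum
#'
#' Computes [sum_lasimti()] for every target and assigns ranks in descending
#' order of the sum. Exact-value ties are broken alphabetically by country
#' code so output files are reproducible.
#'
#' @param targets Character vector of countries to rank (codes or names);
#'   any country also listed in `sources` is excluded.
#' @param sources Source-population codes.
#' @inheritParams sum_lasimti
#' @param quiet Suppress per-pair missing-data messages (default `TRUE`;
#'   the count of missing pairs is still recorded in the result's
#'   `"n_missing_pairs"` attribute).
#' @return A risk table: data frame with columns `country`, `lasimti_sum`,
#'   `rank`, sorted by rank.
#' @export
rank_by_lasimti <- function(targets, sources, conn, times, quiet = TRUE) {
  targets <- to_country_code(targets)
  sources <- to_country_code(sources)
  targets <- setdiff(unique(targets), sources)
  if (length(targets) == 0L) stopf("rank_by_lasimti: empty target set")
  n_missing <- 0L
  sums <- vapply(targets, function(tc) {
    withCallingHandlers(
      suppressWarnings(sum_lasimti(tc, sources, conn, times)),
      message = function(m) {
        n_missing <<- n_missing + 1L
        if (quiet) invokeRestart("muffleMessage")
      })
  }, numeric(1))
  ord <- order(-sums, targets)
  out <- data.frame(country = targets[ord],
                    lasimti_sum = unname(sums[ord]),
                    rank = seq_along(targets),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_missing_pairs") <- n_missing
  out
}

#' Re-rank a risk table with the Habitat Suitability Index
#'
#' Introduction likelihood (LASIMTI) measures whether the vector can
#' *arrive*; habitat suitability measures whether it can *establish*. Two
#' combination strategies are offered:
#'
#' * `"hsi_then_lasimti"` (default) — lexicographic: rank by HSI descending,
#'   breaking ties by LASIMTI sum descending.
#' * `"product"` — rank by the composite `lasimti_sum * hsi` descending.
#'
#' Under both strategies, countries with no HSI estimate are placed after
#' every country that has one, ordered among themselves by LASIMTI sum;
#' remaining exact ties break alphabetically by code.
#'
#' @param table Risk table from [rank_by_lasimti()].
#' @param hsi Data frame with columns `country`, `hsi` (see
#'   [read_hsi_table()]); countries absent from it are treated as missing.
#' @param strategy `"hsi_then_lasimti"` or `"product"`.
#' @return The risk table with added `hsi`, `composite` and recomputed
#'   `rank`, sorted by rank.
#' @export
rank_with_hsi <- function(table, hsi,
                          strategy = c("hsi_then_lasimti", "product")) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(table), "lasimti_sum" %in% names(table))
  stopifnot(is.data.frame(hsi), all(c("country", "hsi") %in% names(hsi)))
  out <- table
  out$hsi <- hsi$hsi[match(out$country, to_country_code(hsi$country))]
  out$composite <- if (strategy == "product") out$lasimti_sum * out$hsi
                   else NA_real_
  has_hsi <- !is.na(out$hsi)
  key1 <- if (strategy == "product") out$composite else out$hsi
  # missing-HSI countries sort after all HSI-bearing ones, by LASIMTI sum
  ord <- order(!has_hsi,
               ifelse(has_hsi, -key1, 0),
               -out$lasimti_sum,
               out$country)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("country", "lasimti_sum", "hsi", "composite", "rank")]
}
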