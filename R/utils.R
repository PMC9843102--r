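# internal helpers shared across modules

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert a pair table to a symmetric matrix
#'
#' Bilateral tables (connectivity, days at sea) are stored unordered; this
#' builds the symmetric country-by-country matrix used by the ranking and
#' network functions. Absent pairs become `NA` (no recorded connection);
#' the diagonal is always `NA` (self-pairs are meaningless).
#'
#' @param pairs Data frame with columns `origin`, `partner`, `value`.
#' @param countries Optional character vector fixing the row/column set
#'   (defaults to the countries present in `pairs`).
#' @return Symmetric numeric matrix with dimnames set to country codes.
#' @export
pairs_to_matrix <- function(pairs, countries = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("origin", "partner", "value") %in% names(pairs)))
  if (is.null(countries)) {
    countries <- sort(unique(c(pairs$origin, pairs$partner)))
  }
  m <- matrix(NA_real_, length(countries), length(countries),
              dimnames = list(countries, countries))
  keep <- pairs$origin %in% countries & pairs$partner %in% countries
  p <- pairs[keep, , drop = FALSE]
  m[cbind(p$origin, p$partner)] <- p$value
  m[cbind(p$partner, p$origin)] <- p$value
  diag(m) <- NA_real_
  m
}

#' Convert a symmetric matrix back to an unordered pair table
#'
#' Inverse of [pairs_to_matrix()]: emits one row per non-`NA` unordered pair,
#' ordered deterministically (origin, then partner, alphabetically).
#'
#' @param m Symmetric numeric matrix with country-code dimnames.
#' @return Data frame with columns `origin`, `partner`, `value`.
#' @export
matrix_to_pairs <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)),
            identical(rownames(m), colnames(m)))
  cn <- rownames(m)
  idx <- which(upper.tri(m) & !is.na(m), arr.ind = TRUE)
  out <- data.frame(origin  = cn[idx[, 1]],
                    partner = cn[idx[, 2]],
                    value   = m[idx],
                    stringsAsFactors = FALSE)
  out[order(out$origin, out$partner), , drop = FALSE]
}
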