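#' Read and validate a bilateral country-pair table
#'
#' Reads a CSV of unordered country pairs. Three table kinds are supported:
#'
#' * `"lsbci"` — columns `origin, partner, value`; values must lie in
#'   \[0, 1\] (a bilateral connectivity index).
#' * `"days"` — columns `origin, partner, value`; values are days at sea and
#'   must be strictly positive.
#' * `"indicators"` — columns `origin, partner` plus the five raw LSBCI
#'   indicators `transshipments, common_direct, common_one_tranship,
#'   competition, max_ship_size`, all finite and non-negative.
#'
#' Country identifiers may be alpha-3 codes or registry names (see
#' [to_country_code()]). Pairs are unordered: a row `(A,B,v)` and a row
#' `(B,A,v)` are the same pair and are deduplicated; the same unordered pair
#' appearing with *conflicting* values is an error. Self-pairs are rejected.
#'
#' @param path Path to a CSV file with a header row.
#' @param kind One of `"lsbci"`, `"days"`, `"indicators"`.
#' @return A data frame of validated pair records with canonical codes:
#'   columns `origin`, `partner`, and `value` (or the five indicator columns
#'   for `kind = "indicators"`).
#' @export
read_pair_table <- function(path, kind = c("lsbci", "days", "indicators")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)

  value_cols <- if (kind == "indicators") indicator_names() else "value"
  required <- c("origin", "partner", value_cols)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stopf("missing required column(s) in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  df <- df[, required, drop = FALSE]
  df$origin <- to_country_code(df$origin)
  df$partner <- to_country_code(df$partner)

  validate_pair_values(df, value_cols, kind)

  self <- which(df$origin == df$partner)
  if (length(self)) {
    stopf("self-pair not allowed (row %d: %s)", self[1], df$origin[self[1]])
  }

  dedupe_unordered_pairs(df, value_cols)
}

indicator_names <- function() {
  c("transshipments", "common_direct", "common_one_tranship",
    "competition", "max_ship_size")
}

validate_pair_values <- function(df, value_cols, kind) {
  for (col in value_cols) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stopf("column '%s' must be finite numeric", col)
    }
    if (any(v < 0)) {
      stopf("column '%s' has negative value at row %d", col, which(v < 0)[1])
    }
  }
  if (kind == "days" && any(df$value <= 0)) {
    stopf("days-at-sea values must be strictly positive (row %d)",
          which(df$value <= 0)[1])
  }
  if (kind == "lsbci" && any(df$value > 1)) {
    stopf("LSBCI values must lie in [0, 1] (row %d)", which(df$value > 1)[1])
  }
  invisible(df)
}

# collapse symmetric duplicates; conflicting duplicate values are an error
dedupe_unordered_pairs <- function(df, value_cols) {
  key <- ifelse(df$origin < df$partner,
                paste(df$origin, df$partner, sep = "|"),
                paste(df$partner, df$origin, sep = "|"))
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      rows <- df[key == k, value_cols, drop = FALSE]
      if (nrow(unique(rows)) > 1L) {
        stopf("conflicting values for country pair %s", gsub("\\|", "-", k))
      }
    }
    df <- df[!duplicated(key), , drop = FALSE]
  }
  # canonical unordered orientation: origin < partner alphabetically
  flip <- df$origin > df$partner
  tmp <- df$origin[flip]
  df$origin[flip] <- df$partner[flip]
  df$partner[flip] <- tmp
  df <- df[order(df$origin, df$partner), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a per-country Habitat Suitability Index table
#'
#' CSV with columns `country, hsi`. HSI values must lie in \[0, 1\];
#' empty cells or `NA` mark countries with no HSI estimate (these are kept,
#' flagged missing, and ranked last by [rank_with_hsi()]).
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns `country` (alpha-3) and `hsi` (`NA` when
#'   missing).
#' @export
read_hsi_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("country", "hsi"), names(df))
  if (length(missing_cols)) {
    stopf("missing required column(s) in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  df$country <- to_country_code(df$country)
  if (anyDuplicated(df$country)) {
    stopf("duplicate HSI entry for %s", df$country[duplicated(df$country)][1])
  }
  hsi <- suppressWarnings(as.numeric(df$hsi))
  bad <- which(!is.na(hsi) & (hsi < 0 | hsi > 1))
  if (length(bad)) stopf("hsi out of [0, 1] at row %d", bad[1])
  data.frame(country = df$country, hsi = hsi, stringsAsFactors = FALSE)
}

#' Write a risk-ranking table to CSV
#'
#' Writes columns `rank, country, lasimti_sum, hsi, composite`, sorted by
#' rank ascending; `hsi` and `composite` are blank when missing or not
#' computed. The file round-trips: reading it back preserves ranks exactly.
#'
#' @param table A risk table from [rank_by_lasimti()] or [rank_with_hsi()].
#' @param path Output CSV path.
#' @return Invisibly, the path written.
#' @export
write_rank_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  cols <- c("rank", "country", "lasimti_sum", "hsi", "composite")
  out <- data.frame(rank = integer(0), country = character(0),
                    lasimti_sum = numeric(0), hsi = numeric(0),
                    composite = numeric(0))
  if (nrow(table)) {
    for (col in setdiff(cols, names(table))) table[[col]] <- NA_real_
    out <- table[order(table$rank), cols, drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a trade network to GraphML or JSON node-link format
#'
#' Nodes carry `in_degree`, `source_population`, and `pagerank` (when a
#' centrality result is supplied); edges carry their LSBCI weight as the
#' attribute `lsbci`. GraphML output is parseable by standard graph tooling.
#'
#' @param net A [build_network()] result.
#' @param path Output file path.
#' @param format `"graphml"` or `"json"`.
#' @param centrality Optional [pagerank()] result whose values are attached
#'   as the node attribute `pagerank`.
#' @return Invisibly, the path written.
#' @export
export_graph <- function(net, path, format = c("graphml", "json"),
                         centrality = NULL) {
  stopifnot(inherits(net, "trade_network"))
  format <- match.arg(format)
  nodes <- net$nodes
  if (!is.null(centrality)) {
    stopifnot(inherits(centrality, "centrality_result"))
    nodes$pagerank <- centrality$scores$pagerank[
      match(nodes$country, centrality$scores$country)]
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("from", "to")], directed = TRUE, vertices = nodes)
    igraph::E(g)$lsbci <- net$edges$weight
    # igraph writes logicals as strings; make the flag explicit
    igraph::V(g)$source_population <- as.character(nodes$source_population)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    links <- data.frame(source = net$edges$from, target = net$edges$to,
                        lsbci = net$edges$weight, stringsAsFactors = FALSE)
    payload <- list(directed = TRUE, nodes = nodes, links = links)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
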