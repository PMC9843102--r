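#' Run the full introduction-risk pipeline
#'
#' Orchestrates every stage: read the connectivity input (either precomputed
#' LSBCI pairs or the five raw indicators), read days at sea and optional
#' HSI, rank targets by LASIMTI sum, re-rank with HSI, build the top-k
#' trade network (with optional travel-time cutoff), compute PageRank
#' centrality, and write all artifacts plus a run manifest into `out_dir`.
#' Output is a pure function of the inputs and config: rerunning produces
#' byte-identical files.
#'
#' @param config A list with elements:
#'   * `lsbci` *or* `indicators` — path to the connectivity CSV (exactly one);
#'   * `days` — path to the days-at-sea CSV;
#'   * `sources` — character vector of source-population codes or names;
#'   * `hsi` — optional path to the HSI CSV;
#'   * `targets` — optional character vector restricting the ranked set
#'     (default: every non-source country in the connectivity table);
#'   * `k` (default 3), `max_days` (default `NULL`), `damping` (default
#'     0.85), `strategy` (default `"hsi_then_lasimti"`), `orientations`
#'     (defaults to [default_orientations()]);
#'   * `out_dir` — output directory.
#' @return Invisibly, a named character vector of the artifact paths:
#'   LASIMTI rank table, HSI-combined rank table (when HSI given), GraphML
#'   and JSON network exports, centrality table, and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr,
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  conn <- collect(
    if (!is.null(cfg$lsbci)) {
      pairs_to_matrix(read_pair_table(cfg$lsbci, kind = "lsbci"))
    } else {
      compute_lsbci(read_pair_table(cfg$indicators, kind = "indicators"),
                    cfg$orientations)
    })
  times <- pairs_to_matrix(read_pair_table(cfg$days, kind = "days"))
  sources <- to_country_code(cfg$sources)
  targets <- if (!is.null(cfg$targets)) to_country_code(cfg$targets)
             else setdiff(rownames(conn), sources)

  paths <- c(rank_lasimti = file.path(cfg$out_dir, "rank_lasimti.csv"),
             network_graphml = file.path(cfg$out_dir, "network.graphml"),
             network_json = file.path(cfg$out_dir, "network.json"),
             centrality = file.path(cfg$out_dir, "centrality.csv"),
             manifest = file.path(cfg$out_dir, "manifest.json"))

  risk <- collect(rank_by_lasimti(targets, sources, conn, times))
  write_rank_table(risk, paths["rank_lasimti"])

  if (!is.null(cfg$hsi)) {
    hsi <- read_hsi_table(cfg$hsi)
    risk_hsi <- rank_with_hsi(risk, hsi, cfg$strategy)
    paths["rank_hsi"] <- file.path(cfg$out_dir, "rank_hsi.csv")
    write_rank_table(risk_hsi, paths["rank_hsi"])
  }

  # intracontinental network: ranked targets only, sources flagged if present
  target_conn <- conn[rownames(conn) %in% targets,
                      colnames(conn) %in% targets, drop = FALSE]
  net <- build_network(target_conn, k = cfg$k, max_days = cfg$max_days,
                       times = if (is.null(cfg$max_days)) NULL else times,
                       sources = sources)
  cent <- pagerank(net, damping = cfg$damping)
  export_graph(net, paths["network_graphml"], "graphml", centrality = cent)
  export_graph(net, paths["network_json"], "json", centrality = cent)
  utils::write.csv(rank_centrality(cent), paths["centrality"],
                   row.names = FALSE)

  manifest <- list(
    package = "lasimti",
    version = as.character(utils::packageVersion("lasimti")),
    # out_dir excluded: the echo describes the analysis, not its location
    config = cfg[setdiff(names(cfg)[!vapply(cfg, is.null, logical(1))],
                         "out_dir")],
    n_targets = length(targets),
    n_sources = length(sources),
    missing_pairs_logged = attr(risk, "n_missing_pairs"),
    warnings = sort(unique(warnings_seen)))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(lsbci = NULL, indicators = NULL, days = NULL, hsi = NULL,
                   sources = NULL, targets = NULL, k = 3, max_days = NULL,
                   damping = 0.85, strategy = "hsi_then_lasimti",
                   orientations = default_orientations(), out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$lsbci) == is.null(cfg$indicators)) {
    stopf("config must supply exactly one of 'lsbci' or 'indicators'")
  }
  if (is.null(cfg$days)) stopf("config must supply 'days'")
  if (is.null(cfg$sources) || length(cfg$sources) == 0L) {
    stopf("config must supply a non-empty 'sources' list")
  }
  if (is.null(cfg$out_dir)) stopf("config must supply 'out_dir'")
  cfg
}
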