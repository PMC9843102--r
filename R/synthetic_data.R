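#' Specify a synthetic trade scenario
#'
#' Bundles the knobs of the synthetic-data generators into one validated
#' spec. The generated world has `n_targets` coastal countries to be ranked
#' and `n_sources` countries with established vector populations. Pairwise
#' connectivity is drawn from a right-skewed Beta law (most pairs weakly
#' connected, a few strong hubs); transit times come from random port
#' locations on the sphere traversed at a single uniform vessel speed; HSI
#' values are uniform on \[0, 1\] with a configurable missing fraction.
#' A "planted" target can have its connectivity to every source multiplied
#' by `boost` (capped at 1) to create a known rank-1 country for recovery
#' experiments.
#'
#' @param n_targets Number of target countries (default 30).
#' @param n_sources Number of source-population countries (default 4).
#' @param seed Integer seed; the same spec always generates byte-identical
#'   data.
#' @param lsbci_shape1,lsbci_shape2 Beta shape parameters of the
#'   connectivity law (default Beta(2, 6), right-skewed).
#' @param speed_knots Uniform vessel speed in knots (default 14).
#' @param missing_hsi_fraction Fraction of targets with no HSI value.
#' @param planted_target Code of the boosted target; defaults to the first
#'   target when `boost > 1`.
#' @param boost Multiplier (>= 1) on the planted target's source
#'   connectivity; 1 means no signal.
#' @return A `scenario_spec` object (validated list).
#' @export
scenario_spec <- function(n_targets = 30, n_sources = 4, seed = 1,
                          lsbci_shape1 = 2, lsbci_shape2 = 6,
                          speed_knots = 14, missing_hsi_fraction = 0,
                          planted_target = NULL, boost = 1) {
  stopifnot(n_targets >= 1, n_sources >= 1, speed_knots > 0,
            lsbci_shape1 > 0, lsbci_shape2 > 0,
            missing_hsi_fraction >= 0, missing_hsi_fraction <= 1,
            boost >= 1)
  targets <- synthetic_codes("T", n_targets)
  sources <- synthetic_codes("S", n_sources)
  if (is.null(planted_target) && boost > 1) planted_target <- targets[1]
  if (!is.null(planted_target)) {
    planted_target <- to_country_code(planted_target)
    if (!planted_target %in% targets) {
      stopf("planted_target %s is not one of the generated targets",
            planted_target)
    }
  }
  structure(list(n_targets = as.integer(n_targets),
                 n_sources = as.integer(n_sources),
                 seed = as.integer(seed),
                 lsbci_shape1 = lsbci_shape1, lsbci_shape2 = lsbci_shape2,
                 speed_knots = speed_knots,
                 missing_hsi_fraction = missing_hsi_fraction,
                 targets = targets, sources = sources,
                 planted_target = planted_target, boost = boost),
            class = "scenario_spec")
}

# deterministic synthetic alpha-3 codes: TAA, TAB, ... / SAA, SAB, ...
synthetic_codes <- function(prefix, n) {
  if (n > 676) stopf("at most 676 synthetic %s-codes available", prefix)
  grid <- expand.grid(b = LETTERS, a = LETTERS, stringsAsFactors = FALSE)
  paste0(prefix, grid$a, grid$b)[seq_len(n)]
}

#' Generate a synthetic pairwise connectivity matrix
#'
#' Draws an LSBCI value for every unordered pair among targets and sources
#' from the spec's Beta law, then applies the planted boost (if any) to the
#' planted target's pairs with each source, capping at 1. Connectivity is
#' generated independently of port geography: a liner-shipping index
#' reflects service topology, not distance.
#'
#' @param spec A [scenario_spec()].
#' @return Symmetric connectivity matrix over all targets and sources.
#' @export
gen_connectivity <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  countries <- c(spec$targets, spec$sources)
  n <- length(countries)
  with_seed(spec$seed, {
    m <- matrix(NA_real_, n, n, dimnames = list(countries, countries))
    vals <- stats::rbeta(n * (n - 1) / 2, spec$lsbci_shape1, spec$lsbci_shape2)
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    if (!is.null(spec$planted_target) && spec$boost > 1) {
      for (s in spec$sources) {
        b <- min(1, spec$boost * m[spec$planted_target, s])
        m[spec$planted_target, s] <- b
        m[s, spec$planted_target] <- b
      }
    }
    m
  })
}

#' Generate synthetic port-to-port transit times
#'
#' Each country receives one port placed uniformly at random on the sphere;
#' days at sea between two countries is the great-circle distance between
#' their ports divided by the distance covered per day at the spec's uniform
#' vessel speed. Times are symmetric, strictly positive, and satisfy the
#' triangle inequality up to the shared speed.
#'
#' @param spec A [scenario_spec()].
#' @return Symmetric days-at-sea matrix over all targets and sources.
#' @export
gen_transit_times <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  countries <- c(spec$targets, spec$sources)
  n <- length(countries)
  with_seed(spec$seed + 1L, {
    lon <- stats::runif(n, -180, 180)
    lat <- asin(stats::runif(n, -1, 1)) * 180 / pi # uniform on the sphere
    ports <- cbind(lon, lat)
    m <- matrix(NA_real_, n, n, dimnames = list(countries, countries))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- transit_days(ports[i, ], ports[j, ], spec$speed_knots)
        m[i, j] <- m[j, i] <- d
      }
    }
    m
  })
}

#' Days at sea between two ports at a uniform vessel speed
#'
#' Great-circle distance on a sphere of radius 6371 km, divided by the
#' distance a vessel covers per day (1 knot = 1.852 km/h).
#'
#' @param from,to Numeric `(lon, lat)` pairs in degrees.
#' @param speed_knots Vessel speed in knots.
#' @return Days at sea (strictly positive for distinct ports).
#' @export
#' @examples
#' transit_days(c(0, 0), c(180, 0), 14) # antipodal: about 32.2 days
transit_days <- function(from, to, speed_knots) {
  km <- geosphere::distCosine(from, to, r = 6371000) / 1000
  km_per_day <- speed_knots * 1.852 * 24
  pmax(km / km_per_day, .Machine$double.eps)
}

#' Generate synthetic per-country habitat suitability
#'
#' Uniform HSI values on \[0, 1\] for the target countries, with exactly
#' `round(missing_hsi_fraction * n_targets)` entries set missing (`NA`),
#' chosen at random under the spec's seed.
#'
#' @param spec A [scenario_spec()].
#' @return Data frame with columns `country`, `hsi`.
#' @export
gen_hsi <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_targets
  with_seed(spec$seed + 2L, {
    hsi <- stats::runif(n)
    n_missing <- round(spec$missing_hsi_fraction * n)
    if (n_missing > 0) hsi[sample.int(n, n_missing)] <- NA_real_
    data.frame(country = spec$targets, hsi = hsi, stringsAsFactors = FALSE)
  })
}

#' Generate a complete, mutually consistent synthetic scenario
#'
#' Bundles [gen_connectivity()], [gen_transit_times()] and [gen_hsi()] with
#' the source set and an answer key recording the planted target (if any),
#' so a recovery experiment can check whether the ranking finds it.
#'
#' @param spec A [scenario_spec()].
#' @return List with elements `spec`, `conn`, `times`, `hsi`, `targets`,
#'   `sources`, and `answer_key` (data frame with `planted_target`, `boost`).
#' @export
gen_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  list(spec = spec,
       conn = gen_connectivity(spec),
       times = gen_transit_times(spec),
       hsi = gen_hsi(spec),
       targets = spec$targets,
       sources = spec$sources,
       answer_key = data.frame(
         planted_target = if (is.null(spec$planted_target)) NA_character_
                          else spec$planted_target,
         boost = spec$boost, stringsAsFactors = FALSE))
}

#' Write a synthetic scenario to disk in the pipeline's input formats
#'
#' Emits exactly the CSV formats [read_pair_table()] and [read_hsi_table()]
#' consume: `lsbci.csv`, `days.csv`, `hsi.csv`, plus `sources.txt` (one code
#' per line) and `answer_key.csv`. Byte-identical across calls for the same
#' spec.
#'
#' @param scenario A [gen_scenario()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(lsbci = file.path(dir, "lsbci.csv"),
             days = file.path(dir, "days.csv"),
             hsi = file.path(dir, "hsi.csv"),
             sources = file.path(dir, "sources.txt"),
             answer_key = file.path(dir, "answer_key.csv"))
  utils::write.csv(matrix_to_pairs(scenario$conn), paths["lsbci"],
                   row.names = FALSE)
  utils::write.csv(matrix_to_pairs(scenario$times), paths["days"],
                   row.names = FALSE)
  utils::write.csv(scenario$hsi, paths["hsi"], row.names = FALSE, na = "")
  writeLines(scenario$sources, paths["sources"])
  utils::write.csv(scenario$answer_key, paths["answer_key"],
                   row.names = FALSE, na = "")
  invisible(paths)
}
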