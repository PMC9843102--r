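#' Build the directed trade network under the top-k / tie rule
#'
#' Each country links out to the partners whose LSBCI ties into its `k`
#' highest values among *eligible* partners. Eligible partners are those
#' with a positive recorded LSBCI; when `max_days` is set, partners farther
#' than the cutoff (or with no recorded transit time) are removed from the
#' eligible set *before* the top-k selection, so a country may link to its
#' 4th-best partner by LSBCI if its top 3 lie beyond the cutoff. Exact ties
#' at the k-th value are all included, so out-degree can exceed `k`; with
#' fewer than `k` eligible partners, all of them are linked.
#'
#' A cutoff of `max_days = 14` matches the window over which
#' *An. stephensi* eggs survive desiccation in transit; `max_days = NULL`
#' (the default) builds the unrestricted network.
#'
#' @param conn Symmetric connectivity matrix (`NA` = no recorded pair).
#' @param k Number of top partners per country (default 3).
#' @param max_days Optional travel-time cutoff in days; requires `times`.
#' @param times Symmetric days-at-sea matrix, required iff `max_days` is set.
#' @param sources Optional codes of countries with established source
#'   populations; flagged on the nodes (and in exports) but not treated
#'   specially by the construction.
#' @return A `trade_network` object: list with `nodes` (data frame
#'   `country`, `in_degree`, `source_population`), `edges` (data frame
#'   `from`, `to`, `weight`), and the `k` / `max_days` used.
#' @export
build_network <- function(conn, k = 3, max_days = NULL, times = NULL,
                          sources = NULL) {
  stopifnot(is.matrix(conn), !is.null(rownames(conn)))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stopf("build_network: k must be a positive integer")
  }
  k <- as.integer(k)
  if (!is.null(max_days)) {
    if (is.null(times)) {
      stopf("build_network: max_days requires a transit-time matrix")
    }
    if (max_days <= 0) stopf("build_network: max_days must be positive")
  }
  countries <- rownames(conn)
  if (!is.null(sources)) sources <- to_country_code(sources)

  edges <- vector("list", length(countries))
  for (i in seq_along(countries)) {
    v <- countries[i]
    w <- conn[v, ]
    eligible <- names(w)[!is.na(w) & w > 0 & names(w) != v]
    if (!is.null(max_days)) {
      covered <- if (v %in% rownames(times)) {
        intersect(eligible, colnames(times))
      } else character(0)
      d <- stats::setNames(times[v, covered], covered)
      eligible <- names(d)[!is.na(d) & d <= max_days]
    }
    if (length(eligible) == 0L) next
    vals <- w[eligible]
    kth <- sort(vals, decreasing = TRUE)[min(k, length(vals))]
    keep <- eligible[vals >= kth]
    edges[[i]] <- data.frame(from = v, to = keep,
                             weight = unname(w[keep]),
                             stringsAsFactors = FALSE)
  }
  edges <- Filter(Negate(is.null), edges)
  edges <- if (length(edges)) {
    do.call(rbind, c(edges, list(make.row.names = FALSE)))
  } else {
    data.frame(from = character(0), to = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  in_deg <- table(factor(edges$to, levels = countries))
  nodes <- data.frame(country = countries,
                      in_degree = as.integer(in_deg),
                      source_population = countries %in% sources,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, k = k, max_days = max_days),
            class = "trade_network")
}

#' @export
print.trade_network <- function(x, ...) {
  cat(sprintf("trade network: %d nodes, %d directed edges (k = %d%s)\n",
              nrow(x$nodes), nrow(x$edges), x$k,
              if (is.null(x$max_days)) ""
              else sprintf(", cutoff %g days", x$max_days)))
  invisible(x)
}

#' Weighted directed PageRank by power iteration
#'
#' PageRank is an eigenvector-centrality variant for directed graphs: the
#' stationary distribution of a random walker that, with probability
#' `damping`, follows an out-edge of the current node chosen proportionally
#' to its LSBCI weight, and otherwise teleports to a uniformly random node.
#' Dangling nodes (no out-edges) redistribute their mass uniformly over all
#' nodes. On the trade network the value of a node is the long-run
#' probability that a randomly chosen vessel is found at that country.
#'
#' The fixed point satisfies
#' `pr = (1 - d)/n + d * (t(P) %*% pr + dangling_mass / n)`
#' where `P[v, u] = weight(v,u) / sum(weight(v, .))`. Iteration stops when
#' the L1 change drops below `tol`.
#'
#' @param net A [build_network()] result.
#' @param damping Damping factor `d` in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter Iteration cap; default 1000.
#' @return A `centrality_result`: list with `scores` (data frame `country`,
#'   `pagerank` in node order), `damping`, `iterations`, `converged`.
#'   The scores sum to 1.
#' @export
pagerank <- function(net, damping = 0.85, tol = 1e-10, max_iter = 1000) {
  stopifnot(inherits(net, "trade_network"))
  if (damping <= 0 || damping >= 1) {
    stopf("pagerank: damping must lie strictly in (0, 1)")
  }
  if (tol <= 0) stopf("pagerank: tol must be positive")
  if (max_iter < 1) stopf("pagerank: max_iter must be >= 1")
  countries <- net$nodes$country
  n <- length(countries)
  if (n == 0L) stopf("pagerank: empty network")

  P <- transition_matrix(net)
  dangling <- rowSums(P) == 0
  pr <- rep(1 / n, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    flow <- as.vector(crossprod(P, pr)) + sum(pr[dangling]) / n
    pr_new <- (1 - damping) / n + damping * flow
    if (sum(abs(pr_new - pr)) < tol) {
      pr <- pr_new
      converged <- TRUE
      break
    }
    pr <- pr_new
  }
  structure(list(
    scores = data.frame(country = countries, pagerank = pr,
                        stringsAsFactors = FALSE),
    damping = damping, iterations = iter, converged = converged),
    class = "centrality_result")
}

# row-stochastic transition matrix (dangling rows left all-zero)
transition_matrix <- function(net) {
  countries <- net$nodes$country
  n <- length(countries)
  W <- matrix(0, n, n, dimnames = list(countries, countries))
  if (nrow(net$edges)) {
    W[cbind(net$edges$from, net$edges$to)] <- net$edges$weight
  }
  out_w <- rowSums(W)
  nz <- out_w > 0
  W[nz, ] <- W[nz, , drop = FALSE] / out_w[nz]
  W
}

#' @export
print.centrality_result <- function(x, ...) {
  cat(sprintf("PageRank (damping %.2f, %d iterations, %s)\n", x$damping,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  print(utils::head(rank_centrality(x)))
  invisible(x)
}

#' Out-neighbors of a country ordered by link strength
#'
#' The actionable "where to surveil next" list: if the vector is detected
#' in `country`, these are its strongest maritime links, in descending LSBCI
#' order (alphabetical on exact ties).
#'
#' @param net A [build_network()] result.
#' @param country Alpha-3 code (or registry name) of a node in the network.
#' @return Data frame with columns `country`, `weight`, strongest first.
#' @export
top_partners <- function(net, country) {
  stopifnot(inherits(net, "trade_network"))
  country <- to_country_code(country)
  if (!country %in% net$nodes$country) {
    stopf("top_partners: %s is not in the network", country)
  }
  e <- net$edges[net$edges$from == country, , drop = FALSE]
  e <- e[order(-e$weight, e$to), , drop = FALSE]
  data.frame(country = e$to, weight = e$weight, stringsAsFactors = FALSE)
}

#' Rank countries by PageRank centrality
#'
#' @param result A [pagerank()] result.
#' @return Data frame with columns `country`, `pagerank`, `rank`, descending
#'   by PageRank; exact ties are ordered alphabetically with consecutive
#'   ranks.
#' @export
rank_centrality <- function(result) {
  stopifnot(inherits(result, "centrality_result"))
  s <- result$scores
  ord <- order(-s$pagerank, s$country)
  out <- data.frame(country = s$country[ord], pagerank = s$pagerank[ord],
                    rank = seq_len(nrow(s)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
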