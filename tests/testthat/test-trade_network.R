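conn_from <- function(entries, countries) {
  m <- matrix(NA_real_, length(countries), length(countries),
              dimnames = list(countries, countries))
  for (e in entries) m[e[[1]], e[[2]]] <- m[e[[2]], e[[1]]] <- e[[3]]
  m
}

test_that("top-k selection includes exact ties and respects eligibility", {
  cn <- c("SDN", "EGY", "KEN", "MAR", "XXX")
  # SDN's partners: EGY, KEN, MAR all tie at 0.5; XXX below -> 3 out-edges
  conn <- conn_from(list(
    list("SDN", "EGY", 0.5), list("SDN", "KEN", 0.5), list("SDN", "MAR", 0.5),
    list("SDN", "XXX", 0.2)), cn)
  net <- build_network(conn, k = 3)
  sdn_out <- net$edges$to[net$edges$from == "SDN"]
  expect_setequal(sdn_out, c("EGY", "KEN", "MAR"))

  # tie at the third value yields four out-edges
  conn2 <- conn_from(list(
    list("SDN", "EGY", 0.9), list("SDN", "KEN", 0.5), list("SDN", "MAR", 0.5),
    list("SDN", "XXX", 0.5)), cn)
  net2 <- build_network(conn2, k = 3)
  expect_setequal(net2$edges$to[net2$edges$from == "SDN"],
                  c("EGY", "KEN", "MAR", "XXX"))

  # fewer eligible partners than k; zero-LSBCI pairs are ineligible
  conn3 <- conn_from(list(list("SDN", "EGY", 0.4), list("SDN", "KEN", 0.3),
                          list("SDN", "MAR", 0)), cn)
  net3 <- build_network(conn3, k = 3)
  expect_setequal(net3$edges$to[net3$edges$from == "SDN"], c("EGY", "KEN"))

  # in_degree attribute matches incoming edge counts; no self-loops
  expect_equal(net$nodes$in_degree,
               as.integer(table(factor(net$edges$to,
                                       levels = net$nodes$country))))
  expect_false(any(net$edges$from == net$edges$to))
  expect_error(build_network(conn, k = 0), "positive")
  expect_error(build_network(conn, max_days = 14), "transit-time")
})

test_that("travel-time cutoff filters partners before top-k selection", {
  cn <- c("AAA", "BBB", "CCC", "DDD", "EEE")
  conn <- conn_from(list(
    list("AAA", "BBB", 0.9), list("AAA", "CCC", 0.8),
    list("AAA", "DDD", 0.7), list("AAA", "EEE", 0.1)), cn)
  times <- conn_from(c(
    list(list("AAA", "BBB", 20), list("AAA", "CCC", 3),
         list("AAA", "DDD", 30), list("AAA", "EEE", 5)),
    # cover every remaining pair: uncovered pairs are ineligible under a cutoff
    lapply(list(c("BBB", "CCC"), c("BBB", "DDD"), c("BBB", "EEE"),
                c("CCC", "DDD"), c("CCC", "EEE"), c("DDD", "EEE")),
           function(p) list(p[1], p[2], 7))), cn)
  # BBB and DDD are beyond 14 days: AAA links to its remaining partners,
  # including low-LSBCI EEE (pre-filter semantics)
  net <- build_network(conn, k = 3, max_days = 14, times = times)
  expect_setequal(net$edges$to[net$edges$from == "AAA"], c("CCC", "EEE"))

  # an infinite cutoff reproduces the unrestricted network
  net_inf <- build_network(conn, k = 3, max_days = Inf, times = times)
  net_free <- build_network(conn, k = 3)
  expect_equal(net_inf$edges, net_free$edges)
})

test_that("network construction matches a brute-force oracle with ties", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    conn <- random_conn(n)
    k <- sample(1:4, 1)
    net <- build_network(conn, k = k)
    got <- sort(paste(net$edges$from, net$edges$to, sep = "->"))
    expect_identical(got, oracle_topk_edges(conn, k))
    # top-k law: out-degree within [min(k, eligible), eligible]
    for (v in rownames(conn)) {
      elig <- sum(!is.na(conn[v, ]) & conn[v, ] > 0)
      outd <- sum(net$edges$from == v)
      expect_gte(outd, min(k, elig))
      expect_lte(outd, elig)
    }
  }
})

test_that("PageRank satisfies the analytic identities", {
  cn <- c("AAA", "BBB")
  net <- network_from_weights(matrix(c(0, 0.7, 0.7, 0), 2, 2,
                                     dimnames = list(cn, cn)))
  pr <- pagerank(net)
  expect_equal(pr$scores$pagerank, c(0.5, 0.5), tolerance = 1e-12)
  expect_true(pr$converged)

  # directed equal-weight ring: uniform 1/n
  n <- 7
  W <- matrix(0, n, n, dimnames = list(sprintf("R%02d", 1:n),
                                       sprintf("R%02d", 1:n)))
  for (i in 1:n) W[i, i %% n + 1] <- 0.3
  prr <- pagerank(network_from_weights(W))
  expect_equal(prr$scores$pagerank, rep(1 / n, n), tolerance = 1e-12)

  # a node with no in-edges in a dangling-free graph sits exactly at (1-d)/n
  W2 <- matrix(0, 3, 3, dimnames = list(c("AAA", "BBB", "CCC"),
                                        c("AAA", "BBB", "CCC")))
  W2["AAA", "BBB"] <- 1; W2["BBB", "CCC"] <- 1; W2["CCC", "BBB"] <- 1
  pr2 <- pagerank(network_from_weights(W2), damping = 0.85)
  expect_equal(pr2$scores$pagerank[1], 0.15 / 3, tolerance = 1e-12)

  expect_error(pagerank(net, damping = 1), "damping")
  expect_error(pagerank(net, tol = 0), "tol")
})

test_that("PageRank matches the dense Google-matrix oracle and igraph", {
  set.seed(202)
  for (rep in 1:25) {
    W <- random_digraph(sample(3:10, 1))
    net <- network_from_weights(W)
    pr <- pagerank(net, tol = 1e-14)
    expect_equal(sum(pr$scores$pagerank), 1, tolerance = 1e-9)
    expect_true(all(pr$scores$pagerank >= (1 - 0.85) / nrow(W) - 1e-12))
    expect_equal(pr$scores$pagerank, oracle_pagerank(W), tolerance = 1e-8)
  }
  # independent library cross-check on one fixed graph
  W <- random_digraph(8)
  net <- network_from_weights(W)
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     vertices = net$nodes$country)
  ig <- igraph::page_rank(g, weights = net$edges$weight, damping = 0.85)
  pr <- pagerank(net, tol = 1e-14)
  expect_equal(pr$scores$pagerank[match(names(ig$vector), pr$scores$country)],
               unname(ig$vector), tolerance = 1e-6)
})

test_that("top partners and centrality ranking order deterministically", {
  cn <- c("DJI", "SDN", "EGY", "KEN", "ZZZ")
  conn <- conn_from(list(
    list("DJI", "SDN", 0.6), list("DJI", "EGY", 0.4), list("DJI", "KEN", 0.3),
    list("SDN", "EGY", 0.2)), cn)
  net <- build_network(conn, k = 3, sources = c("DJI", "SDN"))
  tp <- top_partners(net, "DJI")
  expect_equal(tp$country, c("SDN", "EGY", "KEN"))
  expect_equal(tp$weight, c(0.6, 0.4, 0.3))
  expect_equal(nrow(top_partners(net, "ZZZ")), 0L) # isolated node
  expect_error(top_partners(net, "QQQ"), "not in the network")
  expect_true(all(net$nodes$source_population ==
                    (net$nodes$country %in% c("DJI", "SDN"))))

  fake <- structure(list(scores = data.frame(
    country = c("AAA", "BBB", "CCC", "DDD"),
    pagerank = c(0.5, 0.2, 0.2, 0.1), stringsAsFactors = FALSE),
    damping = 0.85, iterations = 1L, converged = TRUE),
    class = "centrality_result")
  rc <- rank_centrality(fake)
  expect_equal(rc$country, c("AAA", "BBB", "CCC", "DDD"))
  expect_equal(rc$rank, 1:4)

  # 30-node network: ordering agrees with the dense-oracle ordering
  set.seed(303)
  W <- random_digraph(30, p_edge = 0.2)
  net30 <- network_from_weights(W)
  pr30 <- pagerank(net30, tol = 1e-14)
  oracle_order <- order(-oracle_pagerank(W), rownames(W))
  expect_equal(rank_centrality(pr30)$country, rownames(W)[oracle_order])
})
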