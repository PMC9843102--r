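# Independent oracles and fixture factories shared across tests.
# These deliberately avoid the package's own code paths: the PageRank oracle
# assembles the dense Google matrix and takes its dominant eigenvector; the
# top-k oracle enumerates edges by sorting; fixtures are built directly as
# matrices/data frames.

# dense Google-matrix PageRank: dominant left eigenvector of
# G = d * (P + dangling * 1/n) + (1-d) * 1/n
oracle_pagerank <- function(W, damping = 0.85) {
  n <- nrow(W)
  P <- W
  out_w <- rowSums(P)
  for (i in seq_len(n)) {
    P[i, ] <- if (out_w[i] > 0) P[i, ] / out_w[i] else rep(1 / n, n)
  }
  G <- damping * P + (1 - damping) / n
  e <- eigen(t(G))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sum(v)
}

# random weighted digraph as an out-weight matrix; some nodes left dangling
random_digraph <- function(n, p_edge = 0.4, p_dangling = 0.2) {
  W <- matrix(0, n, n, dimnames = list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n)))
  for (i in 1:n) {
    if (runif(1) < p_dangling) next
    js <- setdiff(which(runif(n) < p_edge), i)
    if (length(js) == 0) js <- setdiff(sample.int(n, 1), i)
    W[i, js] <- runif(length(js), 0.05, 1)
  }
  W
}

# wrap an out-weight matrix as a trade_network object
network_from_weights <- function(W) {
  idx <- which(W > 0, arr.ind = TRUE)
  edges <- data.frame(from = rownames(W)[idx[, 1]], to = colnames(W)[idx[, 2]],
                      weight = W[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  nodes <- data.frame(country = rownames(W),
                      in_degree = as.integer(colSums(W > 0)),
                      source_population = FALSE, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, k = NA_integer_, max_days = NULL),
            class = "trade_network")
}

# brute-force top-k/tie edge enumeration from a symmetric connectivity matrix
oracle_topk_edges <- function(conn, k, max_days = NULL, times = NULL) {
  out <- list()
  for (v in rownames(conn)) {
    w <- conn[v, ]
    elig <- names(w)[!is.na(w) & w > 0 & names(w) != v]
    if (!is.null(max_days)) {
      elig <- Filter(function(u) !is.na(times[v, u]) && times[v, u] <= max_days,
                     elig)
    }
    if (!length(elig)) next
    sorted <- sort(w[elig], decreasing = TRUE)
    thr <- sorted[min(k, length(sorted))]
    to <- sort(elig[w[elig] >= thr])
    out[[v]] <- paste(v, to, sep = "->")
  }
  as.character(sort(unlist(out, use.names = FALSE)))
}

# random symmetric connectivity matrix with planted exact ties and zeros
random_conn <- function(n, tie_prob = 0.3, zero_prob = 0.15, na_prob = 0.1) {
  cn <- sprintf("C%02d", 1:n)
  m <- matrix(NA_real_, n, n, dimnames = list(cn, cn))
  vals <- sample(round(runif(5), 2), n * (n - 1) / 2, replace = TRUE) # few levels -> ties
  vals[runif(length(vals)) < zero_prob] <- 0
  vals[runif(length(vals)) < na_prob] <- NA
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# small indicator pair table with n_pairs rows over a ring of countries
random_indicator_table <- function(n_pairs) {
  cn <- sprintf("C%02d", seq_len(n_pairs + 1))
  data.frame(origin = cn[seq_len(n_pairs)], partner = cn[seq_len(n_pairs) + 1],
             transshipments = sample(0:5, n_pairs, TRUE),
             common_direct = sample(0:20, n_pairs, TRUE),
             common_one_tranship = sample(0:40, n_pairs, TRUE),
             competition = sample(1:15, n_pairs, TRUE),
             max_ship_size = runif(n_pairs, 1e3, 2e4),
             stringsAsFactors = FALSE)
}
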