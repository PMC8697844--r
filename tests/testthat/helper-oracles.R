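# Brute-force oracles for the network metrics, independent of igraph's
# algorithms: Floyd-Warshall distances with explicit shortest-path
# counting for betweenness, a triple loop for the Barrat coefficient,
# dense eigendecomposition for eigenvector centrality, and adjacency
# row/column sums for strength.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# Random connected-ish undirected weighted graph on n nodes.
rand_wgraph <- function(n, p = 0.45, directed = FALSE) {
  repeat {
    A <- matrix(0, n, n)
    upper <- which(upper.tri(A))
    on <- upper[stats::runif(length(upper)) < p]
    A[on] <- stats::runif(length(on), 0.1, 2)
    A <- A + t(A)
    if (directed) {
      B <- matrix(0, n, n)
      off <- which(row(B) != col(B))
      on <- off[stats::runif(length(off)) < p]
      B[on] <- stats::runif(length(on), 0.1, 2)
      A <- B
    }
    g <- igraph::graph_from_adjacency_matrix(
      A, mode = if (directed) "directed" else "undirected", weighted = TRUE)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    if (igraph::ecount(g) >= 1) return(g)
  }
}

graph_weight_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
}

oracle_strength <- function(g) {
  W <- graph_weight_matrix(g)
  list(in_strength = colSums(W), out_strength = rowSums(W),
       in_degree = colSums(W > 0), out_degree = rowSums(W > 0))
}

# All-pairs shortest-path betweenness by Floyd-Warshall distances plus
# combinatorial counting of shortest paths (edge cost = 1/weight).
oracle_betweenness <- function(g, tol = 1e-9) {
  n <- igraph::vcount(g)
  W <- graph_weight_matrix(g)
  C <- ifelse(W > 0, 1 / W, Inf)
  diag(C) <- 0
  dist <- C
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (dist[i, k] + dist[k, j] < dist[i, j])
      dist[i, j] <- dist[i, k] + dist[k, j]
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(dist[s, ])) {
      if (t == s || !is.finite(dist[s, t])) next
      preds <- which(is.finite(C[, t]) & C[, t] > 0 &
                       abs(dist[s, ] + C[, t] - dist[s, t]) < tol)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (v == s || v == t || !is.finite(dist[s, t]) || sigma[s, t] == 0) next
      if (abs(dist[s, v] + dist[v, t] - dist[s, t]) < tol)
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  stats::setNames(btw, igraph::V(g)$name)
}

# Exhaustive simple-path enumeration (tiny n only); validates the
# Floyd-Warshall oracle itself.
enum_betweenness <- function(g, tol = 1e-9) {
  n <- igraph::vcount(g)
  W <- graph_weight_matrix(g)
  C <- ifelse(W > 0, 1 / W, Inf)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(v, visited, cost) {
      if (v == t) {
        out[[length(out) + 1]] <<- list(path = visited, cost = cost)
        return()
      }
      for (u in which(is.finite(C[v, ]))) {
        if (u %in% visited) next
        walk(u, c(visited, u), cost + C[v, u])
      }
    }
    walk(s, s, 0)
    out
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    costs <- vapply(ps, `[[`, 0, "cost")
    best <- min(costs)
    shortest <- ps[costs < best + tol]
    for (p in shortest) {
      interior <- setdiff(p$path, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(shortest)
    }
  }
  stats::setNames(btw, igraph::V(g)$name)
}

oracle_barrat <- function(g) {
  W <- graph_weight_matrix(g)
  n <- nrow(W)
  A <- (W > 0) * 1
  k <- rowSums(A)
  s <- rowSums(W)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == h || j == i || h == i) next
      acc <- acc + (W[i, j] + W[i, h]) / 2 * A[i, j] * A[i, h] * A[j, h]
    }
    out[i] <- acc / (s[i] * (k[i] - 1))  # (j, h) ranges over ordered pairs
  }
  stats::setNames(out, igraph::V(g)$name)
}

oracle_eigen <- function(g) {
  W <- graph_weight_matrix(g)
  e <- eigen(W, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  stats::setNames(v / max(v), igraph::V(g)$name)
}

# Tiny deterministic fixtures -------------------------------------------

toy_roster <- function(ids = c("F01", "F02", "M01"), year = 1) {
  data.frame(id = ids, year = year,
             sex = substr(ids, 1, 1),
             age = seq(20, by = 5, length.out = length(ids)),
             rank = seq_along(ids) / length(ids),
             time_swollen = ifelse(substr(ids, 1, 1) == "F", 0.3, 0),
             stringsAsFactors = FALSE)
}

toy_obs <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(year = r[[1]], actor_id = r[[2]], receiver_id = r[[3]],
               groom_min = as.numeric(r[[4]]), co_party_min = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)))
}
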