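# Independent brute-force oracles for graph features. These deliberately
# avoid igraph's algorithms: distances come from Floyd–Warshall, coreness
# from iterative peeling, pagerank from dense power iteration, betweenness
# from explicit path enumeration over the distance matrix.

# Dense all-pairs shortest paths (Floyd–Warshall) on an adjacency/cost
# matrix with Inf for absent edges.
oracle_apsp <- function(cost) {
  n <- nrow(cost)
  d <- cost
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# Cost matrix of a (possibly weighted, possibly directed) igraph.
oracle_cost_matrix <- function(g) {
  n <- igraph::vcount(g)
  m <- matrix(Inf, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else
    rep(1, nrow(el))
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    m[a, b] <- min(m[a, b], w[i])
    if (!igraph::is_directed(g)) m[b, a] <- min(m[b, a], w[i])
  }
  m
}

oracle_harmonic_closeness <- function(g) {
  d <- oracle_apsp(oracle_cost_matrix(g))
  diag(d) <- Inf
  rowSums(ifelse(is.finite(d), 1 / d, 0))
}

oracle_eccentricity <- function(g) {
  d <- oracle_apsp(oracle_cost_matrix(g))
  diag(d) <- Inf
  apply(d, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0) 0 else max(r)
  })
}

# Betweenness by counting shortest paths with a recursive path count over
# the distance matrix (unweighted or weighted; handles ties in path cost).
oracle_betweenness <- function(g, tol = 1e-12) {
  d <- oracle_apsp(oracle_cost_matrix(g))
  cost <- oracle_cost_matrix(g)
  n <- nrow(d)
  # number of shortest paths between s and t
  nsp <- function(s, t, memo) {
    key <- paste(s, t)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (s == t) return(1)
    total <- 0
    for (v in seq_len(n)) {
      if (is.finite(cost[s, v]) &&
          abs(cost[s, v] + d[v, t] - d[s, t]) < tol) {
        total <- total + nsp(v, t, memo)
      }
    }
    memo[[key]] <- total
    total
  }
  btw <- numeric(n)
  memo <- new.env()
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(d[s, t])) next
    tot <- nsp(s, t, memo)
    if (tot == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          abs(d[s, v] + d[v, t] - d[s, t]) < tol) {
        btw[v] <- btw[v] + nsp(s, v, memo) * nsp(v, t, memo) / tot
      }
    }
  }
  # undirected graphs count each unordered pair once
  if (!igraph::is_directed(g)) btw / 2 else btw
}

# Coreness by iterative peeling: repeatedly delete nodes of minimum degree.
oracle_coreness <- function(g) {
  n <- igraph::vcount(g)
  adj <- oracle_cost_matrix(g)
  alive <- rep(TRUE, n)
  core <- integer(n)
  deg <- function() {
    sapply(seq_len(n), function(i) {
      if (!alive[i]) return(-1L)
      sum(is.finite(adj[i, ]) & alive)
    })
  }
  k <- 0L
  while (any(alive)) {
    repeat {
      ds <- deg()
      victims <- which(alive & ds <= k)
      if (length(victims) == 0) break
      core[victims] <- k
      alive[victims] <- FALSE
    }
    k <- k + 1L
  }
  core
}

# Dense pagerank power iteration with uniform teleport.
oracle_pagerank <- function(g, damping = 0.85, weights = NULL,
                            tol = 1e-12, max_iter = 10000) {
  n <- igraph::vcount(g)
  a <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- weights %||% rep(1, nrow(el))
  for (i in seq_len(nrow(el))) {
    a[el[i, 1], el[i, 2]] <- a[el[i, 1], el[i, 2]] + w[i]
    if (!igraph::is_directed(g)) {
      a[el[i, 2], el[i, 1]] <- a[el[i, 2], el[i, 1]] + w[i]
    }
  }
  out <- rowSums(a)
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    contrib <- numeric(n)
    dangling <- 0
    for (i in seq_len(n)) {
      if (out[i] > 0) {
        contrib <- contrib + p[i] * a[i, ] / out[i]
      } else {
        dangling <- dangling + p[i]
      }
    }
    p_new <- (1 - damping) / n + damping * (contrib + dangling / n)
    if (max(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  p
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Rank-statistic-free AUC oracle: explicit pair counting.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
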