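# Independent oracles used by both the unit and the acceptance suites.

# Exhaustive shortest-path betweenness by explicit path enumeration (directed,
# unweighted), normalized by (n-1)(n-2). Independent of igraph's Brandes code.
bf_betweenness <- function(adj, n) {
  paths_between <- function(s, t) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    q <- s
    while (length(q) > 0) {
      v <- q[1]
      q <- q[-1]
      for (w in adj[[v]]) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1
          q <- c(q, w)
        }
      }
    }
    if (!is.finite(dist[t])) return(list())
    res <- list()
    rec <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1L]] <<- path
        return(invisible())
      }
      for (w in adj[[v]]) {
        if (is.finite(dist[w]) && dist[w] == dist[v] + 1 && dist[w] <= dist[t]) {
          rec(c(path, w))
        }
      }
    }
    rec(s)
    res
  }
  b <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      for (p in ps) for (v in setdiff(p, c(s, t))) b[v] <- b[v] + 1 / length(ps)
    }
  }
  b / ((n - 1) * (n - 2))
}

# Plug-in MI (bits) computed by naive double loop over the contingency table
# of two label vectors.
mi_table_oracle <- function(lx, ly) {
  tab <- table(lx, ly)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        pij <- tab[i, j] / n
        mi <- mi + pij * log2(pij / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
      }
    }
  }
  mi
}

# Exact hypergeometric upper tail by summing binomial coefficients.
hyper_tail_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(if (k <= 0) 1 else 0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
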