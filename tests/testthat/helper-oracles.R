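# Independent brute-force oracles and tiny fixtures. All oracles here avoid
# the code paths of the package (and of igraph) they are used to check:
# distances come from Floyd-Warshall on an adjacency matrix, betweenness
# from explicit path-count dynamic programming, bottleneck scores from
# walking every root-to-node tree path, components from union-find.

net_from_edges <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  directed_network(data.frame(source = e[, 1], target = e[, 2]))
}

# Erdos-Renyi-style random digraph with zero-padded node names, no loops
random_digraph <- function(n, p = 0.15, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("v%02d", seq_len(n))
    pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pairs <- pairs[stats::runif(nrow(pairs)) < p, ]
    directed_network(pairs, nodes = ids)
  })
}

# 0/1 adjacency matrix in sorted node order
adj_matrix <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  e <- unique(net$edges[, c("source", "target")])
  e <- e[e$source != e$target, ]
  a[cbind(e$source, e$target)] <- 1L
  a
}

# Floyd-Warshall all-pairs shortest directed distances
oracle_distances <- function(net) {
  a <- adj_matrix(net)
  n <- nrow(a)
  d <- ifelse(a == 1L, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# diameter / CPL / reachable ordered pairs from the oracle distance matrix
oracle_path_panel <- function(net) {
  d <- oracle_distances(net)
  diag(d) <- Inf
  fin <- is.finite(d)
  list(
    diameter = if (any(fin)) max(d[fin]) else 0,
    cpl = if (any(fin)) mean(d[fin]) else NA_real_,
    n_reachable = sum(fin)
  )
}

# betweenness by path-count DP: sigma[s, t] = number of shortest s->t paths
oracle_betweenness <- function(net, normalized = TRUE) {
  a <- adj_matrix(net)
  d <- oracle_distances(net)
  n <- nrow(a)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (t in reach[order(d[s, reach])]) {
      if (t == s) next
      preds <- which(a[, t] == 1L & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == v) next
      for (t in seq_len(n)) {
        if (t == v || t == s || !is.finite(d[s, t])) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (normalized && n > 2) btw <- btw / ((n - 1) * (n - 2))
  stats::setNames(btw, net$nodes)
}

# bottleneck oracle: same deterministic tree (lexicographically smallest
# parent), but "paths meeting at v" counted by walking every root-to-node
# path and incrementing each vertex it visits (root excluded)
oracle_bottlenecks <- function(net) {
  d <- oracle_distances(net)
  a <- adj_matrix(net)
  n <- nrow(a)
  bn <- stats::setNames(integer(n), net$nodes)
  for (s in seq_len(n)) {
    reached <- which(is.finite(d[s, ]))
    tree_size <- length(reached)
    if (tree_size < 2L) next
    parent <- rep.int(NA_integer_, n)
    for (v in reached) {
      if (v == s) next
      preds <- which(a[, v] == 1L & d[s, ] == d[s, v] - 1)
      parent[v] <- min(preds) # sorted order = lexicographic order
    }
    meet <- integer(n)
    for (u in reached) {
      if (u == s) next
      w <- u
      while (!is.na(w) && w != s) {
        meet[w] <- meet[w] + 1L
        w <- parent[w]
      }
    }
    hit <- reached[reached != s & meet[reached] > tree_size / 4]
    bn[hit] <- bn[hit] + 1L
  }
  bn
}

# weak components by union-find
oracle_components <- function(net) {
  n <- length(net$nodes)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  e <- unique(net$edges[, c("source", "target")])
  si <- match(e$source, net$nodes)
  ti <- match(e$target, net$nodes)
  for (i in seq_along(si)) {
    rs <- find(si[i])
    rt <- find(ti[i])
    if (rs != rt) parent[rt] <- rs
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(net$nodes, roots), sort))
}
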