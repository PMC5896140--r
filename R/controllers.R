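#' Identify hub nodes
#'
#' Hubs are the nodes whose degree is at least one standard deviation above
#' the network mean: `degree >= mu + sigma_mult * sigma`, with `sigma` the
#' population standard deviation (the network is a census of itself, not a
#' sample). When every degree is equal, `sigma = 0` and every node
#' qualifies; this is emitted with a warning.
#'
#' @param metrics A [node_metrics()] table (>= 2 rows).
#' @param sigma_mult Number of standard deviations above the mean
#'   (default 1).
#' @param degree_col Which degree flavor defines hubness (default total
#'   `"degree"`; `"in_degree"`/`"out_degree"` also accepted).
#' @return An object of class `hub_criterion`: `mu`, `sigma`, `tau`,
#'   `degree_col`, and `hubs` — a tibble of hub rows sorted by degree
#'   descending, ties lexicographic.
#' @export
identify_hubs <- function(metrics, sigma_mult = 1, degree_col = "degree") {
  stopifnot(degree_col %in% names(metrics))
  deg <- metrics[[degree_col]]
  if (length(deg) < 2L) rlang::abort("Need at least 2 nodes to define hubs.")
  mu <- mean(deg)
  sigma <- sqrt(mean((deg - mu)^2)) # population sd
  tau <- mu + sigma_mult * sigma
  if (sigma == 0) {
    rlang::warn("All degrees equal (sigma = 0): every node qualifies as a hub.")
  }
  hubs <- metrics[deg >= tau, ]
  hubs <- hubs[order(-hubs[[degree_col]], hubs$node), ]
  structure(
    list(mu = mu, sigma = sigma, tau = tau, sigma_mult = sigma_mult,
         degree_col = degree_col, hubs = hubs, n_total = nrow(metrics)),
    class = "hub_criterion"
  )
}

#' @export
print.hub_criterion <- function(x, ...) {
  cat(sprintf(
    "<hub_criterion> %s >= %.3f (mu %.3f + %g sd %.3f): %d hub(s) of %d nodes (%.1f%%)\n",
    x$degree_col, x$tau, x$mu, x$sigma_mult, x$sigma,
    nrow(x$hubs), x$n_total, 100 * nrow(x$hubs) / x$n_total
  ))
  invisible(x)
}

#' Tidy / glance methods for the hub criterion
#' @param x A `hub_criterion`.
#' @param ... Unused.
#' @return `tidy()`: the hub rows; `glance()`: one row with `mu`, `sigma`,
#'   `tau`, `n_hubs`, `n_total`, `hub_pct`.
#' @export
tidy.hub_criterion <- function(x, ...) x$hubs

#' @rdname tidy.hub_criterion
#' @export
glance.hub_criterion <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, sigma = x$sigma, tau = x$tau, degree_col = x$degree_col,
    n_hubs = nrow(x$hubs), n_total = x$n_total,
    hub_pct = round(100 * nrow(x$hubs) / x$n_total, 1)
  )
}

#' Split a metric into subpopulations by kernel density estimation
#'
#' Estimates the probability density of a node metric (degree, clustering
#' coefficient, betweenness centrality) with a Gaussian kernel and splits
#' the sample at the strict local minima of the estimated density — the
#' valleys between modes. Bandwidth follows Silverman's rule,
#' `h = 0.9 min(sd, IQR/1.34) n^(-1/5)`; the density is evaluated on a
#' 512-point uniform grid spanning `[min - 3h, max + 3h]`. Each value is
#' assigned to the interval between boundaries that contains it; a
#' unimodal density yields a single subpopulation. A zero-variance sample
#' is degenerate: one subpopulation, flagged.
#'
#' A local minimum only separates subpopulations when its valley is
#' materially below both flanking peaks: the density at the minimum must
#' sit at least `min_valley_drop` (default 20%) below the smaller of the
#' two adjacent segment maxima. This prominence rule suppresses the
#' shallow wiggles every finite-sample KDE carries, which would otherwise
#' be read as extra modes.
#'
#' @param values Numeric vector (length >= 5).
#' @param metric Name of the metric (for labeling).
#' @param grid_n Grid size (default 512).
#' @param min_valley_drop Minimum relative drop of a valley below its
#'   flanking peaks for it to count as a boundary, in `[0, 1)`
#'   (default 0.2; 0 restores the raw strict-minimum rule).
#' @return An object of class `subpop_split` with the density grid,
#'   `boundaries`, per-value `assignment`, and `n_subpopulations`.
#' @export
kde_split <- function(values, metric = "metric", grid_n = 512L,
                      min_valley_drop = 0.2) {
  values <- as.numeric(values)
  if (length(values) < 5L) rlang::abort("kde_split() needs at least 5 values.")
  s <- stats::sd(values)
  if (s == 0) {
    return(structure(
      list(
        metric = metric,
        grid = tibble::tibble(x = unique(values), density = NA_real_),
        bandwidth = 0, boundaries = numeric(),
        assignment = rep(1L, length(values)), values = values,
        n_subpopulations = 1L, degenerate = TRUE
      ),
      class = "subpop_split"
    ))
  }
  h <- 0.9 * min(s, stats::IQR(values) / 1.34) * length(values)^(-1 / 5)
  if (h <= 0) h <- 0.9 * s * length(values)^(-1 / 5) # zero-IQR fallback
  d <- stats::density(
    values, bw = h, kernel = "gaussian", n = grid_n,
    from = min(values) - 3 * h, to = max(values) + 3 * h
  )
  y <- d$y
  # clamp numerically-dead density to exact zero so floating-point wiggle in
  # empty regions cannot fabricate minima
  y[y < max(y) * 1e-8] <- 0
  i <- 2:(length(y) - 1)
  cand <- i[y[i] < y[i - 1] & y[i] < y[i + 1]]
  # a maximal run of zero density flanked by positive density is one valley:
  # take its midpoint as the boundary
  zero_runs <- rle(y == 0)
  ends <- cumsum(zero_runs$lengths)
  starts <- ends - zero_runs$lengths + 1L
  for (j in which(zero_runs$values)) {
    if (starts[j] > 1L && ends[j] < length(y)) {
      cand <- c(cand, as.integer(round(mean(c(starts[j], ends[j])))))
    }
  }
  cand <- sort(unique(cand))
  cand <- prune_shallow_valleys(y, cand, min_valley_drop)
  boundaries <- d$x[cand]
  boundaries <- boundaries[boundaries > min(values) & boundaries < max(values)]
  assignment <- findInterval(values, boundaries) + 1L
  structure(
    list(
      metric = metric,
      grid = tibble::tibble(x = d$x, density = d$y),
      bandwidth = h, boundaries = boundaries,
      assignment = assignment, values = values,
      n_subpopulations = length(boundaries) + 1L, degenerate = FALSE
    ),
    class = "subpop_split"
  )
}

#' @export
print.subpop_split <- function(x, ...) {
  cat(sprintf(
    "<subpop_split> %s: %d subpopulation(s)%s; bandwidth %.4g\n",
    x$metric, x$n_subpopulations,
    if (x$degenerate) " (degenerate)" else "", x$bandwidth
  ))
  if (length(x$boundaries)) {
    cat("  boundaries:", paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a subpopulation split
#' @param x A `subpop_split`.
#' @param ... Unused.
#' @return A tibble `(value, subpopulation)`.
#' @export
tidy.subpop_split <- function(x, ...) {
  tibble::tibble(value = x$values, subpopulation = x$assignment)
}

#' Density plot of a subpopulation split
#' @param object A `subpop_split`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.subpop_split <- function(object, ...) {
  p <- ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(
      data = tibble::tibble(x = object$values),
      ggplot2::aes(x = .data$x), inherit.aes = FALSE, alpha = 0.4
    ) +
    ggplot2::labs(
      x = object$metric, y = "density",
      title = sprintf("%s: %d subpopulation(s)", object$metric,
                      object$n_subpopulations)
    ) +
    ggplot2::theme_minimal()
  if (length(object$boundaries)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$boundaries, linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

# drop valley candidates whose density is not at least `drop` below the
# smaller flanking segment maximum; weakest valley removed first
prune_shallow_valleys <- function(y, cand, drop) {
  while (length(cand)) {
    cuts <- c(1L, cand, length(y))
    peaks <- vapply(seq_len(length(cand) + 1L), function(s) {
      max(y[cuts[s]:cuts[s + 1L]])
    }, numeric(1))
    ratio <- y[cand] / pmin(peaks[-length(peaks)], peaks[-1])
    worst <- which.max(ratio)
    if (ratio[worst] <= 1 - drop) break
    cand <- cand[-worst]
  }
  cand
}

# integer adjacency lists over sorted node order; lexicographic tie-breaks
# become smallest-index tie-breaks
adjacency_lists <- function(net) {
  nodes <- net$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  e <- dplyr::distinct(net$edges[, c("source", "target")])
  e <- e[e$source != e$target, ] # loops never lie on shortest paths
  si <- unname(idx[e$source])
  ti <- unname(idx[e$target])
  out <- split(ti, factor(si, levels = seq_along(nodes)))
  inc <- split(si, factor(ti, levels = seq_along(nodes)))
  # in-neighbor lists sorted so the first admissible parent is lexicographic
  inc <- lapply(inc, sort)
  list(nodes = nodes, out = unname(out), incoming = unname(inc))
}

# BFS distances from root over out-adjacency; -1 = unreached
bfs_distances <- function(adj, root) {
  n <- length(adj$nodes)
  dist <- rep.int(-1L, n)
  dist[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- unique(unlist(adj$out[frontier], use.names = FALSE))
    nxt <- nxt[dist[nxt] < 0L]
    if (!length(nxt)) break
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  dist
}

#' Shortest-path tree rooted at a node
#'
#' Breadth-first tree over directed, unweighted edges. Where a node has
#' several predecessors at the previous distance level, the
#' lexicographically smallest identifier is chosen as parent, making the
#' tree deterministic. A root that reaches nothing yields a tree of size 1.
#'
#' @param net A `directed_network`.
#' @param root Node identifier present in the network.
#' @return An object of class `sp_tree`: `root`, `parent` (named character
#'   vector over non-root reached nodes), `distance` (named integer
#'   vector), `size` = number of nodes in the tree.
#' @export
shortest_path_tree <- function(net, root) {
  stopifnot(inherits(net, "directed_network"))
  if (!root %in% net$nodes) rlang::abort(sprintf("Root %s not in network.", root))
  adj <- adjacency_lists(net)
  r <- match(root, adj$nodes)
  dist <- bfs_distances(adj, r)
  reached <- which(dist >= 0L)
  parent_idx <- tree_parents(adj, dist, reached, r)
  nonroot <- setdiff(reached, r)
  structure(
    list(
      root = root,
      parent = stats::setNames(adj$nodes[parent_idx[nonroot]], adj$nodes[nonroot]),
      distance = stats::setNames(dist[reached], adj$nodes[reached]),
      size = length(reached)
    ),
    class = "sp_tree"
  )
}

# lexicographic-smallest predecessor one level up, for every reached non-root
tree_parents <- function(adj, dist, reached, root) {
  parent <- rep.int(NA_integer_, length(dist))
  for (v in reached) {
    if (v == root) next
    preds <- adj$incoming[[v]]
    preds <- preds[dist[preds] == dist[v] - 1L]
    parent[v] <- preds[1L] # incoming lists are sorted
  }
  parent
}

#' @export
print.sp_tree <- function(x, ...) {
  cat(sprintf("<sp_tree> root %s, %d node(s)\n", x$root, x$size))
  invisible(x)
}

#' Bottleneck scores from a shortest-path-tree census
#'
#' For every root `s`, the deterministic BFS tree `T_s` is built (see
#' [shortest_path_tree()]); a non-root node `v` earns the indicator
#' `p_s(v) = 1` when more than `|V(T_s)|/4` of the root's paths meet at
#' `v` — paths meeting at `v` being counted as the size of `v`'s subtree
#' (`v` plus its descendants: every path to a descendant passes `v`, and
#' the path ending at `v` is counted). The bottleneck score is
#' `BN(v) = sum over roots s of p_s(v)`; roots score 0 in their own tree.
#' Nodes with a high score sit on a large share of the network's shortest
#' routes and act as control points of information flow.
#'
#' @param net A non-empty `directed_network`.
#' @return A tibble `(node, bn)` sorted by `bn` descending, ties
#'   lexicographic.
#' @export
bottleneck_scores <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  if (n_nodes(net) == 0L) rlang::abort("Cannot score an empty network.")
  adj <- adjacency_lists(net)
  n <- length(adj$nodes)
  bn <- rep.int(0L, n)
  for (r in seq_len(n)) {
    dist <- bfs_distances(adj, r)
    reached <- which(dist >= 0L)
    tree_size <- length(reached)
    if (tree_size < 2L) next
    parent <- tree_parents(adj, dist, reached, r)
    # subtree sizes: accumulate from the deepest level upward
    size <- rep.int(0L, n)
    size[reached] <- 1L
    ord <- reached[order(dist[reached], decreasing = TRUE)]
    for (v in ord) {
      p <- parent[v]
      if (!is.na(p)) size[p] <- size[p] + size[v]
    }
    hit <- reached[reached != r & size[reached] > tree_size / 4]
    bn[hit] <- bn[hit] + 1L
  }
  out <- tibble::tibble(node = adj$nodes, bn = bn)
  out[order(-out$bn, out$node), ]
}

#' Top-k bottleneck nodes
#'
#' The `k` highest-scoring bottlenecks; ties are broken by total degree
#' (descending, when a metrics table is supplied) and then
#' lexicographically, so the ranking is invariant under node-order
#' permutation.
#'
#' @param scores A [bottleneck_scores()] tibble.
#' @param k Number of nodes to return (>= 1; truncated with a warning if
#'   it exceeds the node count).
#' @param metrics Optional [node_metrics()] table for the degree tie-break.
#' @return Character vector of node identifiers, highest score first.
#' @export
top_bottlenecks <- function(scores, k, metrics = NULL) {
  if (k < 1) rlang::abort("`k` must be >= 1.")
  if (k > nrow(scores)) {
    rlang::warn(sprintf("k = %d exceeds node count %d; truncated.", k, nrow(scores)))
    k <- nrow(scores)
  }
  deg <- rep.int(0L, nrow(scores))
  if (!is.null(metrics)) {
    deg <- metrics$degree[match(scores$node, metrics$node)]
    deg[is.na(deg)] <- 0L
  }
  ord <- order(-scores$bn, -deg, scores$node)
  scores$node[ord][seq_len(k)]
}

#' Control backbone: intersection of hub and bottleneck neighborhoods
#'
#' Each controller set (hubs; bottlenecks) induces a neighborhood network —
#' the controllers plus their first neighbors (direction ignored for
#' membership) with all induced edges. The control backbone is the
#' intersection of the two neighborhood networks: the subnetwork governed
#' by both kinds of controller.
#'
#' @param net A `directed_network`.
#' @param hubs Character vector of hub node identifiers (non-empty).
#' @param bottlenecks Character vector of bottleneck identifiers
#'   (non-empty).
#' @return A `directed_network` (empty, with a warning, when the
#'   neighborhoods do not meet).
#' @export
control_backbone <- function(net, hubs, bottlenecks) {
  stopifnot(inherits(net, "directed_network"))
  if (length(hubs) == 0L || length(bottlenecks) == 0L) {
    rlang::abort("Hub and bottleneck lists must be non-empty.")
  }
  bb <- intersect_networks(
    neighborhood_network(net, hubs),
    neighborhood_network(net, bottlenecks)
  )
  if (n_nodes(bb) == 0L) {
    rlang::warn("Hub and bottleneck neighborhoods do not intersect: empty backbone.")
  }
  bb
}

#' Induced first-neighborhood network of a seed set
#'
#' @param net A `directed_network`.
#' @param seeds Character vector of seed nodes.
#' @return Induced subnetwork on the seeds and their first neighbors
#'   (in- or out-, self excluded from the neighbor definition).
#' @export
neighborhood_network <- function(net, seeds) {
  seeds <- intersect(seeds, net$nodes)
  e <- net$edges
  nb <- unique(c(
    e$target[e$source %in% seeds],
    e$source[e$target %in% seeds]
  ))
  induced_network(net, union(seeds, nb))
}
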