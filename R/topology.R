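#' Per-node topology metrics
#'
#' Computes, for every node: in-degree, out-degree and total degree on the
#' directed graph (a self-loop adds 1 to each); the number of distinct
#' neighbors (direction ignored, self excluded); the number of links among
#' those neighbors; the local clustering coefficient
#' `C_I = 2 n_I / (k_I (k_I - 1))` where `n_I` counts the links connecting
#' the `k_I` neighbors (defined 0 when `k_I < 2`); and betweenness
#' centrality over directed shortest paths, normalized by `(N-1)(N-2)`.
#'
#' Path-based quantities follow edge direction; the neighborhood view is
#' undirected because the clustering formula is the undirected one.
#'
#' @param net A non-empty `directed_network`.
#' @return A tibble with one row per node: `node`, `in_degree`,
#'   `out_degree`, `degree`, `neighbors`, `neighbor_links`, `clustering`,
#'   `betweenness`.
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  if (n_nodes(net) == 0L) rlang::abort("Cannot compute metrics on an empty network.")
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  ind <- igraph::degree(g, mode = "in")
  outd <- igraph::degree(g, mode = "out")
  gu <- igraph::simplify(
    igraph::as_undirected(g, mode = "collapse"),
    remove.multiple = TRUE, remove.loops = TRUE
  )
  k <- igraph::degree(gu)
  tri <- igraph::count_triangles(gu)
  cc <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  btw <- igraph::betweenness(g, directed = TRUE, normalized = n > 2)
  tibble::tibble(
    node = igraph::V(g)$name,
    in_degree = as.integer(ind),
    out_degree = as.integer(outd),
    degree = as.integer(ind + outd),
    neighbors = as.integer(k),
    neighbor_links = as.integer(tri),
    clustering = as.numeric(cc),
    betweenness = as.numeric(btw)
  )
}

#' Whole-network topology panel
#'
#' The standard report for one network: node and edge counts, mean
#' clustering coefficient, number of weakly connected components, network
#' diameter (longest finite directed shortest path), the number of
#' reachable ordered node pairs with its percentage of `N(N-1)`,
#' characteristic path length (mean shortest-path length over reachable
#' ordered pairs), and the average number of distinct neighbors per node.
#' Shortest paths are computed over directed edges.
#'
#' @param net A non-empty `directed_network`.
#' @param chunk Number of source rows per distance-matrix block (memory
#'   control on large networks).
#' @return An object of class `topology_report`; see
#'   [glance.topology_report()] for the one-row tibble form.
#' @export
topology_report <- function(net, chunk = 512L) {
  stopifnot(inherits(net, "directed_network"))
  n <- n_nodes(net)
  if (n == 0L) rlang::abort("Cannot report on an empty network.")
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "weak")

  gu <- igraph::simplify(
    igraph::as_undirected(g, mode = "collapse"),
    remove.multiple = TRUE, remove.loops = TRUE
  )
  mets <- node_metrics(net)

  diam <- 0
  n_reach <- 0
  total_len <- 0
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    v <- s:min(s + chunk - 1L, n)
    d <- igraph::distances(g, v = igraph::V(g)[v], mode = "out")
    d[cbind(seq_along(v), v)] <- Inf # exclude self-pairs
    fin <- is.finite(d)
    if (any(fin)) {
      diam <- max(diam, max(d[fin]))
      n_reach <- n_reach + sum(fin)
      total_len <- total_len + sum(d[fin])
    }
  }
  cpl <- if (n_reach > 0) total_len / n_reach else NA_real_
  pct <- if (n > 1) round(100 * n_reach / (n * (n - 1)), 1) else NA_real_

  structure(
    list(
      n_nodes = n,
      n_edges = n_edges(net),
      clustering_coefficient = mean(mets$clustering),
      connected_components = comp$no,
      diameter = as.integer(diam),
      shortest_paths = as.integer(n_reach),
      shortest_paths_pct = pct,
      characteristic_path_length = cpl,
      avg_neighbors = mean(mets$neighbors)
    ),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Topology report\n")
  cat(sprintf("  Number of nodes            %d\n", x$n_nodes))
  cat(sprintf("  Number of edges            %d\n", x$n_edges))
  cat(sprintf("  Clustering coefficient     %.3f\n", x$clustering_coefficient))
  cat(sprintf("  Connected components       %d\n", x$connected_components))
  cat(sprintf("  Network diameter           %d\n", x$diameter))
  cat(sprintf("  Shortest paths             %d (%.1f%%)\n",
              x$shortest_paths, x$shortest_paths_pct))
  cat(sprintf("  Characteristic path length %.3f\n", x$characteristic_path_length))
  cat(sprintf("  Avg. number of neighbours  %.3f\n", x$avg_neighbors))
  invisible(x)
}

#' One-row tibble form of a topology report
#' @param x A `topology_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.topology_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Degree distribution histogram
#'
#' Counts of nodes per observed degree `k >= 1`; zero-degree nodes are
#' reported separately in attribute `"zero_degree"` so the histogram can be
#' log-log fitted directly. Counts plus the zero-degree count always sum to
#' the node total.
#'
#' @param metrics A [node_metrics()] table.
#' @param which One of `"total"`, `"in"`, `"out"`.
#' @return A tibble `(k, count)` with attribute `zero_degree`.
#' @export
degree_distribution <- function(metrics, which = c("total", "in", "out")) {
  which <- match.arg(which)
  col <- switch(which, total = "degree", `in` = "in_degree", out = "out_degree")
  deg <- metrics[[col]]
  tab <- table(deg[deg >= 1L])
  out <- tibble::tibble(k = as.integer(names(tab)), count = as.integer(tab))
  attr(out, "zero_degree") <- sum(deg == 0L)
  attr(out, "which") <- which
  out
}

# shared log10-log10 OLS used by both power-law fits
loglog_fit <- function(x, y, fitted_on) {
  keep <- x >= 1 & y > 0
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) {
    rlang::abort(sprintf(
      "Insufficient data for a log-log fit on %s: need >= 3 positive bins, have %d.",
      fitted_on, length(x)
    ))
  }
  lx <- log10(x)
  ly <- log10(y)
  degenerate <- stats::sd(ly) == 0 || stats::sd(lx) == 0
  if (degenerate) {
    gamma <- 0
    r <- 0
  } else {
    fit <- stats::lm(ly ~ lx)
    gamma <- unname(stats::coef(fit)[2])
    r <- stats::cor(lx, ly)
  }
  structure(
    list(
      gamma = gamma, r = r, r_squared = r^2,
      n_bins = length(x), degenerate = degenerate, fitted_on = fitted_on,
      data = tibble::tibble(x = x, y = y)
    ),
    class = "power_law_fit"
  )
}

#' Fit a power law to a degree histogram
#'
#' Ordinary least squares on `(log10 k, log10 count)` over bins with
#' `count >= 1` — the convention under which a scale-free distribution
#' `P(k) ~ k^-gamma` appears as a straight line whose slope is the signed
#' exponent. Reported alongside are the Pearson correlation `r` of the
#' logged pairs and the coefficient of determination `R^2 = r^2`. Fitting
#' is on the raw histogram with zero-count bins omitted; no log-binning.
#' A flat histogram is degenerate: slope 0, `r` reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param hist A `(k, count)` tibble from [degree_distribution()].
#' @return A `power_law_fit` with fields `gamma` (signed slope), `r`,
#'   `r_squared`, `n_bins`, `degenerate`, `fitted_on`.
#' @export
fit_power_law <- function(hist) {
  fitted_on <- attr(hist, "which") %||% "degree"
  loglog_fit(hist$k, hist$count, paste0(fitted_on, "-degree distribution"))
}

#' Clustering coefficient as a function of degree
#'
#' Fits the mean clustering coefficient per total-degree class against `k`
#' on log-log axes with the same estimator as [fit_power_law()]. In
#' hierarchical networks `C(k) ~ k^-1`; in pure preferential-attachment
#' networks `C(k)` is roughly independent of `k`, so the fitted slope is
#' small with low `R^2`.
#'
#' @param metrics A [node_metrics()] table.
#' @return A `power_law_fit` over degree classes with positive mean
#'   clustering.
#' @export
clustering_vs_degree <- function(metrics) {
  byk <- metrics |>
    dplyr::group_by(k = .data$degree) |>
    dplyr::summarise(c_mean = mean(.data$clustering), .groups = "drop") |>
    dplyr::filter(.data$k >= 1, .data$c_mean > 0)
  if (nrow(byk) < 3L) {
    rlang::abort("Need >= 3 degree classes with positive mean clustering.")
  }
  loglog_fit(byk$k, byk$c_mean, "clustering coefficient vs. node degree")
}

#' Maximum-likelihood power-law exponent of a degree sample
#'
#' Discrete maximum-likelihood estimate of the decay exponent `gamma` in
#' `P(k) ~ k^-gamma`, using the standard continuous-approximation
#' estimator `gamma = 1 + n / sum(log(k_i / (k_min - 1/2)))` over the tail
#' `k_i >= k_min`. When `k_min` is not supplied it is selected by
#' minimizing the Kolmogorov-Smirnov distance between the tail's empirical
#' distribution and the fitted power law (the usual tail-selection rule).
#' This is the comparison estimator: the log-log least-squares fit of
#' [fit_power_law()] remains the reporting default, and the two disagree
#' systematically — least squares on a raw histogram is dragged toward
#' shallower slopes by the noisy count-1 tail, while the MLE recovers the
#' generative exponent.
#'
#' @param degrees Integer vector of node degrees (k >= 1).
#' @param k_min Optional tail cutoff; selected by KS distance when `NULL`.
#' @param min_tail Smallest admissible tail size during selection
#'   (default 50).
#' @return An object of class `power_law_mle`: `gamma` (positive
#'   magnitude), `k_min`, `n_tail`, `ks_distance`.
#' @export
fit_power_law_mle <- function(degrees, k_min = NULL, min_tail = 50L) {
  degrees <- degrees[degrees >= 1]
  if (length(degrees) < 10L) rlang::abort("Need at least 10 positive degrees.")
  gamma_at <- function(km) {
    kk <- degrees[degrees >= km]
    1 + length(kk) / sum(log(kk / (km - 0.5)))
  }
  ks_at <- function(km, g) {
    kk <- degrees[degrees >= km]
    grid <- sort(unique(kk))
    emp <- vapply(grid, function(x) mean(kk <= x), numeric(1))
    # normalize the fitted discrete tail far past the observed maximum
    support <- seq(km, max(kk) * 3L)
    theo <- cumsum(grid^-g) / sum(support^-g)
    max(abs(emp - theo))
  }
  if (is.null(k_min)) {
    cands <- sort(unique(degrees))
    cands <- cands[vapply(cands, function(km) sum(degrees >= km),
                          numeric(1)) >= min_tail]
    if (!length(cands)) cands <- min(degrees)
    scored <- vapply(cands, function(km) {
      g <- gamma_at(km)
      c(g, ks_at(km, g))
    }, numeric(2))
    i <- which.min(scored[2, ])
    k_min <- cands[i]
    gamma <- scored[1, i]
    ks <- scored[2, i]
  } else {
    gamma <- gamma_at(k_min)
    ks <- ks_at(k_min, gamma)
  }
  structure(
    list(gamma = gamma, k_min = as.integer(k_min),
         n_tail = sum(degrees >= k_min), ks_distance = ks),
    class = "power_law_mle"
  )
}

#' @export
print.power_law_mle <- function(x, ...) {
  cat(sprintf(
    "<power_law_mle> gamma = %.3f (k_min = %d, tail n = %d, KS = %.4f)\n",
    x$gamma, x$k_min, x$n_tail, x$ks_distance
  ))
  invisible(x)
}

#' @rdname glance.power_law_fit
#' @export
glance.power_law_mle <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, k_min = x$k_min, n_tail = x$n_tail,
                 ks_distance = x$ks_distance)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> %s\n", x$fitted_on))
  cat(sprintf("  gamma = %.3f   r = %.3f   R^2 = %.3f   (%d bins%s)\n",
              x$gamma, x$r, x$r_squared, x$n_bins,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Tidy / glance methods for power-law fits
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return `tidy()`: the logged fit points; `glance()`: a one-row tibble
#'   with `gamma`, `r`, `r_squared`, `n_bins`, `degenerate`, `fitted_on`.
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, r = x$r, r_squared = x$r_squared,
    n_bins = x$n_bins, degenerate = x$degenerate, fitted_on = x$fitted_on
  )
}

#' @rdname glance.power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  dplyr::mutate(x$data, log10_x = log10(.data$x), log10_y = log10(.data$y))
}

#' Log-log plot of a power-law fit
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- tidy(object)
  intercept <- mean(d$log10_y) - object$gamma * mean(d$log10_x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_x, y = .data$log10_y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      slope = object$gamma, intercept = intercept,
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "log10 k", y = "log10 value",
      title = object$fitted_on,
      subtitle = sprintf("gamma = %.3f, R² = %.3f", object$gamma, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL
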