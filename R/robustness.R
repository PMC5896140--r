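#' Simulate node-removal attacks
#'
#' Removes a growing fraction of nodes and tracks the relative size of the
#' largest weakly connected component, `S(f)` = (main-component size after
#' removal) / (original node count). Removal is cumulative within a
#' replicate (nested subsets), so `S(f)` is non-increasing by construction.
#' Two modes: `random` failure removes uniformly sampled nodes (fresh
#' permutation per replicate, seeded); `targeted` attack removes nodes in
#' descending total-degree order computed once on the intact network (set
#' `adaptive = TRUE` to recompute degrees after every removal step). In
#' scale-free networks random failure rarely hits a hub, so the giant
#' component degrades slowly, while targeted hub removal fragments it
#' quickly — the robustness/fragility signature.
#'
#' @param net A `directed_network`.
#' @param mode `"random"` or `"targeted"`.
#' @param fractions Strictly increasing removal fractions in (0, 1).
#' @param replicates Number of random replicates (ignored for targeted).
#' @param seed Integer seed for the random mode.
#' @param compute_cpl Also compute the characteristic path length among
#'   survivors (directed; costly on large networks, default `FALSE`).
#' @param adaptive Recompute the targeted ordering after each removal step.
#' @return An object of class `attack_curve` wrapping a tibble
#'   `(mode, replicate, fraction, n_removed, S, cpl)`.
#' @export
attack <- function(net, mode = c("random", "targeted"),
                   fractions = seq(0.01, 0.30, by = 0.01),
                   replicates = 20L, seed = 1L,
                   compute_cpl = FALSE, adaptive = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "directed_network"))
  if (any(fractions <= 0 | fractions >= 1)) {
    rlang::abort("Removal fractions must lie strictly inside (0, 1).")
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    rlang::abort("Removal fractions must be strictly increasing.")
  }
  n <- n_nodes(net)
  counts <- pmin(ceiling(fractions * n), n)
  if (any(counts >= n)) rlang::abort("A fraction would remove every node.")
  g <- as_igraph(net)

  measure <- function(order_vec, rep_id) {
    rows <- vector("list", length(fractions))
    for (j in seq_along(fractions)) {
      keep <- setdiff(net$nodes, order_vec[seq_len(counts[j])])
      gs <- igraph::induced_subgraph(g, keep)
      s_rel <- max(igraph::components(gs, mode = "weak")$csize) / n
      cpl <- NA_real_
      if (compute_cpl) {
        d <- igraph::distances(gs, mode = "out")
        diag(d) <- Inf
        fin <- is.finite(d)
        cpl <- if (any(fin)) mean(d[fin]) else NA_real_
      }
      rows[[j]] <- tibble::tibble(
        mode = mode, replicate = rep_id, fraction = fractions[j],
        n_removed = counts[j], S = s_rel, cpl = cpl
      )
    }
    dplyr::bind_rows(rows)
  }

  if (mode == "random") {
    curves <- withr::with_seed(seed, {
      lapply(seq_len(replicates), function(r) measure(sample(net$nodes), r))
    })
    out <- dplyr::bind_rows(curves)
  } else {
    ord <- targeted_order(net, adaptive = adaptive, n_steps = max(counts))
    out <- measure(ord, 1L)
  }
  structure(
    list(curve = out, mode = mode, replicates = if (mode == "random") replicates else 1L,
         seed = if (mode == "random") seed else NA_integer_, n = n),
    class = "attack_curve"
  )
}

# degree-descending removal order; adaptive recomputes after each removal
targeted_order <- function(net, adaptive = FALSE, n_steps = n_nodes(net) - 1L) {
  g <- as_igraph(net)
  if (!adaptive) {
    deg <- igraph::degree(g, mode = "all")
    nm <- igraph::V(g)$name
    return(nm[order(-deg, nm)])
  }
  ord <- character(0)
  for (i in seq_len(n_steps)) {
    deg <- igraph::degree(g, mode = "all")
    nm <- igraph::V(g)$name
    pick <- nm[order(-deg, nm)][1]
    ord <- c(ord, pick)
    g <- igraph::delete_vertices(g, pick)
  }
  ord
}

#' @export
print.attack_curve <- function(x, ...) {
  cat(sprintf(
    "<attack_curve> mode %s, %d replicate(s), %d fraction(s) on %d nodes\n",
    x$mode, x$replicates, length(unique(x$curve$fraction)), x$n
  ))
  invisible(x)
}

#' Tidy an attack curve
#' @param x An `attack_curve`.
#' @param ... Unused.
#' @return The per-replicate curve tibble.
#' @export
tidy.attack_curve <- function(x, ...) x$curve

#' Replicate-averaged attack curve
#' @param x An `attack_curve`.
#' @param ... Unused.
#' @return A tibble `(mode, fraction, S_mean, S_sd, cpl_mean)`.
#' @export
glance.attack_curve <- function(x, ...) {
  x$curve |>
    dplyr::group_by(.data$mode, .data$fraction) |>
    dplyr::summarise(
      S_mean = mean(.data$S), S_sd = stats::sd(.data$S),
      cpl_mean = mean(.data$cpl), .groups = "drop"
    )
}

#' Plot attack curves
#'
#' @param object An `attack_curve`, or a list of them to overlay (e.g.
#'   random vs targeted).
#' @param ... Further `attack_curve` objects to overlay.
#' @return A ggplot of mean `S(f)` against the removal fraction.
#' @export
autoplot.attack_curve <- function(object, ...) {
  curves <- c(list(object), Filter(function(o) inherits(o, "attack_curve"), list(...)))
  d <- dplyr::bind_rows(lapply(curves, glance))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$fraction, y = .data$S_mean, colour = .data$mode
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "fraction of nodes removed", y = "relative main-component size S(f)",
      colour = NULL
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Probability that a uniformly random failure hits a controller
#'
#' `100 * hub_count / N`, rounded to one decimal: with few controllers,
#' random damage rarely lands on one, which is what makes a scale-free
#' network robust to random failure.
#'
#' @param hub_count Number of controller (hub) nodes, `0 <= hub_count <= N`.
#' @param n Total node count (>= 1).
#' @return Percentage rounded to one decimal.
#' @examples
#' hub_hit_probability(196, 7758) # 2.5
#' @export
hub_hit_probability <- function(hub_count, n) {
  if (n < 1) rlang::abort("Node count must be >= 1.")
  if (hub_count < 0 || hub_count > n) {
    rlang::abort("`hub_count` must lie in [0, n].")
  }
  round(100 * hub_count / n, 1)
}
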