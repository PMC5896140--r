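#' Weakly connected components of a directed network
#'
#' Edge direction is ignored for membership (weak connectivity): a merged
#' pathway union is only connected in this sense. Components are ordered by
#' decreasing size, ties broken by the lexicographically smallest member;
#' component 1 is the main component.
#'
#' @param net A non-empty `directed_network`.
#' @return An object of class `component_decomposition`: a list with
#'   `members` (list of sorted node vectors), `sizes`, and `main` (index of
#'   the largest component, always 1 after ordering).
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  if (n_nodes(net) == 0L) rlang::abort("Cannot decompose an empty network.")
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "weak")
  members <- split(igraph::V(g)$name, comp$membership)
  members <- lapply(members, sort)
  smallest <- vapply(members, `[[`, character(1), 1L)
  ord <- order(-lengths(members), smallest)
  members <- unname(members[ord])
  structure(
    list(members = members, sizes = lengths(members), main = 1L),
    class = "component_decomposition"
  )
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf(
    "<component_decomposition> %d component(s); main has %d node(s)\n",
    length(x$members), x$sizes[x$main]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a component decomposition into a node-level table
#'
#' @param x A `component_decomposition`.
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `component` (1 = main),
#'   `component_size`.
#' @export
tidy.component_decomposition <- function(x, ...) {
  tibble::tibble(
    node = unlist(x$members, use.names = FALSE),
    component = rep.int(seq_along(x$members), x$sizes),
    component_size = rep.int(x$sizes, x$sizes)
  )
}

#' Extract the main (largest weak) component
#'
#' Returns the induced subnetwork on the largest weakly connected component.
#' The share of nodes it retains, as a percentage rounded to one decimal, is
#' attached as attribute `"share"` (see [component_share()]).
#'
#' @param net A non-empty `directed_network`.
#' @return A `directed_network` with attribute `share`.
#' @export
main_component <- function(net) {
  comp <- connected_components(net)
  keep <- comp$members[[comp$main]]
  out <- induced_network(net, keep)
  attr(out, "share") <- component_share(length(keep), n_nodes(net))
  out
}

#' Percentage of a network captured by a component
#'
#' `100 * n_sub / n_total`, rounded to one decimal place — the convention
#' used when reporting what share of a network its main component retains.
#'
#' @param n_sub Node count of the component.
#' @param n_total Node count of the whole network.
#' @return A percentage rounded to one decimal.
#' @examples
#' component_share(7758, 7892) # 98.3
#' @export
component_share <- function(n_sub, n_total) {
  if (n_total <= 0) rlang::abort("Total node count must be positive.")
  round(100 * n_sub / n_total, 1)
}

# induced subnetwork on a node subset (keeps edges with both endpoints inside)
induced_network <- function(net, nodes) {
  nodes <- intersect(net$nodes, nodes)
  e <- dplyr::filter(net$edges, .data$source %in% nodes, .data$target %in% nodes)
  directed_network(e, nodes = nodes)
}

#' Intersection of two directed networks
#'
#' Nodes are the node-set intersection; edges are the
#' `(source, interaction, target)` triples present in both networks (their
#' endpoints necessarily survive). Scores are taken from the first network.
#'
#' @param net1,net2 `directed_network` objects.
#' @return A `directed_network`, possibly empty.
#' @export
intersect_networks <- function(net1, net2) {
  stopifnot(inherits(net1, "directed_network"), inherits(net2, "directed_network"))
  nodes <- intersect(net1$nodes, net2$nodes)
  e <- dplyr::semi_join(
    net1$edges, net2$edges,
    by = c("source", "interaction", "target")
  )
  directed_network(e, nodes = nodes)
}

#' Union-merge a list of directed networks
#'
#' Node and edge sets are unioned with duplicate collapse (maximum score
#' kept) — the operation that merges pathway fragments into one network.
#'
#' @param nets A list of `directed_network` objects (length >= 1).
#' @return A `directed_network`.
#' @export
union_merge <- function(nets) {
  if (inherits(nets, "directed_network")) nets <- list(nets)
  if (length(nets) == 0L) rlang::abort("union_merge() needs at least one network.")
  stopifnot(all(vapply(nets, inherits, logical(1), "directed_network")))
  edges <- dplyr::bind_rows(lapply(nets, function(n) n$edges))
  nodes <- unique(unlist(lapply(nets, function(n) n$nodes), use.names = FALSE))
  directed_network(edges, nodes = nodes)
}
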