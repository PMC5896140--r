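#' Construct a directed network from an edge table
#'
#' The central container of the package: a directed network over string node
#' identifiers, stored as a tibble of edge records plus a node vector. Edge
#' records are `(source, interaction, target, score)`; duplicate
#' `(source, interaction, target)` triples are collapsed, keeping the maximum
#' confidence score (a confidence semantics: the best evidence wins).
#' Self-loops are permitted and flagged by `summary()`.
#'
#' @param edges A data frame with columns `source` and `target` (character),
#'   and optionally `interaction` (character, default `"pp"`) and `score`
#'   (integer 0-1000, `NA` allowed).
#' @param nodes Optional character vector of node identifiers; the union of
#'   edge endpoints is always included. Use this to carry isolated nodes.
#' @return An object of class `directed_network`: a list with `edges`
#'   (tibble) and `nodes` (sorted character vector).
#' @examples
#' net <- directed_network(data.frame(source = c("A", "B"), target = c("B", "C")))
#' n_nodes(net)
#' @export
directed_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edge_tbl <- tibble::tibble(
      source = character(), interaction = character(),
      target = character(), score = integer()
    )
  } else {
    edges <- tibble::as_tibble(edges)
    if (!all(c("source", "target") %in% names(edges))) {
      rlang::abort("`edges` must have `source` and `target` columns.")
    }
    if (!"interaction" %in% names(edges)) edges$interaction <- "pp"
    if (!"score" %in% names(edges)) edges$score <- NA_integer_
    edge_tbl <- edges[, c("source", "interaction", "target", "score")]
    edge_tbl$source <- as.character(edge_tbl$source)
    edge_tbl$interaction <- as.character(edge_tbl$interaction)
    edge_tbl$target <- as.character(edge_tbl$target)
    edge_tbl$score <- as.integer(edge_tbl$score)
    bad <- !is.na(edge_tbl$score) & (edge_tbl$score < 0L | edge_tbl$score > 1000L)
    if (any(bad)) {
      rlang::abort(sprintf(
        "Edge scores must lie in [0, 1000]; %d record(s) violate this.", sum(bad)
      ))
    }
    if (any(!nzchar(edge_tbl$source)) || any(!nzchar(edge_tbl$target))) {
      rlang::abort("Node identifiers must be non-empty strings.")
    }
    edge_tbl <- collapse_duplicate_edges(edge_tbl)
  }
  all_nodes <- sort(unique(c(edge_tbl$source, edge_tbl$target, as.character(nodes))))
  structure(list(edges = edge_tbl, nodes = all_nodes), class = "directed_network")
}

# max-score collapse of duplicate (source, interaction, target) triples
collapse_duplicate_edges <- function(edge_tbl, quiet = TRUE) {
  key <- paste(edge_tbl$source, edge_tbl$interaction, edge_tbl$target, sep = "\r")
  if (!anyDuplicated(key)) {
    return(dplyr::arrange(edge_tbl, .data$source, .data$target, .data$interaction))
  }
  n_dup <- sum(duplicated(key))
  out <- edge_tbl |>
    dplyr::group_by(.data$source, .data$interaction, .data$target) |>
    dplyr::summarise(
      score = if (all(is.na(.data$score))) NA_integer_ else
        as.integer(max(.data$score, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$source, .data$target, .data$interaction)
  if (!quiet) {
    rlang::inform(sprintf(
      "Collapsed %d duplicate edge record(s), keeping the maximum score.", n_dup
    ))
  }
  out
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf(
    "<directed_network> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)
  ))
  if (nrow(x$edges) > 0) print(utils::head(x$edges, 5))
  invisible(x)
}

#' @export
summary.directed_network <- function(object, ...) {
  loops <- sum(object$edges$source == object$edges$target)
  scored <- sum(!is.na(object$edges$score))
  cat(sprintf(
    paste0(
      "Directed network: %d nodes, %d edges (%d self-loop%s, %d scored)\n"
    ),
    length(object$nodes), nrow(object$edges), loops,
    if (loops == 1) "" else "s", scored
  ))
  invisible(object)
}

#' Number of nodes / edges in a network
#' @param net A `directed_network`.
#' @return An integer count.
#' @export
n_nodes <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  length(net$nodes)
}

#' @rdname n_nodes
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  nrow(net$edges)
}

#' Edge table of a network
#'
#' @param x A `directed_network`.
#' @param ... Unused.
#' @return The edge tibble (`source`, `interaction`, `target`, `score`).
#' @export
as_tibble.directed_network <- function(x, ...) {
  x$edges
}

#' Convert a network to an igraph object
#'
#' Parallel edges with distinct interaction labels are collapsed to a single
#' arc, so graph metrics see the simple directed graph; self-loops are kept.
#'
#' @param net A `directed_network`.
#' @param simplify Collapse parallel arcs (default `TRUE`).
#' @return An `igraph` graph whose vertices are the network's nodes, in
#'   sorted order.
#' @export
as_igraph <- function(net, simplify = TRUE) {
  stopifnot(inherits(net, "directed_network"))
  el <- net$edges[, c("source", "target")]
  if (simplify) el <- dplyr::distinct(el)
  igraph::graph_from_data_frame(
    el,
    directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Test two networks for equality of node and edge sets
#'
#' Equality is on sets: row order never matters. Scores are compared when
#' `scores = TRUE`.
#'
#' @param a,b `directed_network` objects.
#' @param scores Compare the score column too (default `TRUE`).
#' @return Logical scalar.
#' @export
network_identical <- function(a, b, scores = TRUE) {
  stopifnot(inherits(a, "directed_network"), inherits(b, "directed_network"))
  if (!identical(a$nodes, b$nodes)) return(FALSE)
  ea <- dplyr::arrange(a$edges, .data$source, .data$target, .data$interaction)
  eb <- dplyr::arrange(b$edges, .data$source, .data$target, .data$interaction)
  if (!scores) {
    ea$score <- NULL
    eb$score <- NULL
  }
  isTRUE(all.equal(as.data.frame(ea), as.data.frame(eb), check.attributes = FALSE))
}
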