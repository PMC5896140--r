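#' Read a directed network from a SIF or TSV edge list
#'
#' Two dialects are supported. `sif` is the Cytoscape simple-interaction
#' format: whitespace-separated `source relation target`, one edge per row.
#' `tsv` is a tab-separated edge list with 2 columns (`source`, `target`;
#' the interaction label defaults to `"pp"`), 3 columns
#' (`source`, `interaction`, `target`) or 4 columns (plus an integer
#' confidence `score` in 0-1000); an optional header row
#' `source<TAB>interaction<TAB>target<TAB>score` is recognized and skipped.
#' Duplicate rows are collapsed (set semantics, maximum score kept).
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (by file extension), `"sif"` or `"tsv"`.
#' @return A [directed_network()].
#' @export
read_network <- function(path, dialect = c("auto", "sif", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    rlang::abort(sprintf("Empty network file: %s", path))
  }
  if (dialect == "sif") {
    rows <- lapply(keep, function(i) {
      f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
      if (length(f) != 3L) {
        rlang::abort(sprintf(
          "Malformed SIF row at line %d of %s: expected 3 fields, found %d.",
          i, path, length(f)
        ))
      }
      f
    })
    m <- do.call(rbind, rows)
    edges <- tibble::tibble(
      source = m[, 1], interaction = m[, 2], target = m[, 3],
      score = NA_integer_
    )
  } else {
    first <- strsplit(lines[[keep[1]]], "\t", fixed = TRUE)[[1]]
    has_header <- identical(tolower(first[1]), "source")
    if (has_header) keep <- keep[-1]
    if (length(keep) == 0L) {
      rlang::abort(sprintf("Empty network file (header only): %s", path))
    }
    rows <- lapply(keep, function(i) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (!length(f) %in% c(2L, 3L, 4L)) {
        rlang::abort(sprintf(
          "Malformed TSV row at line %d of %s: expected 2-4 fields, found %d.",
          i, path, length(f)
        ))
      }
      out <- switch(as.character(length(f)),
        "2" = c(f[1], "pp", f[2], NA),
        "3" = c(f[1], f[2], f[3], NA),
        "4" = f
      )
      if (!is.na(out[4]) && nzchar(out[4]) &&
          is.na(suppressWarnings(as.integer(out[4])))) {
        rlang::abort(sprintf(
          "Malformed score at line %d of %s: %s", i, path, out[4]
        ))
      }
      out
    })
    m <- do.call(rbind, rows)
    score <- suppressWarnings(as.integer(m[, 4]))
    edges <- tibble::tibble(
      source = m[, 1], interaction = m[, 2], target = m[, 3], score = score
    )
  }
  directed_network(edges)
}

#' Write a directed network to a SIF or TSV edge list
#'
#' The TSV dialect always writes the full 4-column header
#' (`source`, `interaction`, `target`, `score`; empty score for unscored
#' edges) so that `read_network(write_network(net))` round-trips the edge
#' set exactly. The SIF dialect drops scores (the format has no score
#' column).
#'
#' @param net A `directed_network`.
#' @param path Output path.
#' @param dialect `"sif"` or `"tsv"`.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("tsv", "sif")) {
  stopifnot(inherits(net, "directed_network"))
  dialect <- match.arg(dialect)
  if (n_edges(net) == 0L) {
    rlang::warn("Writing an empty network: output file will have no edge rows.")
  }
  e <- net$edges
  if (dialect == "sif") {
    if (any(!is.na(e$score))) {
      rlang::warn("SIF has no score column; edge scores are dropped on write.")
    }
    body <- sprintf("%s %s %s", e$source, e$interaction, e$target)
    writeLines(body, path, useBytes = TRUE)
  } else {
    sc <- ifelse(is.na(e$score), "", as.character(e$score))
    body <- c(
      "source\tinteraction\ttarget\tscore",
      sprintf("%s\t%s\t%s\t%s", e$source, e$interaction, e$target, sc)
    )
    writeLines(body, path, useBytes = TRUE)
  }
  invisible(net)
}

#' Export a network as GraphML
#'
#' GraphML export for external viewers; node names and edge interaction
#' labels are carried as attributes.
#'
#' @inheritParams write_network
#' @return `net`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "interaction", "score")],
    directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(net)
}
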