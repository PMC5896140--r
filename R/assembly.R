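#' Read and validate an alias table
#'
#' A 2-column TSV `alias<TAB>canonical` mapping synonym identifiers to their
#' canonical form. Validation enforces one-step resolution: canonical IDs
#' must be fixed points (a canonical ID never appears as an alias of a
#' different ID), so chains and cycles in the table are configuration errors
#' surfaced before any renaming happens.
#'
#' @param path Path to the TSV file (optional header `alias<TAB>canonical`).
#' @return A tibble with columns `alias` and `canonical`.
#' @export
read_alias_map <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^alias\t", tolower(lines[[1]]))) lines <- lines[-1]
  if (length(lines) == 0L) {
    return(validate_alias_map(tibble::tibble(alias = character(), canonical = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    rlang::abort(sprintf("Malformed alias row(s) in %s at line(s): %s",
                         path, paste(utils::head(bad, 5), collapse = ", ")))
  }
  m <- do.call(rbind, parts)
  validate_alias_map(tibble::tibble(alias = m[, 1], canonical = m[, 2]))
}

#' @rdname read_alias_map
#' @param alias_map A data frame with columns `alias`, `canonical`.
#' @export
validate_alias_map <- function(alias_map) {
  alias_map <- tibble::as_tibble(alias_map)[, c("alias", "canonical")]
  if (anyDuplicated(alias_map$alias)) {
    dup <- unique(alias_map$alias[duplicated(alias_map$alias)])
    rlang::abort(sprintf("Alias mapped more than once: %s",
                         paste(utils::head(dup, 5), collapse = ", ")))
  }
  # chains/cycles: an alias whose canonical target is itself an alias of
  # something else would require transitive resolution
  chained <- alias_map$canonical %in%
    alias_map$alias[alias_map$alias != alias_map$canonical]
  chained <- chained & (alias_map$alias != alias_map$canonical)
  if (any(chained)) {
    rlang::abort(sprintf(
      "Alias table contains chains or cycles (one-step resolution required): %s",
      paste(utils::head(alias_map$alias[chained], 5), collapse = ", ")
    ))
  }
  alias_map[alias_map$alias != alias_map$canonical, ]
}

#' Harmonize node identifiers against an alias table
#'
#' Renames every aliased node to its canonical identifier. Merged nodes
#' inherit the union of incident edges; duplicate edge records created by
#' the merge are collapsed (maximum score kept). Node count never increases,
#' and the operation is idempotent.
#'
#' @param net A `directed_network`.
#' @param alias_map A validated alias table (see [read_alias_map()]).
#' @return A `directed_network` on canonical identifiers.
#' @export
harmonize <- function(net, alias_map) {
  stopifnot(inherits(net, "directed_network"))
  alias_map <- validate_alias_map(alias_map)
  if (nrow(alias_map) == 0L) return(net)
  lut <- stats::setNames(alias_map$canonical, alias_map$alias)
  rename <- function(x) {
    hit <- x %in% names(lut)
    x[hit] <- unname(lut[x[hit]])
    x
  }
  e <- net$edges
  e$source <- rename(e$source)
  e$target <- rename(e$target)
  directed_network(e, nodes = rename(net$nodes))
}

#' Filter interaction records by confidence score
#'
#' Keeps exactly the records whose score is strictly greater than
#' `min_score` (high-confidence enrichment uses threshold 900, so only
#' scores of 901 and above survive the default). Records lacking a score
#' cannot certify their confidence and are dropped with a warning. Row
#' order is preserved.
#'
#' @param edges An edge table (`source`, `interaction`, `target`, `score`).
#' @param min_score Strict lower bound, in `[0, 1000]` (default 900).
#' @return The surviving subset of `edges`, in the original order.
#' @export
filter_interactions <- function(edges, min_score = 900) {
  edges <- tibble::as_tibble(edges)
  if (min_score < 0 || min_score > 1000) {
    rlang::abort("`min_score` must lie in [0, 1000].")
  }
  if (nrow(edges) == 0L) return(edges)
  if (!"score" %in% names(edges)) edges$score <- NA_integer_
  unscored <- is.na(edges$score)
  if (any(unscored)) {
    rlang::warn(sprintf(
      "%d record(s) lack a confidence score and were dropped.", sum(unscored)
    ))
  }
  edges[!unscored & edges$score > min_score, ]
}

#' Assemble a network from pathway fragments, aliases and enrichment edges
#'
#' The three-stage construction pipeline: (1) union-merge the pathway
#' edge-list files; (2) harmonize identifiers against the alias table;
#' (3) add enrichment interactions that pass the strict confidence filter,
#' restricted to node pairs already present in the harmonized union —
#' enrichment completes the network among its own molecules, it never
#' expands the node set. Per-stage node/edge counts are reported via
#' messages.
#'
#' @param pathway_files Character vector of SIF/TSV pathway files.
#' @param alias_file Optional alias-table TSV (see [read_alias_map()]).
#' @param enrichment_file Optional 4-column TSV of scored candidate edges.
#' @param min_score Strict score threshold for enrichment (default 900).
#' @param enrichment_mode `"directed"` adds rows as listed; `"undirected"`
#'   treats each row as an unordered association and adds both directions.
#' @param quiet Suppress per-stage count messages.
#' @return The assembled `directed_network`.
#' @export
assemble <- function(pathway_files, alias_file = NULL, enrichment_file = NULL,
                     min_score = 900,
                     enrichment_mode = c("directed", "undirected"),
                     quiet = FALSE) {
  enrichment_mode <- match.arg(enrichment_mode)
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  if (length(pathway_files) == 0L) rlang::abort("No pathway files given.")
  nets <- lapply(pathway_files, function(p) {
    tryCatch(read_network(p), error = function(e) {
      rlang::abort(sprintf("[assemble/pathways] %s", conditionMessage(e)))
    })
  })
  net <- union_merge(nets)
  say("Pathway union: %d nodes, %d edges from %d file(s).",
      n_nodes(net), n_edges(net), length(pathway_files))

  if (!is.null(alias_file)) {
    aliases <- tryCatch(read_alias_map(alias_file), error = function(e) {
      rlang::abort(sprintf("[assemble/aliases] %s", conditionMessage(e)))
    })
    net <- harmonize(net, aliases)
    say("After harmonization: %d nodes, %d edges (%d alias entries).",
        n_nodes(net), n_edges(net), nrow(aliases))
  }

  if (!is.null(enrichment_file)) {
    enet <- tryCatch(read_network(enrichment_file, dialect = "tsv"),
                     error = function(e) {
      rlang::abort(sprintf("[assemble/enrichment] %s", conditionMessage(e)))
    })
    cand <- suppressWarnings(filter_interactions(enet$edges, min_score))
    inside <- cand$source %in% net$nodes & cand$target %in% net$nodes
    if (any(!inside)) {
      rlang::warn(sprintf(
        "%d enrichment edge(s) touch nodes absent from the pathway union and were dropped.",
        sum(!inside)
      ))
    }
    cand <- cand[inside, ]
    if (enrichment_mode == "undirected" && nrow(cand) > 0L) {
      rev <- cand
      rev$source <- cand$target
      rev$target <- cand$source
      cand <- dplyr::bind_rows(cand, rev)
      say("Undirected enrichment: each association added in both directions.")
    }
    net <- directed_network(dplyr::bind_rows(net$edges, cand), nodes = net$nodes)
    say("After enrichment (score > %d): %d nodes, %d edges (%d candidate(s) admitted).",
        min_score, n_nodes(net), n_edges(net), nrow(cand))
  }
  net
}
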