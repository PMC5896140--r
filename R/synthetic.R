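#' Generate a directed preferential-attachment (Barabasi-Albert) network
#'
#' Growth with preferential attachment: the generator starts from a
#' complete symmetric clique on `m0` nodes (avoiding zero-degree
#' attachment pathologies) and adds nodes one at a time; each arriving
#' node draws `m` distinct existing targets with probability proportional
#' to current total degree, `p_i = k_i / sum_j k_j`, and the new edges are
#' directed new -> target. Distinct targets are obtained by sequential
#' draws with rejection of repeats. The resulting degree distribution is a
#' power law `P(k) ~ k^-gamma`; with this linear attachment kernel the
#' exponent magnitude falls in the classical 2-3 band.
#'
#' Node identifiers are zero-padded (`n00001`, ...) so lexicographic order
#' equals arrival order.
#'
#' @param n Target node count (> `m0`). Default 2000 — the scale of a
#'   mid-sized curated interactome.
#' @param m Edges added per arriving node (default 2, which gives a mean
#'   total degree near 4, comparable to sparse pathway unions).
#' @param m0 Seed-clique size (>= `m`; defaults to `m + 1`).
#' @param seed Integer seed; the edge set is bit-reproducible given
#'   `(n, m, m0, seed)`.
#' @return A `directed_network` with `m0 (m0 - 1) + m (n - m0)` edges.
#' @export
generate_ba <- function(n = 2000L, m = 2L, m0 = m + 1L, seed = 1L) {
  n <- as.integer(n); m <- as.integer(m); m0 <- as.integer(m0)
  if (m < 1L) rlang::abort("`m` must be >= 1.")
  if (m0 < m) rlang::abort("`m0` must be >= m.")
  if (m0 < 2L) rlang::abort("`m0` must be >= 2 (the seed clique needs an edge).")
  if (n <= m0) rlang::abort("`n` must exceed the seed-clique size m0.")
  width <- nchar(as.character(n))
  ids <- sprintf(paste0("n%0", width, "d"), seq_len(n))

  n_edges_total <- m0 * (m0 - 1L) + m * (n - m0)
  src <- integer(n_edges_total)
  tgt <- integer(n_edges_total)
  # symmetric seed clique
  pairs <- which(outer(seq_len(m0), seq_len(m0), "!="), arr.ind = TRUE)
  ne <- nrow(pairs)
  src[seq_len(ne)] <- pairs[, 1]
  tgt[seq_len(ne)] <- pairs[, 2]

  deg <- numeric(n)
  deg[seq_len(m0)] <- 2 * (m0 - 1)

  withr::with_seed(seed, {
    for (t in (m0 + 1L):n) {
      cum <- cumsum(deg[seq_len(t - 1L)])
      total <- cum[t - 1L]
      picked <- integer(0)
      while (length(picked) < m) {
        cand <- findInterval(stats::runif(1) * total, cum) + 1L
        if (!cand %in% picked) picked <- c(picked, cand)
      }
      idx <- ne + seq_len(m)
      src[idx] <- t
      tgt[idx] <- picked
      ne <- ne + m
      deg[t] <- deg[t] + m
      deg[picked] <- deg[picked] + 1
    }
  })
  directed_network(tibble::tibble(
    source = ids[src], interaction = "pp", target = ids[tgt],
    score = NA_integer_
  ))
}

#' Fragment a network into pathway files, an alias table and enrichment
#'
#' Emulates the raw material a pathway-database export produces: the edge
#' set is partitioned into `n_pathways` overlapping edge-list files
#' (every edge appears in at least one file); a configurable fraction of
#' nodes is given a synonym identifier which replaces the canonical one in
#' a random subset of the fragments (the alias table maps synonym ->
#' canonical); and an enrichment table lists extra within-network node
#' pairs with integer confidence scores, a configured share of which
#' exceeds 900. Running [assemble()] on the output reconstructs the source
#' network exactly whenever the above-threshold enrichment share is zero.
#'
#' @param net The source `directed_network`.
#' @param dir Output directory (created if needed).
#' @param n_pathways Number of pathway files (default 32, a typical count
#'   of curated pathways behind one interactome).
#' @param overlap Fraction of extra, already-covered edges resampled into
#'   each fragment (default 0.2), creating pathway overlap.
#' @param alias_fraction Fraction of nodes given a synonym (default 0.1).
#' @param n_enrichment Number of enrichment candidate pairs (default 200).
#' @param high_score_share Share of enrichment scores strictly above 900
#'   (default 0).
#' @param seed Integer seed.
#' @return A list: `pathway_files`, `alias_file`, `enrichment_file`, and
#'   `bookkeeping` (tibble of generator counts, including
#'   `n_enrichment_above_900`).
#' @export
fragment_network <- function(net, dir, n_pathways = 32L, overlap = 0.2,
                             alias_fraction = 0.1, n_enrichment = 200L,
                             high_score_share = 0, seed = 1L) {
  stopifnot(inherits(net, "directed_network"))
  if (n_edges(net) == 0L) rlang::abort("Cannot fragment an empty network.")
  if (overlap < 0 || alias_fraction < 0 || alias_fraction > 1 ||
      high_score_share < 0 || high_score_share > 1) {
    rlang::abort("Fractions must lie in [0, 1] (overlap >= 0).")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- net$edges
  ne <- nrow(e)
  n_pathways <- min(as.integer(n_pathways), ne)

  withr::with_seed(seed, {
    # every edge gets a primary fragment; overlap adds resampled extras
    primary <- sample(rep_len(seq_len(n_pathways), ne))
    extras <- lapply(seq_len(n_pathways), function(p) {
      k <- round(overlap * sum(primary == p))
      if (k > 0) sample(ne, min(k, ne)) else integer(0)
    })
    # aliases: a synonym per selected node, applied per fragment with prob 1/2
    n_alias <- round(alias_fraction * length(net$nodes))
    aliased_nodes <- sort(sample(net$nodes, n_alias))
    alias_ids <- paste0(aliased_nodes, "_syn")
    lut <- stats::setNames(alias_ids, aliased_nodes)

    pathway_files <- character(n_pathways)
    for (p in seq_len(n_pathways)) {
      rows <- e[sort(unique(c(which(primary == p), extras[[p]]))), ]
      use_alias <- aliased_nodes[stats::runif(n_alias) < 0.5]
      if (length(use_alias)) {
        sub <- stats::setNames(lut[use_alias], use_alias)
        hit_s <- rows$source %in% names(sub)
        hit_t <- rows$target %in% names(sub)
        rows$source[hit_s] <- unname(sub[rows$source[hit_s]])
        rows$target[hit_t] <- unname(sub[rows$target[hit_t]])
      }
      f <- file.path(dir, sprintf("pathway_%02d.sif", p))
      writeLines(sprintf("%s %s %s", rows$source, rows$interaction, rows$target), f)
      pathway_files[p] <- f
    }

    alias_file <- file.path(dir, "aliases.tsv")
    writeLines(
      c("alias\tcanonical", sprintf("%s\t%s", alias_ids, aliased_nodes)),
      alias_file
    )

    # enrichment: random ordered in-network pairs with confidence scores
    n_enrichment <- as.integer(n_enrichment)
    n_high <- round(high_score_share * n_enrichment)
    if (n_enrichment > 0) {
      s <- sample(net$nodes, n_enrichment, replace = TRUE)
      t <- sample(net$nodes, n_enrichment, replace = TRUE)
      fix <- s == t
      while (any(fix)) { # no self-pairs in the candidate table
        t[fix] <- sample(net$nodes, sum(fix), replace = TRUE)
        fix <- s == t
      }
      score <- integer(n_enrichment)
      hi <- seq_len(n_high)
      score[hi] <- sample(901:1000, n_high, replace = TRUE)
      if (n_high < n_enrichment) {
        score[setdiff(seq_len(n_enrichment), hi)] <-
          sample(0:900, n_enrichment - n_high, replace = TRUE)
      }
      enr <- tibble::tibble(source = s, interaction = "pp", target = t,
                            score = score)
    } else {
      enr <- tibble::tibble(source = character(), interaction = character(),
                            target = character(), score = integer())
    }
    enrichment_file <- file.path(dir, "enrichment.tsv")
    writeLines(
      c("source\tinteraction\ttarget\tscore",
        sprintf("%s\t%s\t%s\t%d", enr$source, enr$interaction, enr$target,
                enr$score)),
      enrichment_file
    )
  })

  list(
    pathway_files = pathway_files,
    alias_file = alias_file,
    enrichment_file = enrichment_file,
    bookkeeping = tibble::tibble(
      n_nodes = n_nodes(net), n_edges = ne, n_pathways = n_pathways,
      n_aliased_nodes = length(aliased_nodes),
      n_enrichment = n_enrichment, n_enrichment_above_900 = n_high
    )
  )
}

#' Simulate knockout-phenotype annotations for hub and non-hub nodes
#'
#' Each class samples which of its nodes carry knockout data (hubs are
#' better studied than non-hubs) and assigns each studied node one of the
#' four fertility categories from its class multinomial. Defaults are the
#' observed class proportions of the reference knockout comparison: hub
#' category probabilities (0.238, 0.143, 0.143, 0.476) with 35.6% studied;
#' non-hub probabilities (0.278, 0.174, 0.275, 0.272) with 19.6% studied.
#'
#' @param hubs,non_hubs Disjoint character vectors of node identifiers.
#' @param p_hub,p_nonhub Probability vectors over [phenotype_categories]
#'   (each sums to 1).
#' @param studied_hub,studied_nonhub Fraction of each class with knockout
#'   data.
#' @param seed Integer seed.
#' @return A tibble `(node, category)` covering the studied nodes only.
#' @export
simulate_phenotypes <- function(hubs, non_hubs,
                                p_hub = c(0.238, 0.143, 0.143, 0.476),
                                p_nonhub = c(0.278, 0.174, 0.275, 0.272),
                                studied_hub = 0.356, studied_nonhub = 0.196,
                                seed = 1L) {
  if (length(intersect(hubs, non_hubs))) {
    rlang::abort("Hub and non-hub lists must be disjoint.")
  }
  check_p <- function(p, nm) {
    # 0.005 slack: class proportions quoted from one-decimal percentages
    # need not sum exactly to 1
    if (length(p) != 4L || abs(sum(p) - 1) > 0.005 || any(p < 0)) {
      rlang::abort(sprintf("`%s` must be 4 non-negative probabilities summing to 1.", nm))
    }
    p / sum(p)
  }
  p_hub <- check_p(p_hub, "p_hub")
  p_nonhub <- check_p(p_nonhub, "p_nonhub")
  withr::with_seed(seed, {
    draw <- function(nodes, studied, p) {
      k <- round(studied * length(nodes))
      if (k == 0L) {
        return(tibble::tibble(node = character(), category = character()))
      }
      picked <- sample(nodes, k)
      tibble::tibble(
        node = picked,
        category = sample(phenotype_categories, k, replace = TRUE, prob = p)
      )
    }
    dplyr::bind_rows(
      draw(hubs, studied_hub, p_hub),
      draw(non_hubs, studied_nonhub, p_nonhub)
    )
  })
}

#' Planted hub clustering-coefficient sample
#'
#' Draws a clustering-coefficient sample with two planted hub
#' subpopulations, for exercising [kde_split()]: "party" hubs (partners
#' engaged simultaneously, low clustering) uniform on `[0, 0.17]` and
#' "date" hubs (partners engaged at different times or places, high
#' clustering) uniform on `[0.83, 0.89]`.
#'
#' @param n_party,n_date Subpopulation sizes (>= 0).
#' @param seed Integer seed.
#' @return A tibble `(value, group)` with `group` in
#'   `{"party", "date"}`.
#' @export
planted_hub_metrics <- function(n_party = 100L, n_date = 30L, seed = 1L) {
  if (n_party < 0 || n_date < 0) rlang::abort("Sizes must be >= 0.")
  withr::with_seed(seed, {
    tibble::tibble(
      value = c(stats::runif(n_party, 0, 0.17), stats::runif(n_date, 0.83, 0.89)),
      group = rep(c("party", "date"), c(n_party, n_date))
    )
  })
}
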