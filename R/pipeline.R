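#' Default pipeline configuration
#'
#' Returns the full default configuration for [run_pipeline()], which user
#' configurations (lists or YAML files) are merged over. By default the
#' pipeline simulates its own inputs: a preferential-attachment network of
#' 2000 nodes fragmented into 32 aliased pathway files plus a scored
#' enrichment table, reassembled through the same code path real exports
#' would take.
#'
#' @return A nested list of configuration defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(
      # key is n_nodes, not n: YAML 1.1 reads a bare `n` key as a boolean
      enabled = TRUE, n_nodes = 2000L, m = 2L, m0 = 3L,
      n_pathways = 32L, overlap = 0.2, alias_fraction = 0.1,
      n_enrichment = 200L, high_score_share = 0.25
    ),
    input = list(
      pathway_files = NULL, alias_file = NULL, enrichment_file = NULL,
      network_file = NULL
    ),
    min_score = 900L,
    whole_network = FALSE,
    stages = list(topology = TRUE, controllers = TRUE,
                  robustness = TRUE, phenotype = TRUE),
    hubs = list(sigma_mult = 1),
    bottlenecks = list(k = NULL), # NULL = same cardinality as the hub list
    attack = list(fractions = seq(0.05, 0.30, by = 0.05), replicates = 5L),
    phenotype = list(
      p_hub = c(0.238, 0.143, 0.143, 0.476),
      p_nonhub = c(0.278, 0.174, 0.275, 0.272),
      studied_hub = 0.356, studied_nonhub = 0.196
    )
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' One-command orchestration of assemble -> main component -> topology ->
#' controllers -> robustness -> phenotype. The configuration is a nested
#' list (or the path to a YAML file with the same structure) merged over
#' [pipeline_defaults()]. With the default `simulate` block enabled, no
#' input files are needed: the generators produce pathway fragments, an
#' alias table, an enrichment table and phenotype annotations, all seeded
#' from `config$seed`, and the run is bit-reproducible.
#'
#' Analyses run on the main (largest weakly connected) component unless
#' `whole_network = TRUE`. Stage failures abort with the stage name;
#' per-stage timings go to messages.
#'
#' @param config A nested list, a YAML file path, or `NULL` for pure
#'   defaults.
#' @param out_dir Optional directory: writes `report.json` plus per-stage
#'   TSVs (node metrics, bottleneck scores, attack curves, phenotype
#'   table).
#' @param quiet Suppress progress messages.
#' @return A report list (schema version `"1.0"`) with one element per
#'   enabled stage; all seeds used are echoed in `$seeds`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config %||% list())
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  seed <- as.integer(cfg$seed)
  report <- list(schema_version = "1.0", seeds = list(master = seed))

  net <- stage("input", {
    if (isTRUE(cfg$simulate$enabled)) {
      sim <- cfg$simulate
      src <- generate_ba(n = sim$n_nodes, m = sim$m, m0 = sim$m0, seed = seed)
      dir <- file.path(tempdir(), sprintf("spermnet-sim-%d", seed))
      frag <- fragment_network(
        src, dir, n_pathways = sim$n_pathways, overlap = sim$overlap,
        alias_fraction = sim$alias_fraction, n_enrichment = sim$n_enrichment,
        high_score_share = sim$high_score_share, seed = seed + 1L
      )
      suppressMessages(suppressWarnings(assemble(
        frag$pathway_files, frag$alias_file, frag$enrichment_file,
        min_score = cfg$min_score, quiet = TRUE
      )))
    } else if (!is.null(cfg$input$network_file)) {
      read_network(cfg$input$network_file)
    } else if (!is.null(cfg$input$pathway_files)) {
      suppressMessages(suppressWarnings(assemble(
        cfg$input$pathway_files, cfg$input$alias_file,
        cfg$input$enrichment_file, min_score = cfg$min_score, quiet = TRUE
      )))
    } else {
      rlang::abort("No input: enable the simulate block or give input files.")
    }
  })
  report$network <- list(n_nodes = n_nodes(net), n_edges = n_edges(net))

  analysed <- stage("main_component", {
    if (isTRUE(cfg$whole_network)) net else main_component(net)
  })
  report$main_component <- list(
    n_nodes = n_nodes(analysed), n_edges = n_edges(analysed),
    share_pct = if (isTRUE(cfg$whole_network)) 100 else attr(analysed, "share")
  )

  mets <- NULL
  if (isTRUE(cfg$stages$topology) || isTRUE(cfg$stages$controllers)) {
    mets <- stage("node_metrics", node_metrics(analysed))
  }

  if (isTRUE(cfg$stages$topology)) {
    rep_t <- stage("topology", topology_report(analysed))
    fits <- stage("power_law_fits", {
      # a flavor with too few occupied bins (e.g. near-constant out-degree)
      # is skipped, not fatal
      out <- lapply(c(total = "total", `in` = "in", out = "out"), function(w) {
        tryCatch(glance(fit_power_law(degree_distribution(mets, w))),
                 error = function(e) NULL)
      })
      out <- out[!vapply(out, is.null, logical(1))]
      ck <- tryCatch(glance(clustering_vs_degree(mets)),
                     error = function(e) NULL)
      if (!is.null(ck)) out$clustering_vs_degree <- ck
      out
    })
    report$topology <- c(unclass(rep_t), list(power_law = fits))
  }

  hubs_obj <- NULL
  bn <- NULL
  if (isTRUE(cfg$stages$controllers)) {
    hubs_obj <- stage("hubs", identify_hubs(mets, sigma_mult = cfg$hubs$sigma_mult))
    split <- stage("hub_subpopulations", {
      vals <- hubs_obj$hubs$clustering
      if (length(vals) >= 5) kde_split(vals, "clustering coefficient") else NULL
    })
    bn <- stage("bottlenecks", bottleneck_scores(analysed))
    k <- cfg$bottlenecks$k %||% nrow(hubs_obj$hubs)
    top_bn <- top_bottlenecks(bn, k = max(1L, k), metrics = mets)
    backbone <- stage("control_backbone", {
      if (nrow(hubs_obj$hubs) > 0 && length(top_bn) > 0) {
        suppressWarnings(control_backbone(analysed, hubs_obj$hubs$node, top_bn))
      } else NULL
    })
    report$controllers <- list(
      hub_criterion = as.list(glance(hubs_obj)),
      hub_hit_probability_pct = hub_hit_probability(
        nrow(hubs_obj$hubs), n_nodes(analysed)
      ),
      subpopulations = if (!is.null(split)) list(
        n = split$n_subpopulations,
        boundaries = split$boundaries,
        degenerate = split$degenerate
      ),
      bottleneck_k = length(top_bn),
      top_bottlenecks = utils::head(top_bn, 25),
      backbone = if (!is.null(backbone)) list(
        n_nodes = n_nodes(backbone), n_edges = n_edges(backbone)
      )
    )
  }

  if (isTRUE(cfg$stages$robustness)) {
    atk <- stage("robustness", {
      list(
        random = attack(analysed, "random", fractions = cfg$attack$fractions,
                        replicates = cfg$attack$replicates, seed = seed + 2L),
        targeted = attack(analysed, "targeted", fractions = cfg$attack$fractions)
      )
    })
    report$seeds$attack <- seed + 2L
    report$robustness <- list(
      random = as.data.frame(glance(atk$random)),
      targeted = as.data.frame(glance(atk$targeted))
    )
  } else {
    atk <- NULL
  }

  if (isTRUE(cfg$stages$phenotype)) {
    pheno <- stage("phenotype", {
      if (is.null(hubs_obj)) {
        mets_p <- mets %||% node_metrics(analysed)
        hubs_obj <- identify_hubs(mets_p, sigma_mult = cfg$hubs$sigma_mult)
      }
      hub_ids <- hubs_obj$hubs$node
      ann <- simulate_phenotypes(
        hubs = hub_ids, non_hubs = setdiff(analysed$nodes, hub_ids),
        p_hub = cfg$phenotype$p_hub, p_nonhub = cfg$phenotype$p_nonhub,
        studied_hub = cfg$phenotype$studied_hub,
        studied_nonhub = cfg$phenotype$studied_nonhub,
        seed = seed + 3L
      )
      tab <- build_phenotype_table(ann, hub_ids)
      list(table = tab, test = suppressWarnings(chi_square_test(tab)))
    })
    report$seeds$phenotype <- seed + 3L
    report$phenotype <- list(
      counts = unclass(pheno$table$counts),
      percentages = unclass(pheno$table$percentages),
      chi_square = as.list(tidy(pheno$test))
    )
  } else {
    pheno <- NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report, file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
    )
    write_tsv0 <- function(df, name) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(mets)) write_tsv0(mets, "node_metrics.tsv")
    if (!is.null(bn)) write_tsv0(bn, "bottleneck_scores.tsv")
    if (!is.null(atk)) {
      write_tsv0(dplyr::bind_rows(tidy(atk$random), tidy(atk$targeted)),
                 "attack_curves.tsv")
    }
    if (!is.null(pheno)) write_tsv0(tidy(pheno$table), "phenotype_table.tsv")
    say("Report written to %s", out_dir)
  }
  report
}
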