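test_that("hub threshold is mean plus population standard deviation", {
  metrics <- tibble::tibble(
    node = c("a", "b", "c", "d", "e"),
    degree = c(1L, 1L, 1L, 1L, 10L),
    clustering = 0, betweenness = 0
  )
  h <- identify_hubs(metrics)
  expect_equal(h$mu, 2.8)
  expect_equal(h$sigma, 3.6)
  expect_equal(h$tau, 6.4)
  expect_equal(h$hubs$node, "e")
  expect_equal(glance(h)$hub_pct, 20)

  # regular graph: sigma = 0, every node a hub, warning raised
  reg <- tibble::tibble(node = letters[1:4], degree = 3L)
  expect_warning(hr <- identify_hubs(reg), "sigma = 0")
  expect_equal(nrow(hr$hubs), 4)

  # invariant under relabeling; ordered by degree desc then name
  metrics2 <- metrics[order(metrics$node, decreasing = TRUE), ]
  expect_equal(identify_hubs(metrics2)$hubs$node, h$hubs$node)
})

test_that("hub fraction of the census reproduces the printed probability", {
  expect_equal(hub_hit_probability(196, 7758), 2.5)
})

test_that("kde_split separates planted party/date hubs and stays unimodal otherwise", {
  planted <- planted_hub_metrics(100, 30, seed = 7)
  sp <- kde_split(planted$value, "clustering coefficient")
  expect_equal(sp$n_subpopulations, 2)
  expect_gt(sp$boundaries[1], 0.2)
  expect_lt(sp$boundaries[1], 0.7)
  party <- unique(sp$assignment[planted$group == "party"])
  date <- unique(sp$assignment[planted$group == "date"])
  expect_equal(party, 1L)
  expect_equal(date, 2L)

  uni <- withr::with_seed(3, stats::rnorm(300))
  expect_equal(kde_split(uni)$n_subpopulations, 1)

  const <- kde_split(rep(0.5, 10))
  expect_equal(const$n_subpopulations, 1)
  expect_true(const$degenerate)

  expect_error(kde_split(1:3), "at least 5")
})

test_that("kde_split density integrates to one and covers every value", {
  for (s in 1:5) {
    x <- planted_hub_metrics(80, 40, seed = s)$value
    sp <- kde_split(x)
    grid <- sp$grid
    integral <- sum(diff(grid$x) * (utils::head(grid$density, -1) +
                                      utils::tail(grid$density, -1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
    expect_true(all(sp$grid$density >= 0))
    expect_equal(length(sp$assignment), length(x))
    expect_true(all(sp$assignment >= 1 & sp$assignment <= sp$n_subpopulations))
    expect_true(all(sp$boundaries > min(x) & sp$boundaries < max(x)))
  }
})

test_that("shortest-path trees are deterministic BFS trees with lexicographic parents", {
  chain <- net_from_edges("A", "B", "B", "C")
  t1 <- shortest_path_tree(chain, "A")
  expect_equal(t1$size, 3)
  expect_equal(t1$parent[["B"]], "A")
  expect_equal(t1$parent[["C"]], "B")

  expect_equal(shortest_path_tree(chain, "C")$size, 1)

  diamond <- net_from_edges("A", "B", "A", "C", "B", "D", "C", "D")
  td <- shortest_path_tree(diamond, "A")
  expect_equal(td$parent[["D"]], "B") # lexicographic tie-break

  # tree paths are shortest directed paths
  r <- random_digraph(15, p = 0.25, seed = 11)
  d <- oracle_distances(r)
  tr <- shortest_path_tree(r, r$nodes[1])
  for (v in names(tr$parent)) {
    expect_equal(unname(tr$distance[v]),
                 unname(d[r$nodes[1], v]))
    expect_equal(unname(tr$distance[v]),
                 unname(tr$distance[tr$parent[[v]]]) + 1)
  }
})

test_that("bottleneck scores match hand derivation and the path-walking oracle", {
  chain <- net_from_edges("A", "B", "B", "C")
  bn <- bottleneck_scores(chain)
  got <- stats::setNames(bn$bn, bn$node)
  expect_equal(got[c("A", "B", "C")], c(A = 0L, B = 1L, C = 2L))

  iso <- directed_network(nodes = c("X", "Y"))
  expect_equal(bottleneck_scores(iso)$bn, c(0L, 0L))

  for (s in 1:40) {
    net <- random_digraph(sample(4:8, 1), p = stats::runif(1, 0.15, 0.5),
                          seed = 100 + s)
    bn <- bottleneck_scores(net)
    oracle <- oracle_bottlenecks(net)
    expect_equal(stats::setNames(bn$bn, bn$node)[net$nodes], oracle)
  }

  # BN never exceeds the number of possible roots
  net <- random_digraph(12, p = 0.3, seed = 55)
  expect_true(all(bottleneck_scores(net)$bn <= n_nodes(net)))
})

test_that("top_bottlenecks ranks by score, degree, then name, deterministically", {
  chain <- net_from_edges("A", "B", "B", "C")
  bn <- bottleneck_scores(chain)
  expect_equal(top_bottlenecks(bn, 1), "C")
  expect_equal(length(top_bottlenecks(bn, 3)), 3)
  expect_warning(all4 <- top_bottlenecks(bn, 10), "truncated")
  expect_equal(length(all4), 3)

  net <- random_digraph(14, p = 0.25, seed = 8)
  m <- node_metrics(net)
  bn1 <- bottleneck_scores(net)
  # permuting node order in the scores table does not change the ranking
  bn2 <- bn1[sample(nrow(bn1)), ]
  expect_equal(top_bottlenecks(bn1, 5, m), top_bottlenecks(bn2, 5, m))
})

test_that("bottleneck scores correlate positively with betweenness on BA networks", {
  net <- generate_ba(n = 300, m = 2, seed = 9)
  m <- node_metrics(net)
  bn <- bottleneck_scores(net)
  j <- dplyr::inner_join(m, bn, by = "node")
  rho <- stats::cor(j$bn, j$betweenness, method = "spearman")
  expect_gt(rho, 0)
})

test_that("control backbone equals the set-algebra intersection of neighborhoods", {
  net <- generate_ba(n = 150, m = 2, seed = 12)
  m <- node_metrics(net)
  h <- identify_hubs(m)
  bn <- bottleneck_scores(net)
  tb <- top_bottlenecks(bn, k = nrow(h$hubs), metrics = m)
  bb <- control_backbone(net, h$hubs$node, tb)

  # oracle: independent set operations over the edge table
  nb_of <- function(seeds) {
    e <- net$edges
    union(seeds, union(e$target[e$source %in% seeds], e$source[e$target %in% seeds]))
  }
  keep <- intersect(nb_of(h$hubs$node), nb_of(tb))
  e <- net$edges
  ee <- e[e$source %in% keep & e$target %in% keep, ]
  expect_setequal(bb$nodes, keep)
  expect_setequal(paste(bb$edges$source, bb$edges$target),
                  paste(ee$source, ee$target))

  # hubs == bottlenecks -> backbone is their shared neighborhood network
  same <- control_backbone(net, h$hubs$node, h$hubs$node)
  expect_true(network_identical(same, neighborhood_network(net, h$hubs$node)))

  # disjoint neighborhoods -> empty, with a warning
  two <- net_from_edges("A", "B", "X", "Y")
  expect_warning(bb0 <- control_backbone(two, "A", "X"), "empty backbone")
  expect_equal(n_nodes(bb0), 0)
})
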