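test_that("clustering follows the neighbor-link formula on canonical cases", {
  # symmetric triangle: complete neighborhood, C = 1 everywhere
  tri <- net_from_edges("A", "B", "B", "A", "B", "C", "C", "B", "C", "A", "A", "C")
  m <- node_metrics(tri)
  expect_equal(m$clustering, rep(1, 3))
  expect_equal(m$neighbor_links, rep(1L, 3))

  # star: no leaf-leaf links, center C = 0; leaves have k < 2 -> 0
  star <- net_from_edges("S", "L1", "S", "L2", "S", "L3", "S", "L4")
  ms <- node_metrics(star)
  expect_equal(ms$clustering, rep(0, 5))
  expect_equal(ms$neighbors[ms$node == "S"], 4L)
})

test_that("degrees count direction and self-loops once per endpoint", {
  net <- directed_network(data.frame(source = c("A", "A"), target = c("A", "B")))
  m <- node_metrics(net)
  a <- m[m$node == "A", ]
  expect_equal(a$in_degree, 1L)   # the self-loop
  expect_equal(a$out_degree, 2L)
  expect_equal(a$degree, 3L)
  expect_equal(a$neighbors, 1L)   # self excluded from the neighborhood

  # degree conservation on random digraphs
  r <- random_digraph(25, p = 0.2, seed = 6)
  mr <- node_metrics(r)
  expect_equal(sum(mr$in_degree), n_edges(r))
  expect_equal(sum(mr$out_degree), n_edges(r))
})

test_that("betweenness, diameter, CPL and reachable pairs match brute force", {
  for (s in 1:25) {
    net <- random_digraph(sample(8:20, 1), p = stats::runif(1, 0.08, 0.3), seed = s)
    m <- node_metrics(net)
    expect_equal(m$betweenness, unname(oracle_betweenness(net)),
                 tolerance = 1e-10)
    panel <- oracle_path_panel(net)
    rep_t <- topology_report(net, chunk = 7L)
    expect_equal(rep_t$diameter, as.integer(panel$diameter))
    expect_equal(rep_t$characteristic_path_length, panel$cpl)
    expect_equal(rep_t$shortest_paths, panel$n_reachable)
  }
})

test_that("topology report reproduces hand-derived chain and clique panels", {
  chain <- net_from_edges("A", "B", "B", "C")
  r <- topology_report(chain)
  expect_equal(r$diameter, 2L)
  expect_equal(r$characteristic_path_length, 4 / 3)
  expect_equal(r$shortest_paths, 3L)
  expect_equal(r$shortest_paths_pct, 50.0)

  k4 <- expand.grid(source = LETTERS[1:4], target = LETTERS[1:4],
                    stringsAsFactors = FALSE)
  k4 <- directed_network(k4[k4$source != k4$target, ])
  rk <- topology_report(k4)
  expect_equal(rk$diameter, 1L)
  expect_equal(rk$characteristic_path_length, 1)
  expect_equal(rk$shortest_paths_pct, 100)
  # CPL <= diameter always; equality on the complete symmetric digraph
  expect_lte(r$characteristic_path_length, r$diameter)
})

test_that("CPL on a mid-size preferential-attachment network matches per-source BFS", {
  net <- generate_ba(n = 400, m = 2, seed = 1)
  g <- as_igraph(net)
  total <- 0; count <- 0
  for (v in seq_len(400)) {
    d <- igraph::bfs(g, root = v, mode = "out", unreachable = FALSE,
                     dist = TRUE)$dist
    d <- d[-v]
    total <- total + sum(d[!is.nan(d) & d > 0], na.rm = TRUE)
    count <- count + sum(!is.nan(d) & d > 0, na.rm = TRUE)
  }
  rep_t <- topology_report(net)
  expect_equal(rep_t$characteristic_path_length, total / count,
               tolerance = 1e-12)
})

test_that("degree histograms conserve node counts and report zero-degree mass", {
  iso <- directed_network(nodes = "L")
  h0 <- degree_distribution(node_metrics(iso), "total")
  expect_equal(nrow(h0), 0)
  expect_equal(attr(h0, "zero_degree"), 1L)

  chain <- net_from_edges("A", "B", "B", "C")
  hin <- degree_distribution(node_metrics(chain), "in")
  expect_equal(hin$k, 1L)
  expect_equal(hin$count, 2L)
  expect_equal(attr(hin, "zero_degree"), 1L)

  ba <- generate_ba(n = 200, m = 2, seed = 3)
  hb <- degree_distribution(node_metrics(ba), "total")
  expect_equal(sum(hb$count) + attr(hb, "zero_degree"), 200L)
})

test_that("power-law fit recovers analytic exponents and reports R^2 = r^2", {
  # closed-form OLS oracle, written from scratch (no lm)
  ols_slope <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  h <- tibble::tibble(k = 1:50, count = round(1000 * (1:50)^-2))
  f <- fit_power_law(h)
  keep <- h$count >= 1
  lx <- log10(h$k[keep]); ly <- log10(h$count[keep])
  expect_equal(f$gamma, ols_slope(lx, ly), tolerance = 1e-12)
  expect_equal(f$r_squared, f$r^2)

  # noiseless (unrounded) histograms recover the exponent within +/- 0.05
  for (g in c(-1.5, -2, -2.5, -3)) {
    hg <- tibble::tibble(k = 1:40, count = 5000 * (1:40)^g)
    fg <- fit_power_law(hg)
    expect_equal(fg$gamma, g, tolerance = 0.05)
    expect_gt(fg$r_squared, 0.99)
  }

  flat <- tibble::tibble(k = 1:10, count = 7L)
  ff <- fit_power_law(flat)
  expect_equal(ff$gamma, 0)
  expect_equal(ff$r, 0)
  expect_true(ff$degenerate)

  expect_error(fit_power_law(tibble::tibble(k = 1:2, count = c(3L, 1L))),
               "Insufficient")
})

test_that("clustering-vs-degree fit recovers the hierarchical C(k) ~ 1/k law", {
  ks <- c(2:12)
  metrics <- tibble::tibble(
    node = sprintf("h%02d", seq_along(ks)),
    degree = as.integer(ks),
    clustering = 1 / ks
  )
  f <- clustering_vs_degree(metrics)
  expect_equal(f$gamma, -1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  zero <- tibble::tibble(node = letters[1:5], degree = 1:5, clustering = 0)
  expect_error(clustering_vs_degree(zero), "positive mean clustering")
})

test_that("the MLE exponent recovers planted discrete power laws", {
  # inverse-CDF sample from an exact discrete power law, gamma = 2.5
  ks <- 1:2000
  pmf <- ks^-2.5 / sum(ks^-2.5)
  sample_k <- withr::with_seed(2, {
    sample(ks, 5000, replace = TRUE, prob = pmf)
  })
  f <- fit_power_law_mle(sample_k)
  expect_equal(f$gamma, 2.5, tolerance = 0.1)
  expect_gte(f$n_tail, 50)

  # explicit cutoff overrides the KS selection
  f2 <- fit_power_law_mle(sample_k, k_min = 2)
  expect_equal(f2$k_min, 2L)
  expect_error(fit_power_law_mle(c(1, 2, 3)), "at least 10")
})

test_that("preferential-attachment clustering is roughly degree-independent", {
  net <- generate_ba(n = 5000, m = 3, seed = 4)
  m <- node_metrics(net)
  f <- clustering_vs_degree(m)
  # flat relation: shallow slope compared to the hierarchical -1 law
  expect_lt(abs(f$gamma + 1), 1) # i.e. gamma is closer to 0 than to -2
  expect_lt(f$r_squared, 0.9)
})
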