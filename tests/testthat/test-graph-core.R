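test_that("SIF and TSV parsing transcribe rows with set semantics", {
  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B", "B pp C"), sif)
  net <- read_network(sif, "sif")
  expect_equal(n_nodes(net), 3)
  expect_equal(n_edges(net), 2)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\tB"), tsv)
  expect_equal(n_edges(read_network(tsv, "tsv")), 1)

  tsv4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tpp\tB\t950", tsv4)
  scored <- read_network(tsv4, "tsv")
  expect_equal(scored$edges$score, 950L)
})

test_that("malformed and empty files raise informative parse errors", {
  bad <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B", "A pp"), bad)
  expect_error(read_network(bad, "sif"), "line 2")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_network(empty, "tsv"), "Empty")

  badscore <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tpp\tB\t1500", badscore)
  expect_error(read_network(badscore, "tsv"), "0, 1000")
})

test_that("write/read round trip is the identity on edge sets, both dialects", {
  nets <- list(
    net_from_edges("A", "B", "B", "C", "C", "A"),
    generate_ba(n = 40, m = 2, seed = 5),
    directed_network(data.frame(
      source = c("x", "y"), target = c("y", "z"),
      interaction = c("pp", "pd"), score = c(901L, NA)
    ))
  )
  for (net in nets) {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    write_network(net, tsv, "tsv")
    expect_true(network_identical(read_network(tsv), net))

    sif <- withr::local_tempfile(fileext = ".sif")
    suppressWarnings(write_network(net, sif, "sif"))
    expect_true(network_identical(read_network(sif), net, scores = FALSE))
  }
  expect_warning(
    write_network(directed_network(), withr::local_tempfile(), "tsv"),
    "empty"
  )
})

test_that("duplicate edges collapse to the maximum score", {
  net <- directed_network(data.frame(
    source = c("A", "A", "A"), target = c("B", "B", "B"),
    score = c(300L, 950L, NA)
  ))
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$score, 950L)
})

test_that("weak components match the union-find oracle and order by size", {
  net <- net_from_edges("A", "B", "C", "D")
  comp <- connected_components(net)
  expect_equal(comp$sizes, c(2L, 2L))
  expect_equal(comp$members[[1]], c("A", "B")) # tie broken lexicographically

  chain <- net_from_edges("A", "B", "B", "C")
  expect_equal(length(connected_components(chain)$members), 1)

  # 25-component fixture by disjoint union of seeded blocks
  blocks <- lapply(1:25, function(i) {
    n <- random_digraph(4, p = 0.9, seed = i)
    directed_network(dplyr::mutate(
      n$edges,
      source = paste0("b", i, "_", source),
      target = paste0("b", i, "_", target)
    ))
  })
  big <- union_merge(blocks)
  comp <- connected_components(big)
  expect_equal(length(comp$members), 25)
  oracle <- oracle_components(big)
  expect_setequal(
    vapply(comp$members, paste, character(1), collapse = ","),
    vapply(oracle, paste, character(1), collapse = ",")
  )
  td <- tidy(comp)
  expect_equal(sum(td$component_size[!duplicated(td$component)]), n_nodes(big))
  expect_equal(nrow(td), n_nodes(big))
})

test_that("main_component extracts the largest weak component with its share", {
  net <- net_from_edges("A", "B", "C", "D", "C", "E")
  mc <- main_component(net)
  expect_setequal(mc$nodes, c("C", "D", "E"))
  expect_equal(attr(mc, "share"), 60.0)

  # idempotent on a connected network
  chain <- net_from_edges("A", "B", "B", "C")
  expect_true(network_identical(main_component(chain), chain))
  expect_equal(attr(main_component(chain), "share"), 100)
})

test_that("component share reproduces the printed rounding convention", {
  expect_equal(component_share(7758, 7892), 98.3)
})

test_that("intersection and union obey set algebra", {
  a <- random_digraph(12, p = 0.3, seed = 3)
  b <- random_digraph(12, p = 0.3, seed = 4)
  expect_true(network_identical(intersect_networks(a, a), a))

  d1 <- net_from_edges("A", "B")
  d2 <- net_from_edges("X", "Y")
  expect_equal(n_nodes(intersect_networks(d1, d2)), 0)

  # pairwise-membership oracle
  ab <- intersect_networks(a, b)
  keys <- function(n) paste(n$edges$source, n$edges$target)
  expect_setequal(keys(ab), intersect(keys(a), keys(b)))

  # union: two triangles sharing one edge -> 5 nodes, 5 edges
  t1 <- net_from_edges("A", "B", "B", "C", "C", "A")
  t2 <- net_from_edges("A", "B", "B", "D", "D", "A")
  u <- union_merge(list(t1, t2))
  expect_equal(n_nodes(u), 4)
  expect_equal(n_edges(u), 5)
  expect_true(network_identical(union_merge(list(t1)), t1))

  # associativity/commutativity on edge sets; absorb with intersect
  u1 <- union_merge(list(a, union_merge(list(b, t1))))
  u2 <- union_merge(list(t1, b, a))
  expect_true(network_identical(u1, u2, scores = FALSE))
  expect_true(network_identical(intersect_networks(a, union_merge(list(a, b))), a))
  expect_error(union_merge(list()), "at least one")
})

test_that("disjoint unions add sizes and graphml export is readable", {
  d1 <- net_from_edges("A", "B")
  d2 <- net_from_edges("X", "Y")
  u <- union_merge(list(d1, d2))
  expect_equal(n_nodes(u), 4)
  expect_equal(n_edges(u), 2)

  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(u, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 2)
})
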