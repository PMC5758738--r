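test_that("component decomposition partitions nodes and edges", {
  two_tri <- graph_from_pairs("A", "B", "B", "C", "C", "A",
                              "X", "Y", "Y", "Z", "Z", "X")
  part <- component_partition(two_tri)
  expect_length(part$components, 2)
  expect_equal(part$sizes$n_nodes, c(3, 3))
  expect_equal(part$sizes$n_edges, c(3, 3))
  # equal sizes: ordered by smallest member symbol
  expect_identical(part$components[[1]], c("A", "B", "C"))

  ei <- ppi_network(cbind("A", "B"), nodes = c("A", "B", "C"))
  part2 <- component_partition(ei)
  expect_equal(part2$sizes$n_nodes, c(2, 1))
  expect_equal(part2$sizes$n_edges, c(1, 0))

  # partition property on a random multi-component graph
  set.seed(9)
  g <- igraph::sample_gnp(60, 0.03)
  igraph::V(g)$name <- sprintf("N%02d", 1:60)
  p <- component_partition(g)
  expect_setequal(unlist(p$components), igraph::V(g)$name)
  expect_equal(sum(lengths(p$components)), 60)
  expect_equal(sum(p$sizes$n_edges), igraph::ecount(g))
  expect_true(all(diff(p$sizes$n_nodes) <= 0))
})

test_that("main component extraction matches the planted component structure", {
  spec <- synthetic_spec(rng_seed = 5L, components = c(20L, 15L, 6L),
                         graph = list(n = 120L, m = 1L, planted_hub_count = 0L,
                                      hub_degree_factor = 3))
  net <- suppressMessages(make_network(spec))
  part <- component_partition(net$network)
  expect_equal(part$sizes$n_nodes, c(120L, 20L, 15L, 6L))
  expect_identical(part$components, net$truth$components)
  main <- main_component(net$network)
  expect_setequal(igraph::V(main)$name, net$truth$components[[1]])
  # a connected graph is its own main component
  tri <- graph_from_pairs("A", "B", "B", "C", "C", "A")
  expect_equal(igraph::vcount(main_component(tri)), 3)
})

test_that("seed expansion equals the brute-force distance neighborhood", {
  star <- graph_from_pairs("HUB", "L1", "HUB", "L2", "HUB", "L3")
  expect_setequal(igraph::V(expand_network(star, "HUB", 1))$name,
                  c("HUB", "L1", "L2", "L3"))
  expect_setequal(igraph::V(expand_network(star, c("HUB", "L1"), 0))$name,
                  c("HUB", "L1"))
  expect_error(expand_network(star, "ABSENT", 1), "no seed present")
  expect_message(expand_network(star, c("HUB", "ABSENT"), 0), "absent")

  set.seed(21)
  g <- random_connected_graph(40, 0.08)
  seeds <- c("N03", "N17")
  got <- expand_network(g, seeds, 2)
  d <- igraph::distances(g, v = seeds)
  want <- colnames(d)[apply(d, 2, min) <= 2]
  expect_setequal(igraph::V(got)$name, want)
  # expanding a connected graph beyond its diameter returns the whole graph
  whole <- expand_network(g, "N01", igraph::vcount(g))
  expect_equal(igraph::vcount(whole), igraph::vcount(g))
})

test_that("degree distributions obey the handshake lemma", {
  tri <- graph_from_pairs("A", "B", "B", "C", "C", "A")
  expect_equal(as.data.frame(degree_distribution(tri)),
               data.frame(k = 2L, count = 3L), ignore_attr = TRUE)
  star <- graph_from_pairs("S", "A", "S", "B", "S", "C", "S", "D")
  dd <- degree_distribution(star)
  expect_equal(as.data.frame(dd), data.frame(k = c(1L, 4L), count = c(4L, 1L)),
               ignore_attr = TRUE)

  set.seed(1)
  ba <- igraph::sample_pa(500, m = 2, directed = FALSE)
  igraph::V(ba)$name <- sprintf("V%03d", 1:500)
  dd2 <- degree_distribution(ba)
  # independent recount straight from the adjacency matrix
  deg <- rowSums(as.matrix(igraph::as_adjacency_matrix(ba)))
  recount <- table(deg[deg > 0])
  expect_equal(dd2$count, as.integer(recount))
  expect_equal(dd2$k, as.integer(names(recount)))
  expect_equal(sum(dd2$k * dd2$count), 2 * igraph::ecount(ba))
})

test_that("power-law fitting recovers exact laws and flags thin input", {
  exact <- data.frame(k = c(1, 2, 4, 8), count = 100 * c(1, 2, 4, 8)^(-2))
  fit <- fit_power_law(exact)
  expect_equal(fit$a, 100, tolerance = 1e-9)
  expect_equal(fit$b, -2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$correlation, 1, tolerance = 1e-12)

  flat <- data.frame(k = c(1, 2, 4), count = c(5, 5, 5))
  expect_equal(fit_power_law(flat)$b, 0, tolerance = 1e-12)

  expect_error(fit_power_law(data.frame(k = c(1, 2), count = c(3, 1))),
               "insufficient support")

  set.seed(7)
  ba <- igraph::sample_pa(2000, m = 3, directed = FALSE)
  igraph::V(ba)$name <- paste0("V", 1:2000)
  b <- fit_power_law(degree_distribution(ba))$b
  expect_gt(b, -3.5)
  expect_lt(b, -1.5)
})
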