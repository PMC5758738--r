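test_that("degree cutoff is mean plus multiples of the population SD", {
  expect_equal(degree_cutoff(c(1, 1, 1, 1)), 1)
  expect_equal(degree_cutoff(c(2, 4)), 5)                      # mean 3, pop sd 1
  expect_equal(degree_cutoff(c(2, 4), sd_type = "sample"),
               3 + 2 * sd(c(2, 4)))
  expect_equal(degree_cutoff(c(2, 4), sd_multiplier = 1), 4)
  expect_error(degree_cutoff(5), ">= 2 nodes")

  set.seed(11)
  g <- igraph::sample_pa(1000, m = 2, directed = FALSE)
  igraph::V(g)$name <- paste0("V", 1:1000)
  deg <- degree_centrality(g)
  # independent one-pass mean/variance accumulation
  s1 <- 0; s2 <- 0
  for (d in deg) { s1 <- s1 + d; s2 <- s2 + d * d }
  m <- s1 / length(deg)
  expect_equal(degree_cutoff(deg), m + 2 * sqrt(s2 / length(deg) - m^2),
               tolerance = 1e-9)
})

test_that("hub selection respects the cutoff boundary convention", {
  tab <- data.frame(node = c("A", "B", "C"), degree = c(10, 2, 1))
  expect_identical(as.character(select_hubs(tab, 9)), "A")
  expect_setequal(as.character(select_hubs(tab, 0)), c("A", "B", "C"))
  expect_identical(as.character(select_hubs(tab, 2)), c("A", "B"))
  expect_identical(as.character(select_hubs(tab, 2, inclusive = FALSE)), "A")
  expect_warning(select_hubs(tab, 99), "no hubs")
})

test_that("top-fraction selection handles boundary ties by inclusion", {
  tab20 <- data.frame(node = sprintf("N%02d", 1:20),
                      betweenness = 20:1, closeness = runif(20),
                      stress = 1:20, degree = 1:20)
  expect_identical(as.character(top_fraction(tab20, "betweenness", 0.05)), "N01")
  expect_length(top_fraction(tab20, "betweenness", 1), 20L)

  # 3-way tie spanning the rank-5 boundary in a 100-node table
  vals <- c(100:97, rep(96, 3), 93:1)
  tab100 <- data.frame(node = sprintf("M%03d", 1:100), betweenness = vals,
                       closeness = 0, stress = 0, degree = 0)
  sel <- suppressMessages(top_fraction(tab100, "betweenness", 0.05))
  expect_length(sel, 7L)
  # brute-force rank check: everything at or above the rank-5 value
  expect_setequal(as.character(sel),
                  tab100$node[vals >= sort(vals, decreasing = TRUE)[5]])
})

test_that("hub-bottlenecks are the hub/top-betweenness intersection", {
  expect_identical(as.character(hub_bottlenecks(gene_set(c("A", "B")),
                                                gene_set(c("B", "C")))), "B")
  expect_length(hub_bottlenecks(gene_set("A"), gene_set("B")), 0L)
})

test_that("selection is monotone in cutoff and fraction on tie-free tables", {
  set.seed(41)
  tab <- data.frame(node = sprintf("N%02d", 1:30),
                    degree = sample(100, 30), betweenness = sample(1000, 30),
                    closeness = runif(30), stress = sample(5000, 30))
  for (f in c(0.05, 0.1, 0.5)) {
    expect_length(top_fraction(tab, "stress", f), ceiling(f * 30))
  }
  sizes <- vapply(c(0.1, 0.3, 0.6), function(f) {
    length(top_fraction(tab, "betweenness", f))
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
  h1 <- select_hubs(tab, 50)
  h2 <- select_hubs(tab, 25)
  expect_true(all(h1 %in% h2))
})

test_that("the membership matrix records selection and cluster membership", {
  sel <- structure(list(
    degree_cutoff = 5,
    hubs = gene_set(c("H1", "H2", "H3")),
    top_bc = gene_set(c("H1", "H2", "X")),
    top_cc = gene_set(c("H1", "Y")),
    top_stress = gene_set(c("H1", "H2")),
    hub_bottlenecks = gene_set(c("H1", "H2"))), class = "selection_result")
  cx <- list(list(seed = "H1", members = c("H1", "A", "B")),
             list(seed = "Z", members = c("Z", "Q")))
  m <- membership_report(sel, cx)
  expect_identical(m$gene, c("H1", "H2"))
  expect_true(all(m$hub))
  expect_identical(m$top_cc, c(TRUE, FALSE))
  expect_identical(m$cluster1, c(TRUE, FALSE))
  expect_identical(m$cluster2, c(FALSE, FALSE))
  expect_equal(unname(attr(m, "summary")[["top_stress"]]), 2)

  sel$hub_bottlenecks <- gene_set(character(0))
  empty <- membership_report(sel, cx)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("gene", "hub", "hub_bottleneck") %in% names(empty)))
})

test_that("planted hubs are recovered exactly as hub-bottlenecks", {
  spec <- synthetic_spec(rng_seed = 42L)
  net <- suppressMessages(make_network(spec))
  tab <- centrality_table(main_component(net$network))
  sel <- suppressMessages(select_crucial(tab))
  expect_setequal(as.character(sel$hubs), net$truth$hubs)
  expect_setequal(as.character(sel$hub_bottlenecks), net$truth$hubs)
})
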