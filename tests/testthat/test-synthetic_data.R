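test_that("the generator settings validate their structural constraints", {
  expect_error(synthetic_spec(core_size = 200L,
                              list_sizes = c(50L, 40L, 30L)))
  expect_error(synthetic_spec(components = c(500L)),
               "smaller than the main component")
  spec <- synthetic_spec()
  expect_identical(spec$list_sizes, c(232L, 143L, 132L))
  expect_identical(spec$core_size, 17L)
  expect_length(spec$components, 3L)   # plus the main component: 4 total
  expect_length(spec$complexes, 3L)
})

test_that("generated networks carry verifiable planted structure", {
  spec <- synthetic_spec(rng_seed = 42L)
  net <- suppressMessages(make_network(spec))
  g <- net$network
  # four components of the planted sizes
  part <- component_partition(g)
  expect_equal(part$sizes$n_nodes, c(300L, 40L, 30L, 12L))
  expect_identical(part$components, net$truth$components)
  # simple graph invariants
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  # select_hubs on the output recovers exactly the planted hubs
  main <- main_component(g)
  deg <- degree_centrality(main)
  tab <- data.frame(node = names(deg), degree = unname(deg))
  hubs <- select_hubs(tab, degree_cutoff(deg))
  expect_setequal(as.character(hubs), net$truth$hubs)
  expect_length(hubs, 8L)
  # planted complexes have the recorded density and live in the main component
  for (i in seq_along(net$truth$complexes)) {
    members <- net$truth$complexes[[i]]
    sub <- igraph::induced_subgraph(g, members)
    n_c <- length(members)
    expect_equal(2 * igraph::ecount(sub) / (n_c * (n_c - 1)),
                 net$truth$complex_density[i], tolerance = 1e-12)
    expect_true(all(members %in% igraph::V(main)$name))
  }
})

test_that("generation is deterministic and seed-sensitive", {
  spec <- synthetic_spec(rng_seed = 9L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  suppressMessages(write_synthetic_bundle(spec, d1))
  suppressMessages(write_synthetic_bundle(spec, d2))
  suppressMessages(write_synthetic_bundle(synthetic_spec(rng_seed = 10L), d3))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_false(identical(readLines(file.path(d1, "network.tsv")),
                         readLines(file.path(d3, "network.tsv"))))
})

test_that("the bundle's files feed every parser in the package", {
  spec <- synthetic_spec(rng_seed = 4L)
  dir <- withr::local_tempdir()
  truth <- suppressMessages(write_synthetic_bundle(spec, dir))
  lists <- lapply(c("colon", "gastric", "esophageal"), function(nm) {
    suppressMessages(read_gene_list(file.path(dir, paste0(nm, ".txt")), nm))
  })
  expect_identical(as.character(intersect_gene_sets(lists)), truth$core)
  net <- suppressMessages(read_edge_list(file.path(dir, "network.tsv")))
  expect_equal(igraph::vcount(net), 382)
  ann <- read_gmt(file.path(dir, "annotations.gmt"),
                  universe = readLines(file.path(dir, "universe.txt")))
  expect_length(ann$terms, 73L)
  expect_length(ann$universe, 382L)
  # the planted core genes are network nodes (in the main component)
  expect_true(all(truth$core %in% igraph::V(net)$name))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_identical(sort(tj$hubs), sort(truth$hubs))
})

test_that("a null annotation spec rarely produces significant calls", {
  spec <- synthetic_spec(rng_seed = 1L,
                         annotation = list(n_terms = 73L, planted_enriched = 0L,
                                           n_blocks = 0L, term_size = 6L,
                                           block_core = 4L))
  universe <- sprintf("U%03d", 1:382)
  query <- sprintf("U%03d", 1:45)
  hits <- 0L
  for (s in 1:25) {
    spec$rng_seed <- s
    ann <- make_annotations(spec, query = query, universe = universe)
    expect_length(ann$truth$enriched_terms, 0L)
    res <- ora(query, ann$annotation)
    if (any(res$significant)) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})
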