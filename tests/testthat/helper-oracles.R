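# Independent brute-force oracles. These deliberately share no code with the
# package: shortest paths are enumerated by depth-first search over an edge
# list, the hypergeometric tail is summed from binomial coefficients, and
# k-cores are found by naive peeling.

# adjacency list (integer indices) from an igraph object, via the edge list
oracle_adj <- function(net) {
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1L]; b <- el[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# every simple path from s to t, as a list of integer vectors
oracle_all_paths <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
  }
  walk(s)
  out
}

# unnormalized betweenness and stress by exhaustive shortest-path listing
oracle_betweenness_stress <- function(net) {
  adj <- oracle_adj(net)
  n <- length(adj)
  bc <- numeric(n)
  stress <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      paths <- oracle_all_paths(adj, s, t)
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(shortest)
        stress[inner] <- stress[inner] + 1
      }
    }
  }
  list(betweenness = stats::setNames(bc, igraph::V(net)$name),
       stress = stats::setNames(stress, igraph::V(net)$name))
}

# closed-form tree betweenness: pairs separated by v, from component sizes
# of the tree with v removed
oracle_tree_betweenness <- function(tree) {
  n <- igraph::vcount(tree)
  vapply(igraph::V(tree)$name, function(v) {
    rest <- igraph::delete_vertices(tree, v)
    cs <- igraph::components(rest)$csize
    ((n - 1)^2 - sum(cs^2)) / 2
  }, numeric(1))
}

# exact upper-tail hypergeometric probability from binomial coefficients
oracle_hyper_tail <- function(k, K, n, N) {
  i <- seq.int(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# highest k-core of a small graph by naive peeling, k stepped upwards
oracle_highest_core <- function(net) {
  best_k <- 0L
  best_members <- character(0)
  for (k in 0:igraph::vcount(net)) {
    g <- net
    repeat {
      low <- igraph::V(g)$name[igraph::degree(g) < k]
      if (length(low) == 0L) break
      g <- igraph::delete_vertices(g, low)
    }
    if (igraph::vcount(g) == 0L) break
    best_k <- k
    best_members <- sort(igraph::V(g)$name)
  }
  list(k = best_k, members = best_members)
}

# MCODE vertex weight of every node by peeling its closed neighborhood
oracle_mcode_weights <- function(net, degree_cutoff = 2L) {
  vapply(igraph::V(net)$name, function(v) {
    if (igraph::degree(net, v) < degree_cutoff) return(0)
    nb <- c(v, igraph::V(net)$name[as.integer(igraph::neighbors(net, v))])
    sub <- igraph::induced_subgraph(net, nb)
    core <- oracle_highest_core(sub)
    cg <- igraph::induced_subgraph(sub, core$members)
    nn <- igraph::vcount(cg)
    if (nn < 2L) return(0)
    core$k * 2 * igraph::ecount(cg) / (nn * (nn - 1L))
  }, numeric(1))
}

# a random connected graph with named vertices
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small literal networks used across tests
graph_from_pairs <- function(...) {
  ppi_network(matrix(c(...), ncol = 2L, byrow = TRUE))
}

path3 <- function() graph_from_pairs("A", "B", "B", "C")
cycle4 <- function() graph_from_pairs("A", "B", "B", "C", "C", "D", "D", "A")
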