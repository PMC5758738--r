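#' Specification for the synthetic study replica
#'
#' The generator produces every input the pipeline consumes, with planted
#' ground truth recorded alongside. The defaults are a scaled structural
#' replica of a three-cancer hub-gene study design: three disease gene
#' lists of 232/143/132 symbols sharing exactly a 17-gene core, an
#' interaction network of four connected components whose scale-free main
#' component carries 8 planted hub genes and three planted dense complexes
#' (sizes 12/9/7 at density 0.8), and a GMT annotation of 73 terms of
#' which 43 are enriched for the crucial genes, arranged in 9 kappa-blocks.
#'
#' @param rng_seed integer seed; the whole bundle is a deterministic
#'   function of these generator settings including this seed.
#' @param list_sizes sizes of the three disease gene lists.
#' @param core_size size of the planted common core (in every list and
#'   placed on main-component network nodes).
#' @param graph list: `n` main-component size, `m` preferential-attachment
#'   edges per new node, `planted_hub_count`, `hub_degree_factor` (planted
#'   hub degrees are pushed to this multiple of the highest non-hub
#'   degree, guaranteeing they exceed the mean + 2 SD cutoff).
#' @param components sizes of the extra (non-main) components.
#' @param complexes list of `c(size, density)` pairs for planted dense
#'   modules inside the main component.
#' @param annotation list: `n_terms` total, `planted_enriched`, `n_blocks`
#'   kappa-blocks, `term_size` genes per term, `block_core` query genes
#'   shared by all terms of a block.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(rng_seed = 42L,
                           list_sizes = c(232L, 143L, 132L),
                           core_size = 17L,
                           graph = list(n = 300L, m = 1L,
                                        planted_hub_count = 8L,
                                        hub_degree_factor = 3),
                           components = c(40L, 30L, 12L),
                           complexes = list(c(14L, 0.8), c(12L, 0.8), c(11L, 0.8)),
                           annotation = list(n_terms = 73L,
                                             planted_enriched = 43L,
                                             n_blocks = 9L,
                                             term_size = 6L,
                                             block_core = 4L)) {
  stopifnot(core_size >= 0L, core_size <= min(list_sizes),
            length(list_sizes) >= 2L, graph$n > 0L)
  if (length(components) && any(components >= graph$n)) {
    stop("extra components must be smaller than the main component", call. = FALSE)
  }
  structure(list(rng_seed = as.integer(rng_seed),
                 list_sizes = as.integer(list_sizes),
                 core_size = as.integer(core_size),
                 graph = graph, components = as.integer(components),
                 complexes = complexes, annotation = annotation),
            class = "synthetic_spec")
}

symbol_pool <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Generate overlapping disease gene lists with a planted core
#'
#' Three (or more) lists that share exactly the planted core: list-specific
#' symbols are drawn from disjoint pools, so pairwise extra overlap is
#' zero and the multi-way intersection is the core by construction.
#'
#' @param spec a [synthetic_spec()].
#' @param core_symbols optional character vector to use as the core
#'   (e.g. network node symbols); defaults to fresh symbols.
#' @return List with `lists` (list of [gene_set()]) and `truth`
#'   (list with `core`).
#' @export
make_gene_lists <- function(spec, core_symbols = NULL) {
  with_seed(spec$rng_seed + 1L, {
    core <- core_symbols %||% symbol_pool("CORE", spec$core_size)
    if (length(core) != spec$core_size) {
      stop("core_symbols length must equal core_size", call. = FALSE)
    }
    labels <- c("colon", "gastric", "esophageal")
    if (length(spec$list_sizes) > 3L) {
      labels <- c(labels, sprintf("disease%d", 4:length(spec$list_sizes)))
    }
    lists <- vector("list", length(spec$list_sizes))
    offset <- 0L
    for (i in seq_along(spec$list_sizes)) {
      extra_n <- spec$list_sizes[i] - spec$core_size
      extra <- sprintf("D%d_%04d", i, seq_len(extra_n))
      lists[[i]] <- gene_set(c(core, extra), name = labels[i])
      offset <- offset + extra_n
    }
    list(lists = lists, truth = list(core = sort(toupper(core))))
  })
}

# Wire `members` as the nearest regular graph to the requested density:
# circulant rings plus an optional perfect matching (vertex-transitive, so
# every member has an identical closed neighborhood up to background edges).
# Regularity is what makes the planted complex recoverable as a unit: MCODE
# admits neighbors within a fixed fraction of the seed weight, so member
# weights must be homogeneous. Returns the graph and the realized density.
wire_regular_module <- function(g, members, density) {
  s <- length(members)
  stopifnot(s >= 3L)
  idx <- match(members, igraph::V(g)$name)
  deg <- round(density * (s - 1L))
  if (deg %% 2L == 1L && s %% 2L == 1L) {
    # odd-degree regular graph needs even order; fall to the nearer even degree
    deg <- if (abs(deg - 1L - density * (s - 1L)) <=
               abs(deg + 1L - density * (s - 1L))) deg - 1L else deg + 1L
  }
  deg <- max(2L, min(deg, s - 1L))
  r <- deg %/% 2L
  pairs <- NULL
  for (j in seq_len(r)) {
    for (i in seq_len(s)) {
      pairs <- rbind(pairs, sort(c(idx[i], idx[(i - 1L + j) %% s + 1L])))
    }
  }
  if (deg %% 2L == 1L) {    # s even: add the antipodal perfect matching
    half <- s %/% 2L
    for (i in seq_len(half)) {
      pairs <- rbind(pairs, sort(c(idx[i], idx[i + half])))
    }
  }
  pairs <- unique(pairs)
  # the module's induced subgraph must be exactly the designed regular
  # graph: stray background edges between members would break the weight
  # homogeneity the construction relies on
  members <- igraph::V(g)$name[idx]
  sub_el <- igraph::as_edgelist(igraph::induced_subgraph(g, members))
  if (nrow(sub_el)) {
    g <- igraph::delete_edges(g, igraph::get_edge_ids(g, as.vector(t(sub_el))))
  }
  g <- igraph::add_edges(g, as.vector(t(pairs)))
  list(g = g, density = nrow(pairs) / (s * (s - 1L) / 2))
}

#' Generate the synthetic interaction network with planted structure
#'
#' The main component starts as a preferential-attachment (scale-free)
#' background — sparse by default (`m = 1`), so the background contributes
#' no dense subgraphs of its own. Into it the generator plants, in order:
#' dense complexes (disjoint member sets wired as the nearest regular
#' graph to the requested density; regular wiring makes member weights
#' homogeneous, so each complex is recoverable as a unit and its
#' lexicographically smallest member is the deterministic seed; background
#' edges running between two different complexes are removed so complexes
#' cannot merge), then hub genes (edges added from each planted hub to
#' low-degree non-module nodes until every planted hub exceeds the
#' mean + 2 SD degree cutoff and no other node reaches it). Extra
#' components are small preferential-attachment trees. Edge confidence
#' scores are drawn uniformly from 150-999 so the STRING dialect can be
#' exercised.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `network` (igraph) and `truth`: `hubs`,
#'   `component_sizes`, `components` (member lists), `complexes` (member
#'   lists), `complex_seeds`, `high_confidence_edges` (score >= 700 pairs).
#' @export
make_network <- function(spec) {
  with_seed(spec$rng_seed + 2L, {
    gconf <- spec$graph
    n_main <- gconf$n
    g <- igraph::sample_pa(n_main, m = gconf$m, directed = FALSE)
    igraph::V(g)$name <- symbol_pool("G", n_main)

    # --- plant dense complexes on disjoint node sets
    sizes <- vapply(spec$complexes, `[`, numeric(1), 1L)
    if (sum(sizes) > n_main / 2L) stop("complexes too large for the graph", call. = FALSE)
    avail <- sample(igraph::V(g)$name, sum(sizes))
    module_members <- split(avail, rep(seq_along(sizes), sizes))
    module_seeds <- character(length(sizes))
    module_density <- numeric(length(sizes))
    for (i in seq_along(spec$complexes)) {
      members <- sort(module_members[[i]])
      wired <- wire_regular_module(g, members, spec$complexes[[i]][2L])
      g <- wired$g
      module_members[[i]] <- members
      module_density[i] <- wired$density
      # regular wiring gives every member the same vertex weight, so the
      # lexicographically smallest member wins the seed tie-break
      module_seeds[i] <- members[1L]
    }
    all_module <- unlist(module_members)
    # background edges must not link two complexes (they would merge under
    # expansion) and an outside node may keep at most one edge into any one
    # complex (a second edge would let it enter the complex's k-core and
    # perturb the homogeneous member weights)
    el <- igraph::as_edgelist(g, names = TRUE)
    mod_of <- function(x) {
      out <- integer(length(x))
      for (i in seq_along(module_members)) out[x %in% module_members[[i]]] <- i
      out
    }
    m1 <- mod_of(el[, 1L]); m2 <- mod_of(el[, 2L])
    drop <- m1 > 0L & m2 > 0L & m1 != m2
    bg_end <- ifelse(m1 == 0L & m2 > 0L, el[, 1L],
                     ifelse(m2 == 0L & m1 > 0L, el[, 2L], NA))
    touched <- !is.na(bg_end)
    key <- paste(bg_end[touched], pmax(m1, m2)[touched])
    drop[touched][duplicated(key)] <- TRUE
    if (any(drop)) g <- igraph::delete_edges(g, which(drop))
    if (!igraph::is_connected(g)) {
      # reattach anything the edge cleanup disconnected
      comp <- igraph::components(g)
      main_id <- which.max(comp$csize)
      for (cid in setdiff(seq_along(comp$csize), main_id)) {
        v <- names(comp$membership)[comp$membership == cid][1L]
        anchor <- sample(setdiff(names(comp$membership)[comp$membership == main_id],
                                 all_module), 1L)
        g <- igraph::add_edges(g, match(c(v, anchor), igraph::V(g)$name))
      }
    }

    # --- plant hubs: boost degrees until they, and only they, pass the
    # cutoff. Boost edges are wired triangle-free (no two targets of one hub
    # adjacent, no target shared between adjacent hubs, no target already a
    # hub neighbor) so hub neighborhoods stay star-like: hubs earn top
    # degree and betweenness without forming dense MCODE cores.
    n_hubs <- gconf$planted_hub_count
    hubs <- character(0)
    if (n_hubs > 0L) {
      deg <- igraph::degree(g)
      cand <- setdiff(igraph::V(g)$name, all_module)
      hubs <- sort(cand[order(-deg[cand])][seq_len(n_hubs)])
      hub_nb <- igraph::V(g)$name[as.integer(unlist(igraph::ego(g, 1, hubs)))]
      eligible <- setdiff(cand, c(hubs, hub_nb))
      used_by <- stats::setNames(vector("list", n_hubs), hubs)
      hub_adj <- outer(hubs, hubs, Vectorize(function(a, b) {
        igraph::are_adjacent(g, a, b)
      }))
      dimnames(hub_adj) <- list(hubs, hubs)
      for (iter in 1:60) {
        deg <- igraph::degree(g)
        cutoff <- mean(deg) + 2 * pop_sd(deg)
        non_hub_max <- max(deg[setdiff(igraph::V(g)$name, hubs)])
        target <- max(ceiling(cutoff) + 1, ceiling(gconf$hub_degree_factor *
                                                     non_hub_max))
        if (min(deg[hubs]) > cutoff && non_hub_max < cutoff) break
        for (h in hubs) {
          lack <- target - deg[[h]]
          if (lack <= 0L) next
          taken_nearby <- unlist(used_by[hubs[hub_adj[h, ]]])
          # exclude the hub's whole 2-neighborhood: an edge to a node
          # adjacent to an existing neighbor would close a triangle
          near2 <- igraph::V(g)$name[as.integer(unlist(igraph::ego(g, 2, h)))]
          pool <- setdiff(eligible, c(near2, taken_nearby))
          pool <- pool[order(igraph::degree(g)[pool], pool)]
          chosen <- character(0)
          blocked <- if (length(used_by[[h]])) {
            igraph::V(g)$name[as.integer(unlist(igraph::ego(
              g, 1, used_by[[h]])))]
          } else character(0)
          for (t in pool) {
            if (length(chosen) >= lack) break
            if (t %in% blocked) next
            chosen <- c(chosen, t)
            blocked <- c(blocked, igraph::V(g)$name[
              as.integer(igraph::neighbors(g, t))])
          }
          if (length(chosen) == 0L) next
          hi <- match(h, igraph::V(g)$name)
          g <- igraph::add_edges(g, as.vector(rbind(hi, match(chosen,
                                                              igraph::V(g)$name))))
          used_by[[h]] <- c(used_by[[h]], chosen)
        }
      }
      deg <- igraph::degree(g)
      cutoff <- mean(deg) + 2 * pop_sd(deg)
      if (!(min(deg[hubs]) > cutoff &&
            max(deg[setdiff(igraph::V(g)$name, hubs)]) < cutoff)) {
        stop("hub planting failed to separate hubs from the cutoff", call. = FALSE)
      }
    }

    # --- extra components: small preferential-attachment trees
    comp_truth <- list(sort(igraph::V(g)$name))
    offset <- n_main
    for (s in spec$components) {
      extra <- igraph::sample_pa(s, m = 1L, directed = FALSE)
      igraph::V(extra)$name <- sprintf("G%04d", offset + seq_len(s))
      offset <- offset + s
      g <- igraph::disjoint_union(g, extra)
      comp_truth[[length(comp_truth) + 1L]] <- sort(igraph::V(extra)$name)
    }

    igraph::E(g)$score <- sample(150:999, igraph::ecount(g), replace = TRUE)
    el <- igraph::as_edgelist(g, names = TRUE)
    flip <- el[, 1L] > el[, 2L]
    el[flip, ] <- el[flip, c(2L, 1L), drop = FALSE]
    high_conf <- el[igraph::E(g)$score >= 700, , drop = FALSE]

    list(network = g,
         truth = list(
           hubs = hubs,
           components = comp_truth,
           component_sizes = lengths(comp_truth),
           complexes = module_members,
           complex_seeds = module_seeds,
           complex_density = module_density,
           high_confidence_edges = paste(high_conf[, 1L], high_conf[, 2L])))
  })
}

#' Generate a GMT annotation with planted enriched term blocks
#'
#' The planted enriched terms are organized into `n_blocks` kappa-blocks:
#' all terms of a block share the same `block_core` query genes (so their
#' membership vectors over the query agree exactly, kappa = 1) and blocks
#' use disjoint query genes (between-block kappa <= 0). Each planted term
#' is padded to `term_size` with genes outside the query, so its overlap
#' with the query is exactly `block_core` — an effect size chosen so the
#' planted terms are significant after Benjamini-Hochberg correction with
#' power 1 at the default design, even if one core gene goes missing from
#' the query. Filler (null) terms draw only non-query genes when enriched
#' terms are planted; with `planted_enriched = 0` every term is drawn
#' uniformly from the universe (the null configuration for type-I checks).
#'
#' @param spec a [synthetic_spec()].
#' @param query character vector of query genes (the crucial genes the
#'   annotation is enriched for). Needs at least
#'   `n_blocks * block_core` genes when terms are planted.
#' @param universe background gene vector; must contain the query.
#' @return List with `annotation` (an [annotation_set()]) and `truth`
#'   (`enriched_terms`, `blocks` named list, `n_blocks`).
#' @export
make_annotations <- function(spec, query, universe) {
  aconf <- spec$annotation
  query <- sort(unique(toupper(query)))
  universe <- sort(unique(toupper(universe)))
  stopifnot(all(query %in% universe))
  with_seed(spec$rng_seed + 3L, {
    n_planted <- aconf$planted_enriched
    n_null <- aconf$n_terms - n_planted
    terms <- list()
    term_names <- character(0)
    truth_blocks <- list()
    nonquery <- setdiff(universe, query)
    if (n_planted > 0L) {
      need <- aconf$n_blocks * aconf$block_core
      if (length(query) < need) {
        stop(sprintf("query too small: need %d genes for %d blocks", need,
                     aconf$n_blocks), call. = FALSE)
      }
      core_genes <- sample(query, need)
      block_cores <- split(core_genes, rep(seq_len(aconf$n_blocks),
                                           each = aconf$block_core))
      block_of_term <- sort(rep_len(seq_len(aconf$n_blocks), n_planted))
      for (i in seq_len(n_planted)) {
        b <- block_of_term[i]
        pad <- sample(nonquery, aconf$term_size - aconf$block_core)
        id <- sprintf("T%03d", i)
        terms[[id]] <- c(block_cores[[b]], pad)
        term_names[id] <- sprintf("synthetic process %03d (block %d)", i, b)
      }
      truth_blocks <- lapply(split(sprintf("T%03d", seq_len(n_planted)),
                                   block_of_term), sort)
    }
    null_pool <- if (n_planted > 0L) nonquery else universe
    for (j in seq_len(n_null)) {
      id <- sprintf("N%03d", j)
      terms[[id]] <- sample(null_pool, aconf$term_size)
      term_names[id] <- sprintf("synthetic background %03d", j)
    }
    ann <- annotation_set(terms, term_names, universe = universe)
    list(annotation = ann,
         truth = list(enriched_terms = sort(names(terms)[startsWith(names(terms), "T")]),
                      blocks = truth_blocks,
                      n_blocks = if (n_planted > 0L) aconf$n_blocks else 0L))
  })
}

#' Write the full synthetic input bundle to a directory
#'
#' Emits the files a real analysis would start from — `colon.txt`,
#' `gastric.txt`, `esophageal.txt` (plus `disease<i>.txt` beyond three),
#' `network.tsv` (scored edge list), `network_string.txt` (STRING
#' dialect), `annotations.gmt`, `universe.txt` — together with
#' `truth.json` recording every planted structure. The planted gene-list
#' core is placed on main-component network nodes (outside the planted
#' hubs and complexes), and the annotation query is the planted crucial
#' set: hubs plus complex members.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the truth list (also serialized to `truth.json`).
#' @export
write_synthetic_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_network(spec)
  truth <- net$truth
  reserved <- c(truth$hubs, unlist(truth$complexes))
  pool <- setdiff(truth$components[[1L]], reserved)
  core_symbols <- with_seed(spec$rng_seed + 4L, sample(pool, spec$core_size))
  gl <- make_gene_lists(spec, core_symbols = core_symbols)
  query <- sort(unique(c(truth$hubs, unlist(truth$complexes))))
  ann <- make_annotations(spec, query = query,
                          universe = igraph::V(net$network)$name)
  for (gs in gl$lists) {
    write_gene_list(gs, file.path(dir, paste0(attr(gs, "name"), ".txt")))
  }
  write_network(net$network, file.path(dir, "network.tsv"), format = "edge_list")
  write_network(net$network, file.path(dir, "network_string.txt"), format = "string")
  write_gmt(ann$annotation, file.path(dir, "annotations.gmt"))
  write_lines_lf(igraph::V(net$network)$name, file.path(dir, "universe.txt"))
  truth_all <- list(
    core = gl$truth$core,
    hubs = truth$hubs,
    component_sizes = truth$component_sizes,
    complexes = truth$complexes,
    complex_seeds = truth$complex_seeds,
    query = query,
    enriched_terms = ann$truth$enriched_terms,
    n_blocks = ann$truth$n_blocks
  )
  jsonlite::write_json(truth_all, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(truth_all)
}
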