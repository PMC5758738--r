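#' Interaction networks
#'
#' Networks are undirected simple [igraph][igraph::igraph-package] graphs
#' whose vertices are gene symbols (the `name` vertex attribute). Edge
#' confidence scores, when present, live in the `score` edge attribute —
#' integers in \[0, 1000\] for STRING-style tables, reals in \[0, 1\] for
#' generic edge lists. All constructors normalize to a simple graph:
#' self-loops are dropped, duplicate edges collapsed keeping the maximum
#' score, and edges stored under the canonical (lexicographically sorted)
#' endpoint order so serialization is deterministic.
#'
#' @param edges two-column character matrix or data.frame of endpoints.
#' @param score optional numeric vector of per-edge scores.
#' @param nodes optional character vector of node names (to keep isolated
#'   nodes); defaults to the union of edge endpoints.
#' @return An undirected simple igraph object.
#' @export
ppi_network <- function(edges, score = NULL, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
  mode(edges) <- "character"
  n_in <- nrow(edges)
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
    score <- score[!loops]
  }
  # canonical order inside each pair, then collapse duplicates keeping max score
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L), drop = FALSE]
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    message(sprintf("collapsed %d duplicate edge(s)", sum(duplicated(key))))
    if (!is.null(score)) {
      score <- vapply(split(score, key), max, numeric(1))[unique(key)]
    }
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  if (length(nodes) == 0L) stop("empty network", call. = FALSE)
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  if (!is.null(score)) igraph::E(g)$score <- score[ord]
  attr(g, "n_input_edges") <- n_in
  g
}

#' Read a generic 2/3-column edge list
#'
#' Lines hold `nodeA nodeB [score]` separated by `delimiter` (any run of
#' whitespace by default). A header line is auto-detected when the score
#' cell of the first line is non-numeric. Self-loops are dropped and
#' duplicate edges collapsed (maximum score kept), with counts reported.
#'
#' @param path input file.
#' @param delimiter field separator; `""` (default) splits on whitespace.
#' @param score_column optional 1-based index of the score column; by
#'   default column 3 is used as score when present.
#' @return A [ppi_network()] igraph object.
#' @export
read_edge_list <- function(path, delimiter = "", score_column = NULL) {
  if (!file.exists(path)) stop("cannot read edge list: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty network", call. = FALSE)
  split_fun <- if (nzchar(delimiter)) {
    function(x) strsplit(x, delimiter, fixed = TRUE)[[1]]
  } else {
    function(x) strsplit(trimws(x), "[[:space:]]+")[[1]]
  }
  fields <- lapply(lines, split_fun)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("line %d has fewer than 2 columns", which(nf < 2L)[1L]),
         call. = FALSE)
  }
  sc <- score_column %||% 3L
  has_score <- all(nf >= sc)
  # header auto-detection: first line whose score cell is not numeric
  start <- 1L
  if (has_score && is.na(suppressWarnings(as.numeric(fields[[1L]][sc])))) {
    start <- 2L
    if (length(fields) < 2L) stop("empty network", call. = FALSE)
  }
  fields <- fields[start:length(fields)]
  edges <- t(vapply(fields, function(f) f[1:2], character(2)))
  score <- NULL
  if (has_score) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), sc)))
    if (anyNA(score)) {
      stop(sprintf("non-numeric score on data line %d", which(is.na(score))[1L]),
           call. = FALSE)
    }
  }
  ppi_network(edges, score = score)
}

#' Read a STRING protein.links-style table
#'
#' Expects a whitespace-delimited file whose header names at least
#' `protein1`, `protein2` and `combined_score` (the STRING `protein.links`
#' dialect). Edges with `combined_score < score_threshold` are excluded.
#' Identifiers of the form `taxid.ENSPxxxx` are shortened to the part after
#' the first dot unless `keep_prefix = TRUE`.
#'
#' The default threshold 400 is STRING's "medium confidence" level. It is
#' deliberately prominent in the run log: every downstream count depends
#' on it.
#'
#' @param path input file.
#' @param score_threshold minimum combined score in \[0, 1000\] to keep an
#'   edge (default 400).
#' @param keep_prefix keep the taxon prefix on identifiers?
#' @return A [ppi_network()] igraph object with a `score` edge attribute.
#' @export
read_string_links <- function(path, score_threshold = 400, keep_prefix = FALSE) {
  if (!file.exists(path)) stop("cannot read links file: ", path, call. = FALSE)
  header <- strsplit(trimws(readLines(path, n = 1L, warn = FALSE)),
                     "[[:space:]]+")[[1]]
  required <- c("protein1", "protein2", "combined_score")
  if (!all(required %in% header)) {
    stop("missing protein.links header (protein1 protein2 combined_score)",
         call. = FALSE)
  }
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  a <- as.character(tab$protein1)
  b <- as.character(tab$protein2)
  if (!keep_prefix) {
    a <- sub("^[^.]+\\.", "", a)
    b <- sub("^[^.]+\\.", "", b)
  }
  keep <- tab$combined_score >= score_threshold
  if (!any(keep)) stop("threshold removed all edges", call. = FALSE)
  message(sprintf("STRING links: kept %d / %d edges at combined_score >= %d",
                  sum(keep), length(keep), score_threshold))
  ppi_network(cbind(a[keep], b[keep]), score = tab$combined_score[keep])
}

#' Write a network as an edge list, SIF, or STRING-style links table
#'
#' `edge_list` writes `nodeA <tab> nodeB [<tab> score]`; `sif` writes
#' `nodeA <tab> pp <tab> nodeB` with isolated nodes as single-column lines;
#' `string` writes a `protein1 protein2 combined_score` table (score 999
#' where the network carries none). Output is UTF-8, LF-terminated, sorted,
#' so files are diffable and re-reading yields an identical network.
#'
#' @param net a [ppi_network()] igraph object.
#' @param path output file.
#' @param format one of `"edge_list"`, `"sif"`, `"string"`.
#' @export
write_network <- function(net, path, format = c("edge_list", "sif", "string")) {
  format <- match.arg(format)
  if (igraph::vcount(net) == 0L) stop("refusing to write empty network", call. = FALSE)
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el)) {
    flip <- el[, 1L] > el[, 2L]
    el[flip, ] <- el[flip, c(2L, 1L), drop = FALSE]
  }
  score <- igraph::edge_attr(net, "score")
  ord <- order(el[, 1L], el[, 2L])
  el <- el[ord, , drop = FALSE]
  score <- score[ord]
  isolated <- setdiff(igraph::V(net)$name, as.vector(el))
  lines <- switch(format,
    edge_list = {
      # a bare edge list cannot carry isolated nodes; use SIF for those
      if (length(isolated)) {
        message(sprintf("edge_list format omits %d isolated node(s)",
                        length(isolated)))
      }
      if (is.null(score)) paste(el[, 1L], el[, 2L], sep = "\t") else
        paste(el[, 1L], el[, 2L], format(score, trim = TRUE, scientific = FALSE),
              sep = "\t")
    },
    sif = c(paste(el[, 1L], "pp", el[, 2L], sep = "\t"), sort(isolated)),
    string = {
      sc <- if (is.null(score)) rep(999L, nrow(el)) else round(score)
      c("protein1 protein2 combined_score",
        paste(el[, 1L], el[, 2L], sc))
    }
  )
  write_lines_lf(lines, path)
}

#' Read a SIF (simple interaction format) file
#'
#' Accepts the `nodeA <tab> type <tab> nodeB` dialect written by
#' [write_network()]; single-column lines are isolated nodes.
#'
#' @param path input file.
#' @return A [ppi_network()] igraph object.
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf == 2L)) stop("malformed SIF line (2 fields)", call. = FALSE)
  singles <- unlist(lapply(fields[nf == 1L], `[`, 1L))
  triples <- fields[nf >= 3L]
  edges <- if (length(triples)) {
    t(vapply(triples, function(f) f[c(1L, 3L)], character(2)))
  } else {
    matrix(character(0), ncol = 2L)
  }
  ppi_network(edges, nodes = unique(c(singles, as.vector(edges))))
}
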