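#' Gene sets
#'
#' A gene set is a named, duplicate-free collection of gene symbols. Symbols
#' are compared case-insensitively: they are trimmed and uppercased on
#' construction, matching the uppercase convention of published gene tables.
#' No alias or HGNC resolution is attempted; symbols are opaque strings.
#'
#' @param members character vector of gene symbols.
#' @param name short label for the set (e.g. the disease the list belongs to).
#' @return An object of class `gene_set`: a character vector of unique,
#'   uppercase symbols (sorted), with a `name` attribute.
#' @examples
#' gene_set(c("tp53", "TP53", "egfr"), name = "demo")
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- toupper(trimws(as.character(members)))
  members <- members[nzchar(members)]
  if (any(grepl("[[:space:]]", members))) {
    stop("gene symbols must not contain internal whitespace", call. = FALSE)
  }
  structure(sort(unique(members)), name = name, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d symbols\n", attr(x, "name"), length(x)))
  if (length(x)) cat(" ", paste(head(x, 10L), collapse = " "),
                     if (length(x) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Read a disease gene list from a plain-text file
#'
#' One symbol per line; blank lines and lines starting with `#` are skipped;
#' surrounding whitespace is trimmed. Symbols are uppercased and
#' deduplicated, and the counts read versus kept are reported as a message.
#'
#' @param path path to the gene list file.
#' @param name label for the resulting set; defaults to the file name.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("cannot read gene list: ", path, call. = FALSE)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n_read <- length(lines)
  gs <- gene_set(lines, name = name)
  if (length(gs) == 0L) stop("empty gene list: ", path, call. = FALSE)
  message(sprintf("gene list '%s': %d read / %d kept", name, n_read, length(gs)))
  gs
}

#' Write a gene set in the plain-text one-symbol-per-line format
#'
#' @param gs a [gene_set()] (or character vector of symbols).
#' @param path output file.
#' @export
write_gene_list <- function(gs, path) {
  write_lines_lf(sort(unique(toupper(as.character(gs)))), path)
}

#' Multi-way intersection of gene sets
#'
#' Returns the symbols present in at least `min_sets` of the input sets. The
#' default requires presence in every set — the strict common core across
#' all diseases. `min_sets` generalizes this to "present in at least k
#' lists" for more permissive panels.
#'
#' @param sets a list of at least two [gene_set()]s (or character vectors).
#' @param min_sets minimum number of sets a symbol must appear in
#'   (between 2 and `length(sets)`); defaults to all sets.
#' @param name label for the result.
#' @return A [gene_set()] of the common symbols.
#' @export
intersect_gene_sets <- function(sets, min_sets = length(sets),
                                name = "intersection") {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("need at least 2 gene sets to intersect", call. = FALSE)
  }
  if (min_sets < 2L || min_sets > length(sets)) {
    stop("min_sets must be between 2 and the number of sets", call. = FALSE)
  }
  tallies <- membership_tally(sets)
  gene_set(tallies$symbol[tallies$n_lists >= min_sets], name = name)
}

membership_tally <- function(sets) {
  sets <- lapply(seq_along(sets), function(i) {
    gene_set(sets[[i]], name = attr(sets[[i]], "name") %||% paste0("set", i))
  })
  labels <- vapply(sets, attr, character(1), "name")
  symbol <- sort(unique(unlist(sets)))
  inset <- vapply(sets, function(s) symbol %in% s, logical(length(symbol)))
  inset <- matrix(inset, nrow = length(symbol))
  data.frame(
    symbol = symbol,
    n_lists = rowSums(inset),
    list_names = apply(inset, 1L, function(r) paste(labels[r], collapse = ",")),
    stringsAsFactors = FALSE
  )
}

#' Per-symbol membership report across gene lists
#'
#' One row per symbol in the union of the inputs, with the number of lists
#' it occurs in and their labels — the long-form record behind
#' [intersect_gene_sets()]. Counts of symbols before and after
#' deduplication across lists are attached as attributes (`n_total_entries`,
#' `n_distinct`), since totals quoted for pooled disease lists may refer to
#' either.
#'
#' @param sets a list of [gene_set()]s.
#' @return A data.frame with columns `symbol`, `n_lists`, `list_names`.
#' @export
intersection_report <- function(sets) {
  tallies <- membership_tally(sets)
  tallies <- tallies[order(-tallies$n_lists, tallies$symbol), , drop = FALSE]
  rownames(tallies) <- NULL
  attr(tallies, "n_total_entries") <- sum(vapply(sets, function(s) {
    length(gene_set(s))
  }, integer(1)))
  attr(tallies, "n_distinct") <- nrow(tallies)
  tallies
}
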