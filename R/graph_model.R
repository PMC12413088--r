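#' Mixed physical/regulatory interaction graph
#'
#' Holds a protein node set, undirected physical (PPI) edges and directed
#' regulatory (TF to target) edges. A protein pair may carry both a physical
#' edge and regulatory edge(s); these are distinct parallel edges and are
#' never merged. Physical self-loops are disallowed; regulatory self-loops
#' (autoregulation) are retained but ignored by path queries and the motif
#' census.
#'
#' @param nodes character vector of protein ids (endpoints are added
#'   automatically).
#' @param ppi data.frame with columns `source`, `target` and optionally
#'   `evidence`; order of endpoints is irrelevant, duplicates merge evidence.
#' @param reg data.frame with the same columns; direction is meaningful and
#'   both (a,b) and (b,a) may be present.
#' @param species free-text species label.
#' @return An object of class `mixed_graph`.
#' @export
mixed_graph <- function(nodes = character(), ppi = NULL, reg = NULL,
                        species = "") {
  empty <- data.frame(source = character(), target = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  ppi <- normalize_edge_df(ppi %||% empty)
  reg <- normalize_edge_df(reg %||% empty)
  # canonical undirected storage: endpoint pair sorted bytewise
  self <- ppi$source == ppi$target
  n_self_ppi <- sum(self)
  ppi <- ppi[!self, , drop = FALSE]
  a <- pmin(ppi$source, ppi$target)
  b <- pmax(ppi$source, ppi$target)
  ppi <- data.frame(a = a, b = b, evidence = ppi$evidence,
                    stringsAsFactors = FALSE)
  ppi <- merge_dup_edges(ppi, c("a", "b"))
  reg <- merge_dup_edges(reg, c("source", "target"))
  nodes <- radix_sort(unique(c(nodes, ppi$a, ppi$b, reg$source, reg$target)))
  structure(list(nodes = nodes, ppi = ppi, reg = reg, species = species,
                 n_dropped_ppi_self_loops = n_self_ppi),
            class = "mixed_graph")
}

normalize_edge_df <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"evidence" %in% names(df)) df$evidence <- ""
  miss <- setdiff(c("source", "target"), names(df))
  if (length(miss) > 0) stop("edge table missing column(s): ",
                             paste(miss, collapse = ", "))
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  df$evidence <- as.character(df$evidence)
  df[, c("source", "target", "evidence")]
}

merge_dup_edges <- function(df, keycols) {
  if (nrow(df) == 0) return(df)
  key <- do.call(paste, c(df[keycols], sep = "\t"))
  ev <- vapply(split(df$evidence, key), function(e) {
    e <- unique(e[nzchar(e)])
    paste(radix_sort(e), collapse = ";")
  }, character(1))
  df <- df[!duplicated(key), , drop = FALSE]
  df$evidence <- unname(ev[key[!duplicated(key)]])
  df <- df[radix_order(df[[keycols[1]]], df[[keycols[2]]]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.mixed_graph <- function(x, ...) {
  cat("mixed_graph:", length(x$nodes), "proteins,", nrow(x$ppi),
      "physical edges,", nrow(x$reg), "regulatory edges",
      if (nzchar(x$species)) paste0("(", x$species, ")") else "", "\n")
  invisible(x)
}

#' Load a mixed graph from TSV edge lists
#'
#' Both files are tab-separated with a header naming at least `source` and
#' `target` (optional `evidence`). Reversed physical duplicates collapse;
#' regulatory direction is preserved.
#'
#' @param ppi_path path to the physical edge list (or `NULL` for none).
#' @param reg_path path to the regulatory edge list (or `NULL` for none).
#' @param species free-text species label.
#' @return A [mixed_graph()].
#' @export
load_edges <- function(ppi_path = NULL, reg_path = NULL, species = "") {
  read_one <- function(path) {
    if (is.null(path)) return(NULL)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    miss <- setdiff(c("source", "target"), names(df))
    if (length(miss) > 0) stop("edge TSV ", path, " missing column(s): ",
                               paste(miss, collapse = ", "))
    df
  }
  g <- mixed_graph(ppi = read_one(ppi_path), reg = read_one(reg_path),
                   species = species)
  message("loaded mixed graph: ", length(g$nodes), " nodes, ", nrow(g$ppi),
          " PPI edges, ", nrow(g$reg), " regulatory edges")
  g
}

#' Write a mixed graph to TSV edge lists
#'
#' @param graph a [mixed_graph()].
#' @param ppi_path,reg_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_edges <- function(graph, ppi_path, reg_path) {
  ppi <- data.frame(source = graph$ppi$a, target = graph$ppi$b,
                    evidence = graph$ppi$evidence)
  utils::write.table(ppi, ppi_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$reg, reg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ppi_path, reg_path))
}

check_filter <- function(filter) {
  if (!filter %in% c("physical", "regulatory", "mixed")) {
    stop("edge-type filter must be one of physical, regulatory, mixed")
  }
  filter
}

#' Degree of a protein under an edge-type filter
#'
#' Physical: number of incident PPI edges. Regulatory: in-degree plus
#' out-degree (a reciprocal pair a->b, b->a contributes 2; a self-loop
#' contributes 2). Mixed: their sum.
#'
#' @param graph a [mixed_graph()].
#' @param protein a protein id in the graph.
#' @param filter one of `"physical"`, `"regulatory"`, `"mixed"`.
#' @return Nonnegative integer.
#' @export
protein_degree <- function(graph, protein, filter = "mixed") {
  check_filter(filter)
  if (!protein %in% graph$nodes) stop("unknown protein: ", protein)
  d <- 0L
  if (filter %in% c("physical", "mixed")) {
    d <- d + sum(graph$ppi$a == protein) + sum(graph$ppi$b == protein)
  }
  if (filter %in% c("regulatory", "mixed")) {
    d <- d + sum(graph$reg$source == protein) +
      sum(graph$reg$target == protein)
  }
  as.integer(d)
}

#' Neighbors of a protein under an edge-type filter
#'
#' Union of PPI partners and/or regulatory partners (both directions),
#' excluding the protein itself.
#'
#' @inheritParams protein_degree
#' @return Sorted character vector of protein ids.
#' @export
protein_neighbors <- function(graph, protein, filter = "mixed") {
  check_filter(filter)
  if (!protein %in% graph$nodes) stop("unknown protein: ", protein)
  nb <- character()
  if (filter %in% c("physical", "mixed")) {
    nb <- c(nb, graph$ppi$b[graph$ppi$a == protein],
            graph$ppi$a[graph$ppi$b == protein])
  }
  if (filter %in% c("regulatory", "mixed")) {
    nb <- c(nb, graph$reg$target[graph$reg$source == protein],
            graph$reg$source[graph$reg$target == protein])
  }
  radix_sort(setdiff(unique(nb), protein))
}

# Undirected typed edge table for a filter: columns source, target, type,
# directed. Regulatory self-loops are excluded (path queries and motifs
# require distinct endpoints).
filtered_edges <- function(graph, filter = "mixed") {
  check_filter(filter)
  out <- list()
  if (filter %in% c("physical", "mixed") && nrow(graph$ppi) > 0) {
    out$ppi <- data.frame(source = graph$ppi$a, target = graph$ppi$b,
                          type = "physical", directed = FALSE,
                          stringsAsFactors = FALSE)
  }
  if (filter %in% c("regulatory", "mixed") && nrow(graph$reg) > 0) {
    reg <- graph$reg[graph$reg$source != graph$reg$target, , drop = FALSE]
    if (nrow(reg) > 0) {
      out$reg <- data.frame(source = reg$source, target = reg$target,
                            type = "regulatory", directed = TRUE,
                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(source = character(), target = character(),
                      type = character(), directed = logical(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Traversal view of a mixed graph
#'
#' Adjacency under an edge-type filter as used by the path queries.
#' Regulatory edges are traversable in both directions (their true direction
#' is preserved for display and motif counting); regulatory self-loops are
#' not traversed.
#'
#' @inheritParams protein_degree
#' @param filter one of `"physical"`, `"regulatory"`, `"mixed"`.
#' @return A named list mapping every node id to its sorted traversable
#'   neighbor ids.
#' @export
traversal_view <- function(graph, filter = "mixed") {
  edges <- filtered_edges(graph, filter)
  adj <- stats::setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (i in seq_along(adj)) adj[[i]] <- character()
  if (nrow(edges) > 0) {
    ends <- c(edges$source, edges$target)
    other <- c(edges$target, edges$source)
    sp <- split(other, ends)
    for (v in names(sp)) adj[[v]] <- radix_sort(setdiff(unique(sp[[v]]), v))
  }
  adj
}

# igraph (undirected, simple) over the traversal view; used for BFS
# distances and connectivity.
view_igraph <- function(graph, filter = "mixed") {
  edges <- filtered_edges(graph, filter)
  el <- unique(data.frame(a = pmin(edges$source, edges$target),
                          b = pmax(edges$source, edges$target)))
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}
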