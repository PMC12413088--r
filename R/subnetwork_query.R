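#' Query specification for subnetwork extraction
#'
#' Connects a query protein `s` to proteins annotated to GO term `t` over a
#' chosen edge-type filter, in one of two modes: `k_unique_paths` (the k
#' globally shortest simple paths from `s` to any annotated protein) or
#' `k_unique_nodes` (the k annotated proteins nearest to `s`, each with one
#' witness shortest path).
#'
#' @param protein query protein id `s`.
#' @param term GO term id `t`.
#' @param k positive integer; typical interactive range is 5 to 25.
#' @param mode `"k_unique_paths"` or `"k_unique_nodes"`.
#' @param filter edge-type filter: `"physical"`, `"regulatory"`, `"mixed"`.
#' @param include_inferred whether inferred annotations define the target
#'   set.
#' @return An object of class `query_spec`.
#' @export
query_spec <- function(protein, term, k = 10,
                       mode = c("k_unique_paths", "k_unique_nodes"),
                       filter = "mixed", include_inferred = TRUE) {
  mode <- match.arg(mode)
  check_filter(filter)
  k <- as.integer(k)
  stopifnot(length(k) == 1, k >= 1)
  structure(list(protein = protein, term = term, k = k, mode = mode,
                 filter = filter, include_inferred = include_inferred),
            class = "query_spec")
}

# Assemble the result container from a list of paths (character vectors).
# Node roles: the source is "source"; any other node annotated to the term
# is "annotated" (even if it only appears as an intermediate); the rest are
# "intermediate". Edges are all graph edges of permitted types between
# consecutive path nodes (parallel physical + regulatory edges both shown).
build_subnetwork <- function(graph, paths, spec, annotated) {
  nodes <- unique(unlist(paths, use.names = FALSE))
  if (is.null(nodes)) nodes <- character()
  role <- ifelse(nodes == spec$protein, "source",
                 ifelse(nodes %in% annotated, "annotated", "intermediate"))
  steps <- unique(do.call(rbind, lapply(paths, function(p) {
    if (length(p) < 2) return(NULL)
    data.frame(u = p[-length(p)], v = p[-1], stringsAsFactors = FALSE)
  })))
  all_edges <- filtered_edges(graph, spec$filter)
  if (!is.null(steps) && nrow(steps) > 0) {
    ku <- paste(pmin(steps$u, steps$v), pmax(steps$u, steps$v), sep = "\t")
    ke <- paste(pmin(all_edges$source, all_edges$target),
                pmax(all_edges$source, all_edges$target), sep = "\t")
    edges <- all_edges[ke %in% ku, , drop = FALSE]
  } else {
    edges <- all_edges[0, , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(
    paths = paths,
    nodes = data.frame(id = nodes, role = role, stringsAsFactors = FALSE),
    edges = edges,
    spec = spec), class = "query_subnetwork")
}

#' @export
print.query_subnetwork <- function(x, ...) {
  cat("query_subnetwork:", length(x$paths), "paths,", nrow(x$nodes),
      "nodes,", nrow(x$edges), "typed edges (", x$spec$mode, ",",
      x$spec$filter, ")\n")
  invisible(x)
}

# Multi-source BFS distance (in edges) from a set of seeds over an
# adjacency list. Returns a named numeric vector (Inf = unreachable).
adj_bfs_distances <- function(adj, seeds) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  seeds <- intersect(seeds, names(adj))
  dist[seeds] <- 0
  frontier <- seeds
  d <- 0
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(dist)[dist <= d])
    nxt <- nxt[is.infinite(dist[nxt])]
    d <- d + 1
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

target_set <- function(graph, annots, spec) {
  ann <- annotated_proteins(annots, spec$term, spec$include_inferred)
  # the query protein never belongs to its own target set
  intersect(setdiff(ann, spec$protein), graph$nodes)
}

check_query_pre <- function(graph, annots, spec) {
  if (!spec$protein %in% graph$nodes) {
    stop("query protein not in graph: ", spec$protein)
  }
  if (!spec$term %in% annots$term) stop("unknown GO term: ", spec$term)
}

#' K unique paths: the k shortest simple paths to a GO term
#'
#' Returns the k globally shortest loopless paths (by edge count) from the
#' query protein to *any* protein annotated to the term, over the filtered
#' traversal view. Several paths may share a terminal node, and paths may
#' pass through annotated proteins as intermediates. Ties are broken
#' lexicographically on the node-id sequence, which makes results
#' deterministic and prefix-stable in k. If fewer than k simple paths exist,
#' all of them are returned.
#'
#' The search is a best-first expansion of partial simple paths ordered by
#' (path length + shortest remaining distance to the target set,
#' node-sequence); the distance lower bound is an exact multi-source BFS on
#' the filtered view, so paths are emitted in (length, lexicographic) order
#' like Yen's algorithm with a deterministic tie-break.
#'
#' @param graph a [mixed_graph()].
#' @param annots an [annotation_set()] (propagated if inferred annotations
#'   should count).
#' @param spec a [query_spec()].
#' @return A `query_subnetwork` with paths sorted by nondecreasing length.
#' @export
k_unique_paths <- function(graph, annots, spec) {
  check_query_pre(graph, annots, spec)
  adj <- traversal_view(graph, spec$filter)
  targets <- target_set(graph, annots, spec)
  if (length(targets) == 0) {
    return(build_subnetwork(graph, list(), spec, character()))
  }
  h <- adj_bfs_distances(adj, targets)
  if (is.infinite(h[[spec$protein]])) {
    message("no annotated protein reachable from ", spec$protein,
            " under filter ", spec$filter)
    return(build_subnetwork(graph, list(), spec, targets))
  }
  is_target <- stats::setNames(names(adj) %in% targets, names(adj))

  paths_found <- vector("list", spec$k)
  n_found <- 0L
  # queue columns kept as parallel vectors; paths as a growing list
  q_path <- list(spec$protein)
  q_f <- h[[spec$protein]]
  q_key <- spec$protein
  while (length(q_path) > 0 && n_found < spec$k) {
    i <- radix_order(q_f, q_key)[1]
    path <- q_path[[i]]
    q_path[[i]] <- NULL
    q_f <- q_f[-i]
    q_key <- q_key[-i]
    last <- path[length(path)]
    if (is_target[[last]]) {
      n_found <- n_found + 1L
      paths_found[[n_found]] <- path
    }
    for (nb in adj[[last]]) {
      if (nb %in% path) next
      hn <- h[[nb]]
      if (is.infinite(hn)) next
      child <- c(path, nb)
      q_path[[length(q_path) + 1L]] <- child
      q_f <- c(q_f, length(child) - 1 + hn)
      q_key <- c(q_key, path_key(child))
    }
  }
  build_subnetwork(graph, paths_found[seq_len(n_found)], spec, targets)
}

# Lexicographically smallest shortest path from s to v given BFS distances
# from s; walks forward always choosing the smallest-id neighbor that stays
# on a shortest path (checked against BFS distances from v).
lex_smallest_shortest_path <- function(adj, s, v, dist_s) {
  dist_v <- adj_bfs_distances(adj, v)
  D <- dist_s[[v]]
  path <- s
  cur <- s
  for (step in seq_len(D)) {
    cand <- adj[[cur]]
    ok <- cand[dist_s[cand] == step & dist_v[cand] == D - step]
    cur <- ok[1]  # adjacency lists are sorted, so ok[1] is lex-smallest
    path <- c(path, cur)
  }
  path
}

#' K unique nodes: the k nearest proteins annotated to a GO term
#'
#' Selects up to k distinct annotated proteins with the smallest
#' breadth-first-search distance from the query protein (ties broken by
#' protein id), and connects each through one witness shortest path (the
#' lexicographically smallest). Result paths are sorted by length.
#'
#' @inheritParams k_unique_paths
#' @return A `query_subnetwork`.
#' @export
k_unique_nodes <- function(graph, annots, spec) {
  check_query_pre(graph, annots, spec)
  adj <- traversal_view(graph, spec$filter)
  targets <- target_set(graph, annots, spec)
  if (length(targets) == 0) {
    return(build_subnetwork(graph, list(), spec, character()))
  }
  dist_s <- adj_bfs_distances(adj, spec$protein)
  reach <- targets[is.finite(dist_s[targets])]
  if (length(reach) == 0) {
    message("no annotated protein reachable from ", spec$protein,
            " under filter ", spec$filter)
    return(build_subnetwork(graph, list(), spec, targets))
  }
  sel <- reach[radix_order(dist_s[reach], reach)]
  sel <- sel[seq_len(min(spec$k, length(sel)))]
  paths <- lapply(sel, function(v) {
    lex_smallest_shortest_path(adj, spec$protein, v, dist_s)
  })
  ord <- radix_order(lengths(paths), vapply(paths, path_key, character(1)))
  build_subnetwork(graph, paths[ord], spec, targets)
}

#' Run a query
#'
#' Dispatches on the mode in the [query_spec()].
#'
#' @inheritParams k_unique_paths
#' @return A `query_subnetwork`.
#' @export
run_query <- function(graph, annots, spec) {
  switch(spec$mode,
         k_unique_paths = k_unique_paths(graph, annots, spec),
         k_unique_nodes = k_unique_nodes(graph, annots, spec))
}

#' Re-query from a node inside an existing result
#'
#' Equivalent to a fresh query with the source replaced by `new_source`,
#' which must belong to the previous result's node set. If the new source is
#' itself annotated to the term, it is excluded from its own target set.
#'
#' @param result a `query_subnetwork`.
#' @param new_source a protein id occurring in `result`.
#' @inheritParams k_unique_paths
#' @return A `query_subnetwork`.
#' @export
requery <- function(result, new_source, graph, annots) {
  if (!new_source %in% result$nodes$id) {
    stop("new source not in the current subnetwork: ", new_source)
  }
  spec <- result$spec
  spec$protein <- new_source
  run_query(graph, annots, spec)
}
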