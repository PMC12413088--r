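# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force or through a different
# library (igraph, pROC) than the implementation path they check.

# -- random small mixed graphs ----------------------------------------------

random_mixed_graph <- function(n, p_ppi = 0.25, p_reg = 0.15, seed = 1) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  ppi_keep <- stats::runif(nrow(pairs)) < p_ppi
  ppi <- data.frame(source = pairs[ppi_keep, 1], target = pairs[ppi_keep, 2],
                    stringsAsFactors = FALSE)
  ordered <- expand.grid(source = ids, target = ids,
                         stringsAsFactors = FALSE)
  ordered <- ordered[ordered$source != ordered$target, ]
  reg_keep <- stats::runif(nrow(ordered)) < p_reg
  reg <- ordered[reg_keep, ]
  mixed_graph(nodes = ids, ppi = ppi, reg = reg)
}

# Chain ontology A -> B -> ... (child first), plus annotation helpers.
chain_dag <- function(ids) {
  terms <- data.frame(id = ids, name = ids, namespace = "bp",
                      obsolete = FALSE, stringsAsFactors = FALSE)
  parents <- if (length(ids) > 1) {
    data.frame(child = ids[-length(ids)], parent = ids[-1],
               relation = "is_a", stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  }
  ontology_dag(terms, parents)
}

direct_annots <- function(proteins, terms) {
  annotation_set(data.frame(protein = proteins, term = terms,
                            provenance = "direct", stringsAsFactors = FALSE))
}

# -- ontology oracle ---------------------------------------------------------

# ancestor closure by igraph reachability, independent of the package's
# frontier/topological implementations
oracle_ancestors <- function(dag, term, relations = c("is_a", "part_of")) {
  pe <- dag$parents[dag$parents$relation %in% relations, , drop = FALSE]
  if (nrow(pe) == 0) return(character())
  g <- igraph::graph_from_data_frame(
    pe[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = dag$terms$id))
  out <- names(igraph::subcomponent(g, term, mode = "out"))
  sort(setdiff(out, term), method = "radix")
}

# -- path oracles ------------------------------------------------------------

# exhaustive DFS enumeration of every simple path from s to any target,
# sorted by (length, lexicographic node sequence)
oracle_simple_paths <- function(adj, s, targets, max_len = Inf) {
  paths <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    if (last %in% targets && length(path) > 1) {
      paths[[length(paths) + 1L]] <<- path
    }
    if (length(path) - 1 >= max_len) return()
    for (nb in adj[[last]]) {
      if (!nb %in% path) recurse(c(path, nb))
    }
  }
  recurse(s)
  keys <- vapply(paths, function(p) paste(p, collapse = "\x01"),
                 character(1))
  paths[order(lengths(paths), keys, method = "radix")]
}

oracle_distances <- function(graph, filter, from) {
  edges <- weavenet:::filtered_edges(graph, filter)
  g <- igraph::graph_from_data_frame(
    unique(data.frame(a = edges$source, b = edges$target)),
    directed = FALSE, vertices = data.frame(name = graph$nodes))
  d <- igraph::distances(g, v = from, mode = "all")
  stats::setNames(as.numeric(d[1, ]), colnames(d))
}

# -- motif rule-table oracle -------------------------------------------------

# Classification written independently as explicit per-permutation scans of
# the raw edge configuration bits: ppi is a length-3 logical for the pairs
# (1,2), (1,3), (2,3); reg a length-6 logical for the ordered pairs
# (1,2),(2,1),(1,3),(3,1),(2,3),(3,2).
oracle_classify_bits <- function(ppi_bits, reg_bits) {
  P <- matrix(FALSE, 3, 3)
  P[1, 2] <- P[2, 1] <- ppi_bits[1]
  P[1, 3] <- P[3, 1] <- ppi_bits[2]
  P[2, 3] <- P[3, 2] <- ppi_bits[3]
  R <- matrix(FALSE, 3, 3)
  R[1, 2] <- reg_bits[1]; R[2, 1] <- reg_bits[2]
  R[1, 3] <- reg_bits[3]; R[3, 1] <- reg_bits[4]
  R[2, 3] <- reg_bits[5]; R[3, 2] <- reg_bits[6]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  has <- function(f) any(vapply(perms, f, logical(1)))
  ffl_at <- function(p) R[p[1], p[2]] && R[p[1], p[3]] && R[p[2], p[3]]
  mfl <- has(function(p) ffl_at(p) && P[p[1], p[2]])
  ffl <- has(function(p) ffl_at(p) && !P[p[1], p[2]])
  ic <- has(function(p) P[p[1], p[2]] && R[p[1], p[3]] && R[p[2], p[3]])
  ci <- has(function(p) R[p[1], p[2]] && R[p[1], p[3]] && P[p[2], p[3]])
  out <- character()
  if (all(ppi_bits)) out <- c(out, "protein_clique")
  reg_cls <- if (mfl) "mixed_feedback_loop"
  else if (ffl) "feed_forward_loop"
  else if (ic) "interacting_coregulators"
  else if (ci) "coregulated_interactors"
  else NULL
  c(out, reg_cls)
}

# graph on nodes T1,T2,T3 realizing a configuration bit vector
graph_from_bits <- function(ppi_bits, reg_bits) {
  nodes <- c("T1", "T2", "T3")
  pp <- rbind(c(1, 2), c(1, 3), c(2, 3))[ppi_bits, , drop = FALSE]
  rr <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1),
              c(2, 3), c(3, 2))[reg_bits, , drop = FALSE]
  mixed_graph(
    nodes = nodes,
    ppi = if (nrow(pp) > 0) data.frame(source = nodes[pp[, 1]],
                                       target = nodes[pp[, 2]]) else NULL,
    reg = if (nrow(rr) > 0) data.frame(source = nodes[rr[, 1]],
                                       target = nodes[rr[, 2]]) else NULL)
}

# O(n^3) census: classify every unordered triple
oracle_census <- function(graph, nodes = NULL) {
  nodes <- sort(if (is.null(nodes)) graph$nodes else nodes,
                method = "radix")
  counts <- stats::setNames(integer(5),
    c("protein_clique", "feed_forward_loop", "interacting_coregulators",
      "coregulated_interactors", "mixed_feedback_loop"))
  if (length(nodes) < 3) return(counts)
  sub <- graph
  sub$ppi <- graph$ppi[graph$ppi$a %in% nodes & graph$ppi$b %in% nodes, ]
  sub$reg <- graph$reg[graph$reg$source %in% nodes &
                       graph$reg$target %in% nodes, ]
  tri <- utils::combn(nodes, 3)
  for (i in seq_len(ncol(tri))) {
    cls <- classify_triple(sub, tri[1, i], tri[2, i], tri[3, i])
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

# -- pagerank oracle ---------------------------------------------------------

# dense linear solve of p = (1-a) r + a (W p) with dangling columns equal
# to r; independent of the power iteration
oracle_pagerank <- function(graph, annots, term, cfg) {
  uni <- weavenet:::walk_universe_edges(graph, annots, cfg$universe)
  n <- length(uni$nodes)
  idx <- stats::setNames(seq_len(n), uni$nodes)
  restart <- intersect(annotated_proteins(annots, term), uni$nodes)
  r <- numeric(n); r[idx[restart]] <- 1 / length(restart)
  A <- matrix(0, n, n)
  if (nrow(uni$edges) > 0) {
    for (k in seq_len(nrow(uni$edges))) {
      i <- idx[[uni$edges[k, 1]]]; j <- idx[[uni$edges[k, 2]]]
      A[i, j] <- 1; A[j, i] <- 1
    }
  }
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dj <- sum(A[, j])
    W[, j] <- if (dj > 0) A[, j] / dj else r
  }
  p <- solve(diag(n) - cfg$alpha * W, (1 - cfg$alpha) * r)
  stats::setNames(p / sum(p), uni$nodes)
}

# -- curve oracle ------------------------------------------------------------

oracle_roc_auc_mw <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
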