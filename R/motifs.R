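MOTIF_CLASSES <- c("protein_clique", "feed_forward_loop",
                   "interacting_coregulators", "coregulated_interactors",
                   "mixed_feedback_loop")

# 3x3 logical matrices of the induced sub-pattern on an ordered node triple.
triple_pattern <- function(graph, nodes) {
  P <- matrix(FALSE, 3, 3, dimnames = list(nodes, nodes))
  R <- P
  for (i in 1:2) for (j in (i + 1):3) {
    a <- min(nodes[i], nodes[j]); b <- max(nodes[i], nodes[j])
    if (any(graph$ppi$a == a & graph$ppi$b == b)) {
      P[i, j] <- P[j, i] <- TRUE
    }
  }
  for (i in 1:3) for (j in 1:3) {
    if (i != j && any(graph$reg$source == nodes[i] &
                      graph$reg$target == nodes[j])) R[i, j] <- TRUE
  }
  list(P = P, R = R)
}

.perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

# Classify the unlabeled pattern given PPI (symmetric) and regulatory
# (directed) 3x3 logical matrices. Returns a character vector of classes:
# protein_clique is tallied independently of the regulatory/mixed family,
# within which precedence is MFL > FFL > interacting_coregulators >
# coregulated_interactors.
classify_pattern <- function(P, R) {
  out <- character()
  if (P[1, 2] && P[1, 3] && P[2, 3]) out <- c(out, "protein_clique")
  mfl <- ffl <- ic <- ci <- FALSE
  for (r in seq_len(nrow(.perms3))) {
    x <- .perms3[r, 1]; y <- .perms3[r, 2]; z <- .perms3[r, 3]
    if (R[x, y] && R[x, z] && R[y, z]) {
      if (P[x, y]) mfl <- TRUE else ffl <- TRUE
    }
    if (P[x, y] && R[x, z] && R[y, z]) ic <- TRUE
    if (R[x, y] && R[x, z] && P[y, z]) ci <- TRUE
  }
  reg_class <- if (mfl) "mixed_feedback_loop"
  else if (ffl) "feed_forward_loop"
  else if (ic) "interacting_coregulators"
  else if (ci) "coregulated_interactors"
  else NULL
  c(out, reg_class)
}

#' Classify a 3-node motif
#'
#' Classifies the induced mixed subgraph on three distinct proteins into the
#' five motif classes: *protein clique* (all three physical pairs present),
#' *feed-forward loop* (TF X regulates TF Y, both regulate Z, X and Y do not
#' physically interact), *mixed feedback loop* (a feed-forward loop whose
#' two TFs physically interact — takes precedence over feed-forward loop),
#' *interacting coregulators* (physically interacting X and Y both regulate
#' Z), and *coregulated interactors* (one TF regulates physically
#' interacting Y and Z). A triple can be a protein clique and one
#' regulatory/mixed class at the same time; within the regulatory/mixed
#' family one class is reported by precedence (see the methods vignette).
#' Both orientations of a reciprocal regulation are considered.
#'
#' @param graph a [mixed_graph()].
#' @param a,b,c three distinct protein ids in the graph.
#' @return Character vector of matched classes (length 0, 1 or 2).
#' @export
classify_triple <- function(graph, a, b, c) {
  nodes <- c(a, b, c)
  if (length(unique(nodes)) != 3) stop("motif nodes must be distinct")
  if (!all(nodes %in% graph$nodes)) stop("motif nodes must be in the graph")
  pat <- triple_pattern(graph, nodes)
  classify_pattern(pat$P, pat$R)
}

# Pair-adjacency (any edge type, undirected, self-loops dropped) used to
# restrict the census to closed triangles: every motif class requires all
# three pairs to be adjacent.
union_adjacency <- function(graph, nodes) {
  reg <- graph$reg[graph$reg$source != graph$reg$target, , drop = FALSE]
  pairs <- rbind(
    data.frame(a = graph$ppi$a, b = graph$ppi$b, stringsAsFactors = FALSE),
    data.frame(a = pmin(reg$source, reg$target),
               b = pmax(reg$source, reg$target), stringsAsFactors = FALSE))
  pairs <- unique(pairs[pairs$a %in% nodes & pairs$b %in% nodes, ,
                        drop = FALSE])
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character()
  if (nrow(pairs) > 0) {
    sp <- split(c(pairs$b, pairs$a), c(pairs$a, pairs$b))
    for (v in names(sp)) adj[[v]] <- radix_sort(unique(sp[[v]]))
  }
  adj
}

#' Motif census of a mixed graph or node subset
#'
#' Counts, per motif class, the unordered node triples of the induced
#' subgraph classified to that class by [classify_triple()]. The census
#' enumerates closed triangles of the pair-adjacency (every class needs all
#' three pairs adjacent), which equals full triple enumeration.
#'
#' @param graph a [mixed_graph()].
#' @param nodes optional node subset (default: all nodes).
#' @return Named integer vector over the five classes.
#' @export
motif_census <- function(graph, nodes = NULL) {
  nodes <- radix_sort(nodes %||% graph$nodes)
  stopifnot(all(nodes %in% graph$nodes))
  # restrict edge tables once: triple_pattern scans them per triangle
  sub <- graph
  sub$ppi <- graph$ppi[graph$ppi$a %in% nodes & graph$ppi$b %in% nodes, ,
                       drop = FALSE]
  sub$reg <- graph$reg[graph$reg$source %in% nodes &
                       graph$reg$target %in% nodes, , drop = FALSE]
  adj <- union_adjacency(sub, nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)  # bytewise rank, not locale
  counts <- stats::setNames(integer(length(MOTIF_CLASSES)), MOTIF_CLASSES)
  for (u in nodes) {
    nb_u <- adj[[u]][idx[adj[[u]]] > idx[[u]]]
    if (length(nb_u) < 2) next
    for (vi in seq_len(length(nb_u) - 1L)) {
      v <- nb_u[vi]
      ws <- intersect(nb_u[(vi + 1L):length(nb_u)], adj[[v]])
      for (w in ws) {
        cls <- classify_triple(sub, u, v, w)
        counts[cls] <- counts[cls] + 1L
      }
    }
  }
  counts
}

#' Background motif distribution of a graph
#'
#' Whole-graph census plus proportions normalized over the five classes.
#'
#' @param graph a [mixed_graph()].
#' @return List with `counts` (named integer) and `proportions` (named
#'   numeric summing to 1 when any motif exists, otherwise all zero).
#' @export
background_distribution <- function(graph) {
  counts <- motif_census(graph)
  total <- sum(counts)
  props <- if (total > 0) counts / total else counts * 0
  list(counts = counts, proportions = props)
}

# One random connected induced node sample of the requested size: snowball
# growth from a uniformly chosen seed node, adding a uniformly chosen
# neighbor of the current set at each step. Restart on dead ends.
sample_connected_nodes <- function(adj, size, max_tries = 200L) {
  nodes <- names(adj)
  for (try in seq_len(max_tries)) {
    cur <- sample(nodes, 1)
    frontier <- adj[[cur]]
    while (length(cur) < size && length(frontier) > 0) {
      nxt <- if (length(frontier) == 1) frontier else sample(frontier, 1)
      cur <- c(cur, nxt)
      frontier <- setdiff(unique(c(frontier, adj[[nxt]])), cur)
    }
    if (length(cur) == size) return(cur)
  }
  stop("could not sample a connected induced subgraph of size ", size,
       "; the graph may have no component that large")
}

#' Motif enrichment of a subnetwork against its background graph
#'
#' Compares observed motif counts in a subnetwork with a Monte-Carlo null of
#' random connected induced subgraphs of the same node count drawn from the
#' background graph (queried subnetworks are connected by construction, so
#' the null is connectivity-matched). Reports, per class: observed count,
#' null mean/sd, enrichment ratio observed/null-mean (`NA` when the null
#' mean is 0), Z-score (0 when sd is 0 and observed equals the mean, `NA`
#' when sd is 0 otherwise) and the empirical upper-tail p-value with the
#' add-one correction, p = (1 + #\{null >= observed\}) / (reps + 1).
#'
#' @param sub_counts named counts from [motif_census()] on the subnetwork.
#' @param graph the background [mixed_graph()].
#' @param sub_node_count node count of the subnetwork (>= 3).
#' @param reps number of null replicates (>= 100 recommended).
#' @param seed RNG seed recorded in the report.
#' @return A `motif_report`: data.frame (class, observed, null_mean,
#'   null_sd, enrichment, z, p) with attributes `reps` and `seed`.
#' @export
motif_enrichment <- function(sub_counts, graph, sub_node_count,
                             reps = 999, seed = 1) {
  stopifnot(sub_node_count >= 3)
  if (sub_node_count > length(graph$nodes)) {
    stop("subnetwork larger than the background graph")
  }
  sub_counts <- sub_counts[MOTIF_CLASSES]
  adj <- union_adjacency_full(graph)
  null <- with_seed(seed, {
    t(vapply(seq_len(reps), function(i) {
      motif_census(graph, sample_connected_nodes(adj, sub_node_count))
    }, stats::setNames(numeric(length(MOTIF_CLASSES)), MOTIF_CLASSES)))
  })
  mu <- colMeans(null)
  sdv <- apply(null, 2, stats::sd)
  z <- ifelse(sdv > 0, (sub_counts - mu) / sdv,
              ifelse(sub_counts == mu, 0, NA_real_))
  p <- vapply(MOTIF_CLASSES, function(cl) {
    (1 + sum(null[, cl] >= sub_counts[[cl]])) / (reps + 1)
  }, numeric(1))
  rep_df <- data.frame(class = MOTIF_CLASSES,
                       observed = as.integer(sub_counts),
                       null_mean = unname(mu), null_sd = unname(sdv),
                       enrichment = ifelse(mu > 0, sub_counts / mu, NA_real_),
                       z = unname(z), p = unname(p),
                       stringsAsFactors = FALSE)
  attr(rep_df, "reps") <- reps
  attr(rep_df, "seed") <- seed
  class(rep_df) <- c("motif_report", "data.frame")
  rep_df
}

union_adjacency_full <- function(graph) union_adjacency(graph, graph$nodes)
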