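#' Random-walk configuration
#'
#' @param alpha damping factor in (0,1): the probability of following an
#'   edge rather than restarting. Default 0.7 (restart probability 0.3).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter maximum number of iterations.
#' @param universe walk substrate: `"full"` (proteins, GO-term nodes and
#'   annotation edges on top of the interaction edges), `"annotations_only"`
#'   (protein-term annotation edges only) or `"interactions_only"`
#'   (physical + regulatory edges among proteins only).
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(alpha = 0.7, tol = 1e-10, max_iter = 1000,
                        universe = c("full", "annotations_only",
                                     "interactions_only")) {
  universe <- match.arg(universe)
  stopifnot(alpha > 0, alpha < 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = max_iter,
                 universe = universe), class = "walk_config")
}

# Undirected simple edge list (two-column character matrix) of the walk
# universe plus its node set. GO-term nodes are prefixed as-is (GO ids never
# collide with protein ids in practice; collisions would merge nodes).
walk_universe_edges <- function(graph, annots, universe) {
  interact <- NULL
  if (universe %in% c("full", "interactions_only")) {
    fe <- filtered_edges(graph, "mixed")
    interact <- cbind(pmin(fe$source, fe$target), pmax(fe$source, fe$target))
  }
  annot <- NULL
  if (universe %in% c("full", "annotations_only")) {
    annot <- cbind(annots$protein, annots$term)
  }
  edges <- unique(rbind(interact, annot))
  nodes <- radix_sort(unique(c(graph$nodes, as.vector(edges))))
  list(nodes = nodes, edges = edges)
}

#' Personalized PageRank from the proteins annotated to a GO term
#'
#' Power iteration for the stationary distribution
#' `p = (1 - alpha) r + alpha W^T p`, where `r` is uniform over the restart
#' set (the proteins annotated to the term, direct or inferred) and `W` is
#' the column-normalized adjacency of the undirected walk universe. Dangling
#' nodes redistribute their mass to the restart vector. Iteration stops when
#' the L1 change drops below the tolerance; the result sums to 1.
#'
#' @param graph a [mixed_graph()].
#' @param annots a propagated [annotation_set()].
#' @param term GO term id whose annotated proteins form the restart set.
#' @param cfg a [walk_config()].
#' @return Named numeric vector of visitation probabilities over all nodes
#'   of the walk universe (proteins and, depending on the universe, GO-term
#'   nodes).
#' @export
personalized_pagerank <- function(graph, annots, term, cfg = walk_config()) {
  restart <- annotated_proteins(annots, term, include_inferred = TRUE)
  if (length(restart) == 0) stop("empty restart set for term ", term)
  uni <- walk_universe_edges(graph, annots, cfg$universe)
  restart <- intersect(restart, uni$nodes)
  if (length(restart) == 0) stop("restart set absent from walk universe")
  n <- length(uni$nodes)
  idx <- stats::setNames(seq_len(n), uni$nodes)
  r <- numeric(n)
  r[idx[restart]] <- 1 / length(restart)
  if (is.null(uni$edges) || nrow(uni$edges) == 0) {
    return(stats::setNames(r, uni$nodes))
  }
  i <- idx[uni$edges[, 1]]
  j <- idx[uni$edges[, 2]]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n))
  deg <- Matrix::colSums(A)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  alpha <- cfg$alpha
  p <- r
  for (it in seq_len(cfg$max_iter)) {
    walk <- as.numeric(A %*% (p * inv_deg))
    dangling <- sum(p[deg == 0])
    p_new <- (1 - alpha) * r + alpha * (walk + dangling * r)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < cfg$tol) {
      return(stats::setNames(p / sum(p), uni$nodes))
    }
  }
  stop("personalized PageRank did not converge in ", cfg$max_iter,
       " iterations (residual ", format(delta), ")")
}

# Scores for an arbitrary set of candidate proteins under one method.
# random_walk / degree / one_hop: larger is better; hypergeometric: smaller
# is better (upper-tail p-value).
score_proteins <- function(graph, annots, proteins, term, method,
                           cfg = walk_config(), pr_cache = NULL) {
  ann <- annotated_proteins(annots, term, include_inferred = TRUE)
  switch(method,
    random_walk = {
      pr <- if (!is.null(pr_cache) && !is.null(pr_cache[[term]])) {
        pr_cache[[term]]
      } else {
        p <- personalized_pagerank(graph, annots, term, cfg)
        if (!is.null(pr_cache)) pr_cache[[term]] <- p
        p
      }
      stats::setNames(ifelse(proteins %in% names(pr), pr[proteins], 0),
                      proteins)
    },
    degree = stats::setNames(vapply(proteins, protein_degree,
                                    numeric(1), graph = graph,
                                    filter = "mixed"), proteins),
    one_hop = stats::setNames(vapply(proteins, function(s) {
      length(intersect(protein_neighbors(graph, s, "mixed"), ann))
    }, numeric(1)), proteins),
    hypergeometric = {
      N <- length(graph$nodes)
      K <- length(intersect(ann, graph$nodes))
      stats::setNames(vapply(proteins, function(s) {
        x <- length(intersect(protein_neighbors(graph, s, "mixed"), ann))
        n_draw <- min(protein_degree(graph, s, "mixed"), N)
        stats::phyper(x - 1, K, N - K, n_draw, lower.tail = FALSE)
      }, numeric(1)), proteins)
    },
    stop("unknown method: ", method)
  )
}

method_higher_is_better <- function(method) method != "hypergeometric"

#' Rank a query protein's association with a GO term
#'
#' Scores the query protein against all candidate proteins not annotated
#' (directly or by inference) to the term, using one of four methods:
#' `random_walk` (personalized PageRank visitation probability),
#' `degree` (degree in the full mixed graph; ignores the term and serves as
#' a degree-bias control), `one_hop` (number of neighbors annotated to the
#' term) or `hypergeometric` (upper-tail probability of observing that many
#' annotated neighbors given the term size and the protein's degree;
#' smaller is better). The rank is a competition rank in the method's
#' better-direction (1 = best; ties share the best rank).
#'
#' @param graph a [mixed_graph()].
#' @param annots a propagated [annotation_set()].
#' @param protein query protein id.
#' @param term GO term id.
#' @param method one of `"random_walk"`, `"degree"`, `"one_hop"`,
#'   `"hypergeometric"`.
#' @param cfg a [walk_config()].
#' @return A `ranking_report`: list with `method`, `protein`, `term`,
#'   `score`, `rank`, `n_candidates` and the full named `scores` vector
#'   over candidates.
#' @export
rank_query <- function(graph, annots, protein, term,
                       method = c("random_walk", "degree", "one_hop",
                                  "hypergeometric"),
                       cfg = walk_config(), pr_cache = NULL) {
  method <- match.arg(method)
  if (!protein %in% graph$nodes) stop("unknown protein: ", protein)
  ann <- annotated_proteins(annots, term, include_inferred = TRUE)
  if (length(intersect(ann, graph$nodes)) == 0) {
    stop("term has no annotated proteins in the graph: ", term)
  }
  candidates <- radix_sort(unique(c(setdiff(graph$nodes, ann), protein)))
  scores <- score_proteins(graph, annots, candidates, term, method, cfg,
                           pr_cache)
  rank <- competition_rank(scores, method_higher_is_better(method))
  structure(list(method = method, protein = protein, term = term,
                 score = unname(scores[protein]),
                 rank = unname(rank[protein]),
                 n_candidates = length(candidates),
                 scores = scores),
            class = "ranking_report")
}

# Competition ranking (min rank for ties) in the better-direction.
competition_rank <- function(scores, higher_better = TRUE) {
  s <- if (higher_better) -scores else scores
  r <- rank(s, ties.method = "min")
  stats::setNames(as.integer(r), names(scores))
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("ranking_report [", x$method, "]: ", x$protein, " vs ", x$term,
      " -> rank ", x$rank, " of ", x$n_candidates,
      " (score ", format(x$score, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Batch ranking over (protein, term) pairs
#'
#' One [rank_query()] report per pair; the PageRank vector is computed once
#' per distinct term and reused. Per-pair errors are collected, not fatal.
#'
#' @inheritParams rank_query
#' @param pairs data.frame with columns `protein` and `term`.
#' @return List of `ranking_report` (or `NULL` with a recorded error);
#'   errors in attribute `errors`.
#' @export
batch_rank <- function(graph, annots, pairs,
                       method = "random_walk", cfg = walk_config()) {
  pr_cache <- new.env(parent = emptyenv())
  errors <- character()
  reports <- lapply(seq_len(nrow(pairs)), function(i) {
    tryCatch(
      rank_query(graph, annots, pairs$protein[i], pairs$term[i], method,
                 cfg, pr_cache = pr_cache),
      error = function(e) {
        errors[[length(errors) + 1L]] <<- conditionMessage(e)
        NULL
      })
  })
  attr(reports, "errors") <- errors
  reports
}
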