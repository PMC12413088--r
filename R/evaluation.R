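#' Sample positive (protein, term) pairs
#'
#' Draws n distinct direct annotation records uniformly at random. Each
#' positive is evaluated on a graph from which that annotation edge (and
#' any inferred ancestor records left without direct support) has been
#' removed.
#'
#' @param annots an [annotation_set()].
#' @param n number of positives.
#' @param seed RNG seed.
#' @return data.frame with columns `protein`, `term`.
#' @export
sample_positives <- function(annots, n, seed = 1) {
  direct <- annots[annots$provenance == "direct", , drop = FALSE]
  if (n > nrow(direct)) {
    stop("requested ", n, " positives but only ", nrow(direct),
         " direct records exist")
  }
  idx <- with_seed(seed, sample.int(nrow(direct), n))
  data.frame(protein = direct$protein[idx], term = direct$term[idx],
             stringsAsFactors = FALSE)
}

#' Remove one direct annotation edge (with unsupported inferred ancestors)
#'
#' Deletes the direct (protein, term) record and recomputes the protein's
#' inferred records from its remaining direct annotations, so inferred
#' ancestor records that had no other direct support disappear with the
#' edge.
#'
#' @param annots a propagated [annotation_set()].
#' @param protein,term the direct record to remove.
#' @param dag the [ontology_dag()] used for propagation.
#' @param relations relations traversed by the closure.
#' @return A propagated [annotation_set()] without the record.
#' @export
remove_annotation <- function(annots, protein, term, dag,
                              relations = c("is_a", "part_of")) {
  hit <- annots$protein == protein & annots$term == term &
    annots$provenance == "direct"
  if (!any(hit)) stop("no direct record for (", protein, ", ", term, ")")
  keep <- annots[!(annots$protein == protein), , drop = FALSE]
  mine_direct <- annots[annots$protein == protein & !hit &
                        annots$provenance == "direct", , drop = FALSE]
  if (nrow(mine_direct) > 0) {
    mine <- propagate_annotations(annotation_set(mine_direct), dag,
                                  relations)
    keep <- rbind(keep, mine)
  }
  annotation_set(keep)
}

#' Sample degree-matched nearby negatives for a positive pair
#'
#' Negatives must (1) lie near the positive protein on the interactions-only
#' view (within `radius` hops; the radius is relaxed stepwise through
#' `radii` when fewer than `m` candidates exist), (2) not be annotated —
#' directly or by inference — to the positive's term (never relaxed), and
#' (3) have approximately the positive's mixed degree:
#' `|deg(neg) - deg(pos)| <= max(deg_slack, deg_frac * deg(pos))`.
#'
#' @param graph a [mixed_graph()].
#' @param annots a propagated [annotation_set()].
#' @param protein,term the positive pair.
#' @param m maximum number of negatives.
#' @param seed RNG seed.
#' @param radii increasing proximity radii tried in order.
#' @param deg_slack,deg_frac degree-matching tolerance parameters.
#' @return Character vector of sampled negative ids with attributes
#'   `radius` (the radius actually used) and `n_eligible`; `character(0)`
#'   if no protein is eligible at the largest radius.
#' @export
sample_negatives <- function(graph, annots, protein, term, m = 100,
                             seed = 1, radii = c(2, 3, 4),
                             deg_slack = 2, deg_frac = 0.1) {
  ann <- annotated_proteins(annots, term, include_inferred = TRUE)
  dist <- adj_bfs_distances(traversal_view(graph, "mixed"), protein)
  dpos <- protein_degree(graph, protein, "mixed")
  tol <- max(deg_slack, deg_frac * dpos)
  degs <- node_degrees(graph)
  base_ok <- !(graph$nodes %in% ann) & graph$nodes != protein &
    abs(degs - dpos) <= tol
  used_radius <- NA_integer_
  eligible <- character()
  for (r in radii) {
    eligible <- graph$nodes[base_ok & dist[graph$nodes] <= r]
    used_radius <- r
    if (length(eligible) >= m) break
  }
  if (length(eligible) == 0) {
    out <- character()
    attr(out, "radius") <- used_radius
    attr(out, "n_eligible") <- 0L
    return(out)
  }
  sel <- if (length(eligible) <= m) radix_sort(eligible) else {
    radix_sort(with_seed(seed, sample(eligible, m)))
  }
  attr(sel, "radius") <- used_radius
  attr(sel, "n_eligible") <- length(eligible)
  sel
}

# Mixed degrees of every node, vectorized.
node_degrees <- function(graph) {
  tab <- table(factor(c(graph$ppi$a, graph$ppi$b, graph$reg$source,
                        graph$reg$target), levels = graph$nodes))
  stats::setNames(as.integer(tab), graph$nodes)
}

#' Build an evaluation dataset of positives with matched negatives
#'
#' @inheritParams sample_negatives
#' @param n_positives number of positive pairs.
#' @param m_negatives negatives per positive.
#' @param seed master seed; per-positive sampling derives from it.
#' @return An `eval_dataset`: list of trials, each with `protein`, `term`,
#'   `negatives`, `radius`; positives with no eligible negative are skipped
#'   and listed in attribute `skipped`.
#' @export
build_eval_dataset <- function(graph, annots, n_positives, m_negatives,
                               seed = 1, radii = c(2, 3, 4),
                               deg_slack = 2, deg_frac = 0.1) {
  pos <- sample_positives(annots, n_positives, seed = derive_seed(seed, 1))
  skipped <- character()
  trials <- list()
  for (i in seq_len(nrow(pos))) {
    neg <- sample_negatives(graph, annots, pos$protein[i], pos$term[i],
                            m = m_negatives,
                            seed = derive_seed(seed, 1000 + i),
                            radii = radii, deg_slack = deg_slack,
                            deg_frac = deg_frac)
    if (length(neg) == 0) {
      skipped <- c(skipped, paste0(pos$protein[i], "/", pos$term[i]))
      next
    }
    trials[[length(trials) + 1L]] <-
      list(protein = pos$protein[i], term = pos$term[i],
           negatives = as.character(neg), radius = attr(neg, "radius"))
  }
  structure(trials, class = "eval_dataset", skipped = skipped, seed = seed)
}

# --- ROC / PR ---------------------------------------------------------------

# Points of the ROC curve by threshold sweep over distinct scores (higher
# score = predicted positive first); ties enter together. AUC by trapezoid.
roc_curve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  ord <- order(-scores)
  labels <- labels[ord]; scores <- scores[ord]
  P <- sum(labels == 1); N <- sum(labels == 0)
  tp <- cumsum(labels == 1); fp <- cumsum(labels == 0)
  last <- !duplicated(scores, fromLast = TRUE)  # one point per threshold
  tpr <- c(0, tp[last] / max(P, 1))
  fpr <- c(0, fp[last] / max(N, 1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Precision-recall with step interpolation: AUC = sum over recall
# increments of the precision at that threshold.
pr_curve <- function(labels, scores) {
  ord <- order(-scores)
  labels <- labels[ord]; scores <- scores[ord]
  P <- sum(labels == 1)
  tp <- cumsum(labels == 1)
  fp <- cumsum(labels == 0)
  last <- !duplicated(scores, fromLast = TRUE)
  recall <- tp[last] / max(P, 1)
  precision <- tp[last] / (tp[last] + fp[last])
  auc <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = c(0, recall),
                           precision = c(1, precision)), auc = auc)
}

#' Run the annotation-prediction benchmark
#'
#' For every trial, the positive's direct annotation edge (plus unsupported
#' inferred ancestors) is removed, the positive and its negatives are
#' scored by each method on that modified annotation set, and scores are
#' pooled across trials on a common scale: the within-trial normalized rank
#' `rank / (1 + candidates)` (competition rank in the method's
#' better-direction; smaller is better), negated so that larger pooled
#' scores mean stronger predicted association. ROC (trapezoid AUC) and PR
#' (step-interpolated AUC) curves are computed per method from the pooled
#' table.
#'
#' @param graph a [mixed_graph()].
#' @param annots a propagated [annotation_set()].
#' @param dag the [ontology_dag()].
#' @param dataset an `eval_dataset` from [build_eval_dataset()].
#' @param methods character vector of scoring methods.
#' @param cfg a [walk_config()].
#' @return An `eval_curves`: per method a list with `roc`, `pr`, `roc_auc`,
#'   `pr_auc`, plus the pooled `table` (trial, protein, label, method
#'   columns of pooled scores).
#' @export
run_benchmark <- function(graph, annots, dag, dataset,
                          methods = c("random_walk", "degree", "one_hop",
                                      "hypergeometric"),
                          cfg = walk_config()) {
  stopifnot(length(dataset) > 0)
  rows <- list()
  failures <- stats::setNames(integer(length(methods)), methods)
  for (ti in seq_along(dataset)) {
    trial <- dataset[[ti]]
    annots_t <- remove_annotation(annots, trial$protein, trial$term, dag)
    cand <- c(trial$protein, trial$negatives)
    labels <- c(1L, rep(0L, length(trial$negatives)))
    row <- data.frame(trial = ti, protein = cand, label = labels,
                      stringsAsFactors = FALSE)
    ok <- TRUE
    for (mth in methods) {
      sc <- tryCatch(
        score_proteins(graph, annots_t, cand, trial$term, mth, cfg),
        error = function(e) NULL)
      if (is.null(sc)) {
        failures[mth] <- failures[mth] + 1L
        row[[mth]] <- NA_real_
        next
      }
      r <- competition_rank(sc, method_higher_is_better(mth))
      row[[mth]] <- -(r / (1 + length(cand)))
    }
    rows[[ti]] <- row
  }
  pooled <- do.call(rbind, rows)
  out <- list(table = pooled, methods = methods, failures = failures)
  for (mth in methods) {
    keep <- !is.na(pooled[[mth]])
    roc <- roc_curve(pooled$label[keep], pooled[[mth]][keep])
    pr <- pr_curve(pooled$label[keep], pooled[[mth]][keep])
    out[[mth]] <- list(roc = roc$points, pr = pr$points,
                       roc_auc = roc$auc, pr_auc = pr$auc)
  }
  class(out) <- "eval_curves"
  out
}

#' @export
print.eval_curves <- function(x, ...) {
  cat("eval_curves over", length(unique(x$table$trial)), "trials:\n")
  for (mth in x$methods) {
    cat(sprintf("  %-16s ROC AUC %.3f  PR AUC %.3f\n", mth,
                x[[mth]]$roc_auc, x[[mth]]$pr_auc))
  }
  invisible(x)
}

#' Plot ROC and PR curves
#'
#' Writes one ROC and one PR figure with per-method series and the AUC
#' (rounded to 2 decimals) in the legend.
#'
#' @param curves an `eval_curves`.
#' @param out_prefix file prefix; `<prefix>_roc.png` and `<prefix>_pr.png`
#'   are written.
#' @return Invisibly, the two file paths.
#' @export
plot_curves <- function(curves, out_prefix) {
  roc_df <- do.call(rbind, lapply(curves$methods, function(mth) {
    cbind(curves[[mth]]$roc,
          method = sprintf("%s (AUC %.2f)", mth, curves[[mth]]$roc_auc))
  }))
  pr_df <- do.call(rbind, lapply(curves$methods, function(mth) {
    cbind(curves[[mth]]$pr,
          method = sprintf("%s (AUC %.2f)", mth, curves[[mth]]$pr_auc))
  }))
  roc_path <- paste0(out_prefix, "_roc.png")
  pr_path <- paste0(out_prefix, "_pr.png")
  g1 <- ggplot2::ggplot(roc_df, ggplot2::aes(x = fpr, y = tpr, color = method)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  color = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(roc_path, g1, width = 5, height = 4, dpi = 150)
  g2 <- ggplot2::ggplot(pr_df, ggplot2::aes(x = recall, y = precision, color = method)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Recall", y = "Precision", color = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(pr_path, g2, width = 5, height = 4, dpi = 150)
  invisible(c(roc_path, pr_path))
}
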