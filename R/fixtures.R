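#' Specification for a synthetic fixture
#'
#' Describes a synthetic ontology, mixed graph and annotation set with
#' planted, recoverable structure: each leaf GO term gets a cluster of
#' member proteins whose pairwise PPI probability is the background
#' probability times `density_boost`, plus a transcription-factor member
#' regulating the others; only a `completeness` fraction of true members is
#' actually annotated, so the hidden members are learnable targets for the
#' ranking methods. Defaults are the package's reference study conditions
#' (see the methods vignette for the rationale).
#'
#' @param n_proteins number of proteins.
#' @param ppi_mean_degree mean background PPI degree (Erdos-Renyi
#'   probability `ppi_mean_degree / (n_proteins - 1)`).
#' @param n_terms number of leaf GO terms with planted clusters.
#' @param members_per_term true member count of each term's cluster.
#' @param density_boost multiplier on the background PPI probability for
#'   within-cluster pairs.
#' @param completeness probability that a true member is annotated.
#' @param tf_fraction fraction of proteins acting as background TFs, each
#'   regulating `reg_out` random targets (cluster TFs are planted on top).
#' @param reg_out out-degree of each background TF.
#' @param cluster_tfs number of dedicated (non-member) regulators planted
#'   per term, each regulating every member.
#' @param depth,branching shape of the ontology tree below the root.
#' @param seed RNG seed; identical specs give identical fixtures.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 500, ppi_mean_degree = 36,
                         n_terms = 20, members_per_term = 45,
                         density_boost = 3, completeness = 0.8,
                         tf_fraction = 0.05, reg_out = 4, cluster_tfs = 5,
                         depth = 2, branching = 5, seed = 1) {
  stopifnot(n_proteins >= 10, ppi_mean_degree > 0, n_terms >= 1,
            members_per_term >= 3, density_boost >= 0,
            completeness >= 0, completeness <= 1,
            tf_fraction >= 0, tf_fraction <= 1, cluster_tfs >= 0,
            depth >= 1, branching >= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic ontology
#'
#' A rooted tree of the requested depth and branching (ids `GO:1NNNNNN`),
#' optionally with cross-links giving some terms a second parent.
#'
#' @param depth tree depth below the root.
#' @param branching children per internal term.
#' @param n_cross_links number of extra is_a edges to random non-ancestor
#'   terms one level up.
#' @param namespace namespace label for every term.
#' @param seed RNG seed (used only for cross-links).
#' @return An [ontology_dag()].
#' @export
make_ontology <- function(depth = 2, branching = 5, n_cross_links = 0,
                          namespace = "biological_process", seed = 1) {
  stopifnot(depth >= 1, branching >= 1)
  ids <- "GO:1000000"
  levels <- list("GO:1000000")
  parents <- list()
  counter <- 0L
  for (d in seq_len(depth)) {
    lev <- character()
    for (p in levels[[d]]) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- sprintf("GO:1%06d", counter)
        lev <- c(lev, id)
        parents[[length(parents) + 1L]] <-
          data.frame(child = id, parent = p, relation = "is_a",
                     stringsAsFactors = FALSE)
      }
    }
    levels[[d + 1L]] <- lev
    ids <- c(ids, lev)
  }
  pdf <- do.call(rbind, parents)
  if (n_cross_links > 0 && depth >= 2) {
    extra <- with_seed(seed, {
      kids <- sample(levels[[depth + 1L]], min(n_cross_links,
                                               length(levels[[depth + 1L]])))
      data.frame(child = kids,
                 parent = sample(levels[[depth]], length(kids),
                                 replace = TRUE),
                 relation = "is_a", stringsAsFactors = FALSE)
    })
    pdf <- unique(rbind(pdf, extra))
  }
  tdf <- data.frame(id = ids,
                    name = ifelse(ids == "GO:1000000", namespace,
                                  paste0("synthetic term ", ids)),
                    namespace = namespace, obsolete = FALSE,
                    stringsAsFactors = FALSE)
  ontology_dag(tdf, pdf)
}

#' Generate a mixed graph with planted cluster structure
#'
#' Background: Erdos-Renyi PPI edges plus random TF regulation. Planted per
#' leaf term: a member cluster with boosted within-cluster PPI probability
#' and a cluster TF (the first member) regulating every other member.
#' Returns the graph, the ontology, the (direct) annotation set over the
#' *observed* members, and a ground-truth record including the hidden
#' members.
#'
#' @param spec a [fixture_spec()].
#' @return List with `graph` ([mixed_graph()]), `dag` ([ontology_dag()]),
#'   `annots` (direct [annotation_set()]), and `truth` (list with
#'   `members`, `hidden`, `cluster_tf` per term).
#' @export
make_mixed_graph <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_proteins
    proteins <- sprintf("P%04d", seq_len(n))
    p_bg <- min(1, spec$ppi_mean_degree / (n - 1))
    # background PPI: sample pair indices via binomial count, then distinct
    # pairs
    n_pairs <- n * (n - 1) / 2
    m_bg <- stats::rbinom(1, n_pairs, p_bg)
    pick <- sample(n_pairs, m_bg)
    ij <- pair_from_index(pick, n)
    ppi <- data.frame(source = proteins[ij[, 1]], target = proteins[ij[, 2]],
                      evidence = "bg", stringsAsFactors = FALSE)
    # ontology: enough leaves for the requested terms
    depth <- spec$depth
    branching <- spec$branching
    while (branching^depth < spec$n_terms) branching <- branching + 1L
    dag <- make_ontology(depth, branching, n_cross_links = 0)
    leaves <- setdiff(dag$terms$id, dag$parents$parent)
    terms <- leaves[seq_len(spec$n_terms)]
    truth <- list()
    planted_ppi <- list()
    planted_reg <- list()
    # planted pairs are drawn on top of the background draw; choose the
    # planted probability so the combined within-cluster edge probability
    # equals density_boost * p_bg exactly
    p_target <- min(1, p_bg * spec$density_boost)
    p_in <- if (p_bg >= 1) 0 else max(0, 1 - (1 - p_target) / (1 - p_bg))
    for (t in terms) {
      n_tfs <- spec$cluster_tfs %||% 3
      picked <- sample(proteins, spec$members_per_term + n_tfs)
      # cluster regulators are not members: they drive the process but are
      # not annotated to it, so regulator-mediated association is visible
      # only to walk-based scoring over the mixed graph
      tf <- utils::head(picked, n_tfs)
      members <- utils::tail(picked, spec$members_per_term)
      pairs <- utils::combn(radix_sort(members), 2)
      keep <- stats::runif(ncol(pairs)) < p_in
      if (any(keep)) {
        planted_ppi[[t]] <- data.frame(source = pairs[1, keep],
                                       target = pairs[2, keep],
                                       evidence = "cluster",
                                       stringsAsFactors = FALSE)
      }
      if (n_tfs > 0) {
        planted_reg[[t]] <- data.frame(
          source = rep(tf, each = length(members)),
          target = rep(members, times = length(tf)),
          evidence = "cluster_tf", stringsAsFactors = FALSE)
      }
      observed <- members[stats::runif(length(members)) < spec$completeness]
      truth[[t]] <- list(members = radix_sort(members),
                         hidden = radix_sort(setdiff(members, observed)),
                         observed = radix_sort(observed),
                         cluster_tf = tf)
    }
    # background regulation
    n_tf <- round(spec$tf_fraction * n)
    reg_bg <- NULL
    if (n_tf > 0 && spec$reg_out > 0) {
      tfs <- sample(proteins, n_tf)
      reg_bg <- do.call(rbind, lapply(tfs, function(tf) {
        data.frame(source = tf,
                   target = sample(setdiff(proteins, tf), spec$reg_out),
                   evidence = "bg_tf", stringsAsFactors = FALSE)
      }))
    }
    graph <- mixed_graph(nodes = proteins,
                         ppi = rbind(ppi, do.call(rbind, planted_ppi)),
                         reg = rbind(reg_bg, do.call(rbind, planted_reg)),
                         species = "synthetic")
    ann_rows <- do.call(rbind, lapply(terms, function(t) {
      obs <- truth[[t]]$observed
      if (length(obs) == 0) return(NULL)
      data.frame(protein = obs, term = t, provenance = "direct",
                 evidence = "IEA", stringsAsFactors = FALSE)
    }))
    annots <- annotation_set(ann_rows)
    list(graph = graph, dag = dag, annots = annots,
         truth = stats::setNames(truth, terms), terms = terms, spec = spec)
  })
}

# Map linear indices in 1..n*(n-1)/2 to (i < j) pairs.
pair_from_index <- function(k, n) {
  # row i occupies indices offset(i)+1 .. offset(i)+(n-i), offset cumulative
  sizes <- (n - 1):1
  ends <- cumsum(sizes)
  i <- findInterval(k - 1, c(0, ends), rightmost.closed = FALSE)
  j <- k - c(0, ends)[i] + i
  cbind(i, j)
}

#' Plant disjoint motif instances into a graph
#'
#' Adds edges forming `count` instances of one motif class on triples of
#' nodes that currently have no edges among or between them, so the census
#' on the affected nodes finds exactly the planted instances.
#'
#' @param graph a [mixed_graph()].
#' @param class a motif class name (see [classify_triple()]).
#' @param count number of disjoint instances.
#' @param seed RNG seed for triple selection.
#' @return List with `graph` (augmented) and `triples` (list of node
#'   triples, each ordered as the motif's X, Y, Z).
#' @export
plant_motifs <- function(graph, class, count, seed = 1) {
  stopifnot(class %in% MOTIF_CLASSES, count >= 1)
  adj <- union_adjacency_full(graph)
  avail <- with_seed(seed, sample(graph$nodes))
  chosen <- list()
  used <- character()
  for (v in avail) {
    if (length(chosen) == count) break
    if (v %in% used) next
    # greedily pick mutually non-adjacent, unused partners
    partners <- character()
    for (w in avail) {
      if (length(partners) == 2) break
      if (w == v || w %in% used || w %in% adj[[v]]) next
      if (length(partners) == 1 &&
          (w %in% adj[[partners]] || partners %in% adj[[w]])) next
      partners <- c(partners, w)
    }
    if (length(partners) == 2) {
      chosen[[length(chosen) + 1L]] <- c(v, partners)
      used <- c(used, v, partners)
    }
  }
  if (length(chosen) < count) {
    stop("not enough mutually non-adjacent triples to plant ", count,
         " motifs")
  }
  ppi_new <- list(); reg_new <- list()
  for (tri in chosen) {
    x <- tri[1]; y <- tri[2]; z <- tri[3]
    e <- motif_edge_template(class, x, y, z)
    ppi_new[[length(ppi_new) + 1L]] <- e$ppi
    reg_new[[length(reg_new) + 1L]] <- e$reg
  }
  aug <- mixed_graph(
    nodes = graph$nodes,
    ppi = rbind(data.frame(source = graph$ppi$a, target = graph$ppi$b,
                           evidence = graph$ppi$evidence),
                do.call(rbind, ppi_new)),
    reg = rbind(graph$reg, do.call(rbind, reg_new)),
    species = graph$species)
  list(graph = aug, triples = chosen)
}

motif_edge_template <- function(class, x, y, z) {
  ppi <- function(...) {
    p <- rbind(...)
    if (is.null(p)) return(NULL)
    data.frame(source = p[, 1], target = p[, 2], evidence = "planted",
               stringsAsFactors = FALSE)
  }
  reg <- ppi
  switch(class,
    protein_clique = list(ppi = ppi(c(x, y), c(x, z), c(y, z)), reg = NULL),
    feed_forward_loop = list(ppi = NULL,
                             reg = reg(c(x, y), c(x, z), c(y, z))),
    mixed_feedback_loop = list(ppi = ppi(c(x, y)),
                               reg = reg(c(x, y), c(x, z), c(y, z))),
    interacting_coregulators = list(ppi = ppi(c(x, y)),
                                    reg = reg(c(x, z), c(y, z))),
    coregulated_interactors = list(ppi = ppi(c(y, z)),
                                   reg = reg(c(x, y), c(x, z))))
}

#' Write a fixture to a bundle directory
#'
#' Emits the canonical plain-text parts consumed by the readers: `ppi.tsv`,
#' `reg.tsv`, `ontology.obo`, `annotations.gaf`, `truth.json` and
#' `meta.json`.
#'
#' @param fixture result of [make_mixed_graph()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edges(fixture$graph, file.path(dir, "ppi.tsv"),
              file.path(dir, "reg.tsv"))
  write_obo(fixture$dag, file.path(dir, "ontology.obo"))
  write_gaf(fixture$annots, file.path(dir, "annotations.gaf"))
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(list(species = fixture$graph$species,
                            n_nodes = length(fixture$graph$nodes),
                            n_ppi = nrow(fixture$graph$ppi),
                            n_reg = nrow(fixture$graph$reg)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a graph bundle directory
#'
#' Reads the parts written by [write_fixture_bundle()] / the `build` CLI
#' command, propagates annotations, and returns the assembled objects.
#'
#' @param dir bundle directory.
#' @return List with `graph`, `dag`, `annots` (propagated).
#' @export
load_bundle <- function(dir) {
  graph <- load_edges(file.path(dir, "ppi.tsv"), file.path(dir, "reg.tsv"))
  dag <- parse_obo(file.path(dir, "ontology.obo"))
  annots <- parse_gaf(file.path(dir, "annotations.gaf"), dag)
  list(graph = graph, dag = dag,
       annots = propagate_annotations(annots, dag))
}
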