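test_that("parse_obo reads chains, multiple parents and obsolete flags", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000003", "name: C", "namespace: bp", "",
    "[Term]", "id: GO:0000002", "name: B", "namespace: bp",
    "is_a: GO:0000003 ! C", "",
    "[Term]", "id: GO:0000001", "name: A", "namespace: bp",
    "is_a: GO:0000002 ! B", "",
    "[Term]", "id: GO:0000004", "name: D", "namespace: bp",
    "is_a: GO:0000002", "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000005", "name: gone", "namespace: bp",
    "is_obsolete: true", ""), obo)
  dag <- parse_obo(obo)
  expect_equal(nrow(dag$terms), 5)
  expect_equal(sum(dag$terms$obsolete), 1)
  expect_equal(nrow(dag$parents), 4)
  expect_setequal(dag$parents$parent[dag$parents$child == "GO:0000004"],
                  c("GO:0000002", "GO:0000003"))
  expect_equal(term_ancestors(dag, "GO:0000001"),
               c("GO:0000002", "GO:0000003"))
})

test_that("cyclic is_a relations are rejected", {
  terms <- data.frame(id = c("GO:1", "GO:2"), name = "x", namespace = "bp",
                      obsolete = FALSE)
  parents <- data.frame(child = c("GO:1", "GO:2"),
                        parent = c("GO:2", "GO:1"), relation = "is_a")
  expect_error(ontology_dag(terms, parents), "cyclic")
})

test_that("ontology OBO round-trip is exact on generated DAGs", {
  for (sd in 1:3) {
    dag <- make_ontology(depth = 3, branching = 3, n_cross_links = 5,
                         seed = sd)
    path <- tempfile(fileext = ".obo")
    write_obo(dag, path)
    back <- parse_obo(path)
    reorder <- function(d) {
      d$terms <- d$terms[order(d$terms$id), ]
      rownames(d$terms) <- NULL
      d$parents <- d$parents[order(d$parents$child, d$parents$parent), ]
      rownames(d$parents) <- NULL
      d
    }
    expect_equal(reorder(back), reorder(dag))
  }
})

test_that("parse_gaf drops NOT qualifiers, merges evidence, counts skips", {
  dag <- chain_dag(c("GO:0000001", "GO:0000002"))
  dag$terms <- rbind(dag$terms,
                     data.frame(id = "GO:0000009", name = "obs",
                                namespace = "bp", obsolete = TRUE))
  gaf <- tempfile(fileext = ".gaf")
  gline <- function(prot, qual, term, ev) {
    paste("DB", prot, prot, qual, term, "REF", ev, "", "P", "", "",
          "protein", "taxon:7227", "20240101", "DB", "", "", sep = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               gline("Eb1", "", "GO:0000001", "IDA"),
               gline("Eb1", "", "GO:0000001", "IMP"),
               gline("shot", "NOT", "GO:0000001", "IDA"),
               gline("Msps", "", "GO:0000002", "ISS"),
               gline("Ncd", "", "GO:0000009", "IDA"),
               gline("Ncd", "", "GO:9999999", "IDA")), gaf)
  suppressMessages(ann <- parse_gaf(gaf, dag))
  expect_equal(nrow(ann), 2)
  expect_equal(ann$evidence[ann$protein == "Eb1"], "IDA|IMP")
  expect_equal(attr(ann, "n_dropped_not"), 1)
  expect_equal(attr(ann, "n_dropped_obsolete"), 1)
  expect_equal(attr(ann, "n_dropped_unknown"), 1)
})

test_that("protein ids are matched case-insensitively, first form kept", {
  dag <- chain_dag(c("GO:0000001", "GO:0000002"))
  gaf <- tempfile(fileext = ".gaf")
  gline <- function(prot, term) {
    paste("DB", prot, prot, "", term, "REF", "IDA", "", "P", "", "",
          "protein", "taxon:0", "20240101", "DB", "", "", sep = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               gline("Eb1", "GO:0000001"),
               gline("EB1", "GO:0000002")), gaf)
  ann <- parse_gaf(gaf, dag)
  expect_setequal(unique(ann$protein), "Eb1")
})

test_that("propagation adds ancestors, excludes roots, keeps direct", {
  dag <- chain_dag(c("GO:0000001", "GO:0000002", "GO:0000003"))
  ann <- direct_annots("p1", "GO:0000001")
  prop <- propagate_annotations(ann, dag)
  expect_equal(prop$term[prop$provenance == "inferred"], "GO:0000002")
  expect_false("GO:0000003" %in% prop$term)  # namespace root excluded

  # a direct record on an ancestor is not downgraded
  ann2 <- direct_annots(c("p1", "p1"), c("GO:0000001", "GO:0000002"))
  prop2 <- propagate_annotations(ann2, dag)
  expect_equal(prop2$provenance[prop2$term == "GO:0000002"], "direct")
})

test_that("propagation equals brute-force ancestor closure and is idempotent", {
  for (sd in 1:5) {
    dag <- make_ontology(depth = 3, branching = 3, n_cross_links = 6,
                         seed = sd)
    set.seed(sd)
    prots <- sprintf("p%02d", 1:20)
    live <- dag$terms$id[!dag$terms$obsolete]
    recs <- data.frame(protein = sample(prots, 40, replace = TRUE),
                       term = sample(live, 40, replace = TRUE),
                       provenance = "direct", stringsAsFactors = FALSE)
    ann <- annotation_set(recs)
    prop <- propagate_annotations(ann, dag)
    # oracle: per-record igraph reachability closure
    roots <- ontology_roots(dag)
    expected <- unique(do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
      anc <- setdiff(oracle_ancestors(dag, ann$term[i]), roots)
      rbind(data.frame(protein = ann$protein[i], term = ann$term[i]),
            if (length(anc)) data.frame(protein = ann$protein[i], term = anc))
    })))
    got <- unique(prop[, c("protein", "term")])
    expect_setequal(paste(got$protein, got$term),
                    paste(expected$protein, expected$term))
    # direct records preserved with provenance
    expect_true(all(paste(ann$protein, ann$term) %in%
                    paste(prop$protein[prop$provenance == "direct"],
                          prop$term[prop$provenance == "direct"])))
    # idempotence
    expect_identical(propagate_annotations(prop, dag), prop)
  }
})

test_that("annotated_proteins respects the true-path property", {
  dag <- make_ontology(depth = 2, branching = 3, seed = 1)
  set.seed(1)
  leaves <- setdiff(dag$terms$id, dag$parents$parent)
  ann <- propagate_annotations(
    direct_annots(sample(sprintf("p%02d", 1:15), 25, replace = TRUE),
                  sample(leaves, 25, replace = TRUE)), dag)
  for (i in seq_len(nrow(dag$parents))) {
    child <- dag$parents$child[i]; parent <- dag$parents$parent[i]
    if (parent %in% ontology_roots(dag)) next
    expect_true(all(annotated_proteins(ann, child) %in%
                    annotated_proteins(ann, parent)))
  }
  # direct-only result is a subset of direct-or-inferred
  t1 <- leaves[1]
  expect_true(all(annotated_proteins(ann, t1, include_inferred = FALSE) %in%
                  annotated_proteins(ann, t1)))
  expect_warning(res <- annotated_proteins(ann, "GO:7777777"), "no annotation")
  expect_length(res, 0)
})
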