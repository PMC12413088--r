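# annotate the given proteins directly to term "GO:0000100"
annot_to <- function(prots) direct_annots(prots, rep("GO:0000100", length(prots)))
QT <- "GO:0000100"

test_that("adjacent annotated node gives the single 1-edge path at k=1", {
  g <- mixed_graph(ppi = data.frame(source = c("S", "S"),
                                    target = c("A", "B")))
  res <- k_unique_paths(g, annot_to("A"), query_spec("S", QT, k = 1))
  expect_equal(res$paths, list(c("S", "A")))
  expect_equal(res$nodes$role[res$nodes$id == "S"], "source")
  expect_equal(res$nodes$role[res$nodes$id == "A"], "annotated")
})

test_that("k beyond the number of simple paths returns all, unpadded", {
  g <- mixed_graph(ppi = data.frame(source = c("S", "S", "A", "B"),
                                    target = c("A", "B", "T", "T")))
  res <- k_unique_paths(g, annot_to("T"), query_spec("S", QT, k = 50))
  adj <- traversal_view(g, "mixed")
  expect_equal(length(res$paths),
               length(oracle_simple_paths(adj, "S", "T")))
})

test_that("k_unique_paths equals exhaustive enumeration on random graphs", {
  n_checked <- 0
  for (sd in 1:25) {
    g <- random_mixed_graph(9, p_ppi = 0.2, p_reg = 0.1, seed = sd)
    set.seed(sd + 100)
    targets <- sample(g$nodes, 3)
    s <- sample(setdiff(g$nodes, targets), 1)
    ann <- annot_to(targets)
    for (filt in c("physical", "regulatory", "mixed")) {
      for (k in c(1, 4, 7)) {
        spec <- query_spec(s, QT, k = k, filter = filt)
        got <- k_unique_paths(g, ann, spec)$paths
        adj <- traversal_view(g, filt)
        want <- oracle_simple_paths(adj, s, targets)
        want <- want[seq_len(min(k, length(want)))]
        expect_identical(got, want)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 200)
})

test_that("k paths are prefix-stable as k grows", {
  g <- random_mixed_graph(10, seed = 7)
  ann <- annot_to(c("N01", "N05"))
  p3 <- k_unique_paths(g, ann, query_spec("N09", QT, k = 3))$paths
  p8 <- k_unique_paths(g, ann, query_spec("N09", QT, k = 8))$paths
  expect_identical(p8[seq_along(p3)], p3)
})

test_that("k_unique_nodes selects by distance with lexicographic ties", {
  g <- mixed_graph(ppi = data.frame(
    source = c("S", "S", "A", "B", "C"),
    target = c("A", "B", "C", "D", "E")))
  ann <- annot_to(c("A", "B", "E"))
  res1 <- k_unique_nodes(g, ann, query_spec("S", QT, k = 1,
                                            mode = "k_unique_nodes"))
  expect_equal(res1$paths, list(c("S", "A")))  # A before B on id ties
  res2 <- k_unique_nodes(g, ann, query_spec("S", QT, k = 2,
                                            mode = "k_unique_nodes"))
  expect_setequal(vapply(res2$paths, function(p) p[length(p)],
                         character(1)), c("A", "B"))
})

test_that("k_unique_nodes equals brute-force distance ranking", {
  for (sd in 1:20) {
    g <- random_mixed_graph(10, p_ppi = 0.22, p_reg = 0.12, seed = sd)
    set.seed(sd + 50)
    targets <- sample(g$nodes, 4)
    s <- sample(setdiff(g$nodes, targets), 1)
    ann <- annot_to(targets)
    for (filt in c("physical", "mixed")) {
      spec <- query_spec(s, QT, k = 2, mode = "k_unique_nodes",
                         filter = filt)
      res <- k_unique_nodes(g, ann, spec)
      d <- oracle_distances(g, filt, s)
      reach <- targets[is.finite(d[targets]) & targets != s]
      want <- reach[order(d[reach], reach, method = "radix")]
      want <- want[seq_len(min(2, length(want)))]
      got <- vapply(res$paths, function(p) p[length(p)], character(1))
      expect_setequal(got, want)
      # witness paths are shortest
      for (p in res$paths) {
        expect_equal(length(p) - 1, unname(d[p[length(p)]]))
      }
    }
  }
})

test_that("selected nodes are never farther than unselected ones", {
  g <- random_mixed_graph(12, seed = 3)
  targets <- c("N02", "N06", "N10", "N11")
  res <- k_unique_nodes(g, annot_to(targets),
                        query_spec("N01", QT, k = 2,
                                   mode = "k_unique_nodes"))
  d <- oracle_distances(g, "mixed", "N01")
  sel <- vapply(res$paths, function(p) p[length(p)], character(1))
  unsel <- setdiff(targets[is.finite(d[targets])], sel)
  if (length(unsel) > 0) {
    expect_lte(max(d[sel]), min(d[unsel]))
  }
})

test_that("a source annotated to the term is excluded from its targets", {
  g <- mixed_graph(ppi = data.frame(source = c("S", "A"),
                                    target = c("A", "B")))
  ann <- annot_to(c("S", "B"))  # Gdf6a-style: query protein in the term
  res <- k_unique_paths(g, ann, query_spec("S", QT, k = 5))
  terminals <- vapply(res$paths, function(p) p[length(p)], character(1))
  expect_false("S" %in% terminals)
  expect_true(all(terminals == "B"))
})

test_that("unreachable or absent targets give an empty, diagnosed result", {
  g <- mixed_graph(nodes = c("S", "X"),
                   ppi = data.frame(source = "A", target = "B"))
  expect_message(
    res <- k_unique_paths(g, annot_to("A"),
                          query_spec("S", QT, k = 3)),
    "reachable")
  expect_length(res$paths, 0)
  expect_error(k_unique_paths(g, annot_to("A"),
                              query_spec("ZZ", QT, k = 1)), "not in graph")
})

test_that("requery equals a fresh query from the new source", {
  for (sd in 1:10) {
    g <- random_mixed_graph(10, seed = sd)
    targets <- c("N03", "N07")
    ann <- annot_to(targets)
    spec <- query_spec("N01", QT, k = 4)
    res <- k_unique_paths(g, ann, spec)
    if (nrow(res$nodes) < 2) next
    new_s <- setdiff(res$nodes$id, "N01")[1]
    re <- requery(res, new_s, g, ann)
    spec2 <- spec; spec2$protein <- new_s
    expect_identical(re, k_unique_paths(g, ann, spec2))
    # idempotence on the same source
    expect_identical(requery(res, "N01", g, ann), res)
  }
  g <- random_mixed_graph(8, seed = 1)
  res <- k_unique_paths(g, annot_to("N03"), query_spec("N01", QT, k = 2))
  expect_error(requery(res, "N08", g, annot_to("N03")), "not in")
})

test_that("mixed traversal reaches at least what each single view reaches", {
  for (sd in 1:5) {
    g <- random_mixed_graph(12, seed = sd)
    dm <- oracle_distances(g, "mixed", "N01")
    dp <- oracle_distances(g, "physical", "N01")
    dr <- oracle_distances(g, "regulatory", "N01")
    expect_true(all(is.finite(dm[is.finite(dp)])))
    expect_true(all(is.finite(dm[is.finite(dr)])))
  }
})

test_that("result invariants hold: simplicity, sorting, set unions", {
  g <- random_mixed_graph(11, seed = 13)
  targets <- c("N02", "N08", "N11")
  res <- k_unique_paths(g, annot_to(targets),
                        query_spec("N04", QT, k = 10))
  for (p in res$paths) {
    expect_equal(anyDuplicated(p), 0)
    expect_equal(p[1], "N04")
    expect_true(p[length(p)] %in% targets)
  }
  expect_true(all(diff(lengths(res$paths)) >= 0))
  expect_setequal(res$nodes$id, unique(unlist(res$paths)))
})
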