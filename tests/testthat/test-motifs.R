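test_that("canonical triples classify to their motif class", {
  # pure physical triangle
  g1 <- mixed_graph(ppi = data.frame(source = c("A", "A", "B"),
                                     target = c("B", "C", "C")))
  expect_equal(classify_triple(g1, "A", "B", "C"), "protein_clique")
  # regulatory feed-forward loop
  g2 <- mixed_graph(reg = data.frame(source = c("A", "A", "B"),
                                     target = c("B", "C", "C")))
  expect_equal(classify_triple(g2, "A", "B", "C"), "feed_forward_loop")
  # the same loop with physically interacting TFs is a mixed feedback
  # loop, never a feed-forward loop
  g3 <- mixed_graph(ppi = data.frame(source = "A", target = "B"),
                    reg = data.frame(source = c("A", "A", "B"),
                                     target = c("B", "C", "C")))
  expect_equal(classify_triple(g3, "A", "B", "C"), "mixed_feedback_loop")
  # interacting coregulators: PPI pair regulating a shared target
  g4 <- mixed_graph(ppi = data.frame(source = "A", target = "B"),
                    reg = data.frame(source = c("A", "B"),
                                     target = c("C", "C")))
  expect_equal(classify_triple(g4, "A", "B", "C"),
               "interacting_coregulators")
  # coregulated interactors: one TF regulating a PPI pair
  g5 <- mixed_graph(ppi = data.frame(source = "B", target = "C"),
                    reg = data.frame(source = c("A", "A"),
                                     target = c("B", "C")))
  expect_equal(classify_triple(g5, "A", "B", "C"),
               "coregulated_interactors")
  expect_error(classify_triple(g1, "A", "A", "B"), "distinct")
})

test_that("classification matches the rule table on all 2^9 configurations", {
  ppi_grid <- expand.grid(p1 = c(FALSE, TRUE), p2 = c(FALSE, TRUE),
                          p3 = c(FALSE, TRUE))
  reg_grid <- expand.grid(r1 = c(FALSE, TRUE), r2 = c(FALSE, TRUE),
                          r3 = c(FALSE, TRUE), r4 = c(FALSE, TRUE),
                          r5 = c(FALSE, TRUE), r6 = c(FALSE, TRUE))
  n <- 0
  for (i in seq_len(nrow(ppi_grid))) {
    for (j in seq_len(nrow(reg_grid))) {
      pb <- unlist(ppi_grid[i, ]); rb <- unlist(reg_grid[j, ])
      g <- graph_from_bits(pb, rb)
      got <- classify_triple(g, "T1", "T2", "T3")
      want <- oracle_classify_bits(pb, rb)
      expect_identical(sort(got), sort(want))
      n <- n + 1
    }
  }
  expect_equal(n, 512)
})

test_that("classification is invariant under node relabeling", {
  set.seed(42)
  perms <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  for (rep in 1:30) {
    pb <- stats::runif(3) < 0.5
    rb <- stats::runif(6) < 0.4
    g <- graph_from_bits(pb, rb)
    base <- sort(classify_triple(g, "T1", "T2", "T3"))
    nodes <- c("T1", "T2", "T3")
    for (r in seq_len(nrow(perms))) {
      p <- nodes[perms[r, ]]
      expect_identical(sort(classify_triple(g, p[1], p[2], p[3])), base)
    }
  }
})

test_that("census equals brute-force triple enumeration on random graphs", {
  for (sd in 1:20) {
    g <- random_mixed_graph(sample(8:13, 1), p_ppi = 0.25, p_reg = 0.12,
                            seed = sd)
    expect_identical(motif_census(g), oracle_census(g))
    # and on an induced subset
    sub <- sort(sample(g$nodes, 7))
    expect_identical(motif_census(g, sub), oracle_census(g, sub))
  }
})

test_that("census counts cliques combinatorially and handles empties", {
  ids <- c("A", "B", "C", "D")
  pairs <- t(utils::combn(ids, 2))
  g <- mixed_graph(ppi = data.frame(source = pairs[, 1],
                                    target = pairs[, 2]))
  expect_equal(unname(motif_census(g)["protein_clique"]), 4L)  # C(4,3)
  g0 <- mixed_graph(nodes = ids)
  expect_true(all(motif_census(g0) == 0))
})

test_that("adding a physical edge never decreases the clique count", {
  g <- random_mixed_graph(9, seed = 5)
  base <- motif_census(g)["protein_clique"]
  # add one absent PPI edge
  all_pairs <- t(utils::combn(g$nodes, 2))
  have <- paste(g$ppi$a, g$ppi$b)
  free <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% have, ,
                    drop = FALSE]
  g2 <- mixed_graph(nodes = g$nodes,
                    ppi = rbind(data.frame(source = g$ppi$a,
                                           target = g$ppi$b),
                                data.frame(source = free[1, 1],
                                           target = free[1, 2])),
                    reg = g$reg)
  expect_gte(motif_census(g2)["protein_clique"], base)
})

test_that("background distribution normalizes over the five classes", {
  g <- mixed_graph(reg = data.frame(source = c("A", "A", "B"),
                                    target = c("B", "C", "C")))
  bg <- background_distribution(g)
  expect_equal(unname(bg$proportions["feed_forward_loop"]), 1)
  expect_equal(sum(bg$proportions), 1)
  fx <- plant_motifs(mixed_graph(nodes = sprintf("Q%02d", 1:30)),
                     "protein_clique", 5, seed = 2)
  bg2 <- background_distribution(fx$graph)
  expect_equal(unname(bg2$counts["protein_clique"]), 5L)
  expect_equal(sum(bg2$proportions), 1)
})

test_that("planted motifs are recovered exactly and exclusively", {
  classes <- weavenet:::MOTIF_CLASSES
  g <- mixed_graph(nodes = sprintf("Q%02d", 1:40))
  for (cls in classes) {
    g <- plant_motifs(g, cls, 1, seed = match(cls, classes))$graph
  }
  cen <- motif_census(g)
  expect_equal(unname(cen), rep(1L, 5))
  # planted mixed feedback loops are never miscounted as feed-forward
  g2 <- plant_motifs(mixed_graph(nodes = sprintf("R%02d", 1:12)),
                     "mixed_feedback_loop", 2, seed = 1)$graph
  cen2 <- motif_census(g2)
  expect_equal(unname(cen2["mixed_feedback_loop"]), 2L)
  expect_equal(unname(cen2["feed_forward_loop"]), 0L)
})

test_that("enrichment is calibrated against its own background", {
  g <- random_mixed_graph(18, p_ppi = 0.3, p_reg = 0.15, seed = 11)
  obs <- motif_census(g)
  rep <- motif_enrichment(obs, g, length(g$nodes), reps = 60, seed = 5)
  # the subnetwork IS the background: null draws equal the observation
  expect_true(all(abs(rep$z[!is.na(rep$z)]) < 1e-12))
  expect_true(all(rep$p >= 0 & rep$p <= 1))
  expect_equal(attr(rep, "reps"), 60)
})

test_that("degenerate null gives p = 1 and z = 0 for absent motifs", {
  g <- mixed_graph(ppi = data.frame(source = c("A", "B", "C", "D"),
                                    target = c("B", "C", "D", "E")))
  obs <- motif_census(g, c("A", "B", "C"))
  rep <- motif_enrichment(obs, g, 3, reps = 50, seed = 1)
  row <- rep[rep$class == "feed_forward_loop", ]
  expect_equal(row$observed, 0L)
  expect_equal(row$p, 1)
  expect_equal(row$z, 0)
})

test_that("a planted dense cluster is significantly enriched", {
  # sparse physical background plus one dense planted clique neighborhood
  set.seed(3)
  n <- 40
  ids <- sprintf("B%02d", 1:n)
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < 0.04
  clique <- ids[1:6]
  cl_pairs <- t(utils::combn(clique, 2))
  g <- mixed_graph(nodes = ids,
                   ppi = rbind(
                     data.frame(source = pairs[keep, 1],
                                target = pairs[keep, 2]),
                     data.frame(source = cl_pairs[, 1],
                                target = cl_pairs[, 2])))
  obs <- motif_census(g, clique)
  rep <- motif_enrichment(obs, g, length(clique), reps = 199, seed = 7)
  expect_lte(rep$p[rep$class == "protein_clique"], 0.05)
})
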