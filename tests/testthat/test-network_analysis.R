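path_net <- function(ids, layer = "protein") {
  nodes <- stats::setNames(rep(layer, length(ids)), ids)
  tripartite_network(nodes, cbind(ids[-length(ids)], ids[-1]))
}

test_that("a tiny ingredient-candidate fixture builds the expected network", {
  ings <- ingredient_set("i1", list("RP"), 40, 0.3)
  assoc <- data.frame(ingredient = "i1", gene = c("A", "B"),
                      evidence = "validated", similarity = NA_real_,
                      prediction_score = NA_real_, stringsAsFactors = FALSE)
  comp <- build_compendium(assoc, assoc[0, ], ings)
  ca <- map_candidates(comp, merge_disease_genes("A", list()))
  net <- build_network(ca, comp)
  expect_equal(length(net$nodes), 2)  # i1 and A; B is not a candidate
  expect_equal(nrow(net$edges), 1)
  expect_identical(unname(net$nodes[c("i1", "A")]),
                   c("ingredient", "candidate_target"))

  # duplicate association changes nothing (idempotence)
  comp2 <- build_compendium(rbind(assoc, assoc[1, ]), assoc[0, ], ings)
  net2 <- build_network(ca, comp2)
  expect_identical(net2$edges, net$edges)
})

test_that("network construction equals brute force on random fixtures", {
  set.seed(43)
  for (rep in 1:15) {
    n_ing <- sample(3:6, 1)
    ings <- ingredient_set(sprintf("i%d", 1:n_ing),
                           as.list(rep("RP", n_ing)), 40, 0.3)
    assoc <- unique(data.frame(
      ingredient = sample(ings$ingredient, 30, TRUE),
      gene = sprintf("G%02d", sample(15, 30, TRUE)),
      stringsAsFactors = FALSE))
    assoc$evidence <- "validated"
    assoc$similarity <- NA_real_; assoc$prediction_score <- NA_real_
    comp <- build_compendium(assoc, assoc[0, ], ings)
    dis <- sprintf("G%02d", sample(15, 8))
    ca <- suppressWarnings(map_candidates(comp, merge_disease_genes(dis, list())))
    ppi_a <- sprintf("G%02d", sample(15, 20, TRUE))
    ppi_b <- sprintf("P%02d", sample(10, 20, TRUE))
    edges <- make_edge_set(ppi_a, ppi_b, runif(20, 0.85, 1))
    ca <- expand_interactors(ca, edges)
    net <- build_network(ca, comp)

    brute_edges <- unique(rbind(
      t(apply(as.matrix(assoc[assoc$gene %in% ca$candidates,
                              c("ingredient", "gene")]), 1,
              function(r) sort(r))),
      t(apply(as.matrix(ca$kept_edges[, c("a", "b")]), 1, sort))))
    got <- unname(apply(net$edges, 1, paste, collapse = "|"))
    want <- unname(apply(brute_edges, 1, paste, collapse = "|"))
    expect_setequal(got, want)
    # handshake lemma on every constructed network
    expect_equal(sum(node_degrees(net)), 2 * nrow(net$edges))
  }
})

test_that("degree statistics: triangle, star and the 2E/N identity", {
  tri <- tripartite_network(
    c(A = "protein", B = "protein", C = "protein"),
    rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  st <- network_stats(tri)
  expect_equal(unname(st$degrees), c(2L, 2L, 2L))
  expect_equal(st$mean_degree, 2)
  expect_equal(st$key_threshold, 4)

  star5 <- tripartite_network(
    stats::setNames(rep("protein", 6), c("hub", paste0("l", 1:5))),
    cbind("hub", paste0("l", 1:5)))
  st5 <- network_stats(star5)
  expect_equal(sort(unname(st5$degrees), decreasing = TRUE),
               c(5L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(st5$mean_degree, 10 / 6)

  set.seed(47)
  ids <- sprintf("n%02d", 1:20)
  pairs <- t(utils::combn(ids, 2))
  pairs <- pairs[runif(nrow(pairs)) < 0.2, ]
  er <- tripartite_network(stats::setNames(rep("protein", 20), ids), pairs)
  ster <- network_stats(er)
  expect_equal(ster$mean_degree, 2 * ster$n_edges / ster$n_nodes)
})

test_that("key selection: cycles have none, star K1,9 selects the center", {
  cyc_ids <- paste0("c", 1:8)
  cyc <- tripartite_network(
    stats::setNames(rep("protein", 8), cyc_ids),
    cbind(cyc_ids, cyc_ids[c(2:8, 1)]))
  keys <- select_key_nodes(cyc)
  expect_length(unlist(keys), 0)

  star9 <- tripartite_network(
    stats::setNames(c("ingredient", rep("candidate_target", 9)),
                    c("hub", paste0("t", 1:9))),
    cbind("hub", paste0("t", 1:9)))
  st <- network_stats(star9)
  expect_equal(st$key_threshold, 2 * 18 / 10)
  keys <- select_key_nodes(star9, st)
  expect_identical(keys$key_ingredients, "hub")
  expect_length(keys$key_targets_pooled, 0)
})

test_that("key-node selection is invariant under relabeling and edge order", {
  set.seed(53)
  ids <- sprintf("x%02d", 1:15)
  pairs <- t(utils::combn(ids, 2))
  pairs <- pairs[runif(nrow(pairs)) < 0.3, ]
  net <- tripartite_network(stats::setNames(rep("protein", 15), ids), pairs)
  keys <- select_key_nodes(net)

  relabel <- stats::setNames(sprintf("y%02d", sample(15)), ids)
  perm <- sample(nrow(pairs))
  net2 <- tripartite_network(
    stats::setNames(rep("protein", 15), unname(relabel[ids])),
    cbind(unname(relabel[pairs[perm, 1]]), unname(relabel[pairs[perm, 2]])))
  keys2 <- select_key_nodes(net2)
  expect_setequal(unname(relabel[keys$key_proteins]), keys2$key_proteins)
})

test_that("planted hub ingredients are recovered across seeded runs", {
  hits <- vapply(1:25, function(s) {
    run <- run_synthetic_study(small_params(), seed = s, enrich = FALSE)
    all(run$ground_truth$planted_hub_ingredients %in%
        run$keys$key_ingredients)
  }, logical(1))
  expect_true(all(hits))
})
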