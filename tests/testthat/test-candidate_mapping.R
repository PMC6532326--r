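make_comp <- function(universe, validated_genes = character()) {
  ings <- ingredient_set("i1", list("RP"), 40, 0.3)
  mk <- function(genes, ev) if (length(genes) == 0) NULL else
    data.frame(ingredient = "i1", gene = genes, evidence = ev,
               similarity = NA_real_, prediction_score = NA_real_,
               stringsAsFactors = FALSE)
  empty <- data.frame(ingredient = character(), gene = character(),
                      evidence = character(), similarity = numeric(),
                      prediction_score = numeric(), stringsAsFactors = FALSE)
  v <- mk(validated_genes, "validated")
  p <- mk(setdiff(universe, validated_genes), "predicted")
  build_compendium(if (is.null(v)) empty else v,
                   if (is.null(p)) empty else p, ings)
}

make_dset <- function(genes) merge_disease_genes(genes, list())

test_that("candidate mapping is the set intersection with evidence classes", {
  comp <- make_comp(c("A", "B", "C"), validated_genes = "B")
  d <- make_dset(c("B", "C", "D"))
  ca <- map_candidates(comp, d)
  expect_identical(ca$candidates, c("B", "C"))
  expect_identical(unname(ca$evidence_of), c("validated", "predicted"))
  # every candidate is classified, and the two classes partition the set
  expect_equal(sum(ca$evidence_of == "validated") +
               sum(ca$evidence_of == "predicted"), length(ca$candidates))

  expect_warning(map_candidates(comp, make_dset("ZZZ")), "no overlap")
})

test_that("mapping equals brute force and is symmetric on random fixtures", {
  set.seed(37)
  for (rep in 1:20) {
    uni <- sprintf("G%02d", sample(40, sample(5:25, 1)))
    dis <- sprintf("G%02d", sample(40, sample(5:25, 1)))
    comp <- make_comp(uni)
    ca <- suppressWarnings(map_candidates(comp, make_dset(dis)))
    expect_identical(ca$candidates, sort(intersect(unique(uni), unique(dis))))
  }
})

test_that("interactor expansion keeps strict >0.9 edges touching candidates", {
  comp <- make_comp(c("AKT1", "TP53"))
  ca <- map_candidates(comp, make_dset("AKT1"))
  edges <- make_edge_set(c("AKT1", "AKT1", "MDM2"),
                         c("TP53", "EGFR", "EGFR"),
                         c(0.95, 0.90, 0.99))
  out <- expand_interactors(ca, edges)
  # 0.90 is dropped (strict >); TP53 becomes an interactor; the
  # MDM2-EGFR edge has no candidate endpoint and EGFR never enters
  expect_identical(out$interactors, "TP53")
  expect_equal(nrow(out$kept_edges), 1)
  expect_true(all(out$kept_edges$score > 0.9))
  expect_length(intersect(out$interactors, out$candidates), 0)
})

test_that("interactor-interactor edges follow the configuration flag", {
  comp <- make_comp("A")
  ca <- map_candidates(comp, make_dset("A"))
  edges <- make_edge_set(c("A", "A", "X"), c("X", "Y", "Y"),
                         c(0.95, 0.95, 0.95))
  with_ii <- expand_interactors(ca, edges, include_interactor_interactor = TRUE)
  without <- expand_interactors(ca, edges, include_interactor_interactor = FALSE)
  expect_equal(nrow(with_ii$kept_edges), 3)
  expect_equal(nrow(without$kept_edges), 2)
  expect_identical(with_ii$interactors, without$interactors)
})

test_that("expansion matches brute force and is monotone in score_min", {
  set.seed(41)
  for (rep in 1:10) {
    nodes <- sprintf("N%02d", 1:30)
    n_e <- 200
    a <- sample(nodes, n_e, TRUE); b <- sample(nodes, n_e, TRUE)
    ok <- a != b
    edges <- make_edge_set(a[ok], b[ok], runif(sum(ok)))
    cands_genes <- sample(nodes, 6)
    comp <- make_comp(cands_genes)
    ca <- map_candidates(comp, make_dset(cands_genes))
    out <- expand_interactors(ca, edges, 0.9)
    brute_keep <- edges[edges$score > 0.9 &
                        (edges$a %in% cands_genes | edges$b %in% cands_genes), ]
    brute_int <- sort(setdiff(c(brute_keep$a, brute_keep$b), cands_genes))
    expect_identical(out$interactors, brute_int)

    lower <- expand_interactors(ca, edges, 0.7)
    expect_true(all(out$interactors %in% lower$interactors))
    expect_lte(nrow(out$kept_edges), nrow(lower$kept_edges))
  }
})

test_that("score_min of 1.0 leaves no interactors; bad scores error", {
  comp <- make_comp("A")
  ca <- map_candidates(comp, make_dset("A"))
  edges <- make_edge_set("A", "B", 1.0)
  out <- expand_interactors(ca, edges, score_min = 1.0)
  expect_length(out$interactors, 0)
  bad <- data.frame(a = "A", b = "B", score = 1.7)
  expect_error(expand_interactors(ca, bad), "score")
})
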