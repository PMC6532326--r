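gsc <- function(...) {
  terms <- list(...)
  structure(terms, class = "gene_set_collection")
}
term <- function(genes, name = "t", category = "kegg")
  list(name = name, category = category, genes = genes)

test_that("hypergeometric p matches the closed form for a full-overlap draw", {
  bg <- sprintf("G%02d", 1:20)
  sets <- gsc(T1 = term(bg[1:5]))
  rows <- hypergeom_enrich(bg[1:5], sets, bg)
  # all 5 query genes inside a 5-gene term: p = 1/C(20,5)
  expect_equal(rows$p, 1 / choose(20, 5), tolerance = 1e-12)
})

test_that("hypergeometric p equals exhaustive enumeration on small draws", {
  bg <- sprintf("G%02d", 1:10)
  K <- 5
  sets <- gsc(T1 = term(bg[seq_len(K)]))
  for (n in c(2, 4, 5, 7)) {
    query <- bg[c(seq_len(ceiling(n / 2)), 10 - seq_len(floor(n / 2)) + 1)]
    query <- unique(query)[seq_len(n)]
    k <- length(intersect(query, bg[seq_len(K)]))
    if (k == 0) next
    rows <- hypergeom_enrich(query, sets, bg)
    expect_equal(rows$p, enum_hyper_p(10, K, n, k), tolerance = 1e-12)
  }
})

test_that("terms with no query hit are omitted; contract errors raised", {
  bg <- sprintf("G%02d", 1:12)
  sets <- gsc(HIT = term(bg[1:4]), MISS = term(bg[9:12]))
  rows <- hypergeom_enrich(bg[1:3], sets, bg)
  expect_identical(rows$term_id, "HIT")
  expect_error(hypergeom_enrich(character(), sets, bg), "nonempty")
  expect_error(hypergeom_enrich("NOT_IN_BG", sets, bg), "background")
})

test_that("BH adjustment is per category, monotone in p-rank, and <= 1", {
  bg <- sprintf("G%02d", 1:30)
  sets <- gsc(K1 = term(bg[1:6]), K2 = term(bg[c(1, 10:14)]),
              M1 = term(bg[1:6], category = "molecular_function"))
  rows <- hypergeom_enrich(bg[1:6], sets, bg)
  expect_true(all(rows$q >= rows$p - 1e-15))
  expect_true(all(rows$q <= 1))
  for (cat in unique(rows$category)) {
    rr <- rows[rows$category == cat, ]
    expect_equal(rr$q, stats::p.adjust(rr$p, "BH"))
    expect_false(is.unsorted(rr$q[order(rr$p)]))
  }
})

test_that("enrichment p is invariant to genes outside the background", {
  bg <- sprintf("G%02d", 1:15)
  sets <- gsc(T1 = term(c(bg[1:5], "ALIEN1", "ALIEN2")))
  with_alien <- hypergeom_enrich(bg[1:4], sets, bg)
  sets2 <- gsc(T1 = term(bg[1:5]))
  without <- hypergeom_enrich(bg[1:4], sets2, bg)
  expect_equal(with_alien$p, without$p)
  expect_equal(with_alien$K, without$K)
})

test_that("Cohen's kappa matches hand-computed 2x2-table values", {
  # x=(1,1,0,0), y=(1,0,1,0): po=0.5, pe=0.5 -> kappa 0
  expect_equal(cohen_kappa(c(TRUE, TRUE, FALSE, FALSE),
                           c(TRUE, FALSE, TRUE, FALSE)), 0)
  # x=(1,1,1,0), y=(1,1,0,0): po=0.75, pe=0.5 -> kappa 0.5
  expect_equal(cohen_kappa(c(TRUE, TRUE, TRUE, FALSE),
                           c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(cohen_kappa(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
  # disjoint memberships agree less than chance
  expect_lte(cohen_kappa(c(TRUE, TRUE, FALSE, FALSE),
                         c(FALSE, FALSE, TRUE, TRUE)), 0)
})

test_that("kappa grouping links identical terms and separates disjoint ones", {
  bg <- sprintf("G%02d", 1:20)
  sets <- gsc(A1 = term(bg[1:5]), A2 = term(bg[1:5]), B1 = term(bg[10:14]))
  query <- bg[c(1:3, 10:12)]
  rows <- hypergeom_enrich(query, sets, bg)
  grouped <- kappa_group(rows, sets, query)
  gid <- stats::setNames(grouped$group_id, grouped$term_id)
  expect_identical(gid[["A1"]], gid[["A2"]])
  expect_false(gid[["B1"]] == gid[["A1"]])
  # unique group shares sum to 1 within the category
  expect_equal(sum(grouped$group_share[!duplicated(grouped$group_id)]), 1)
  expect_equal(grouped$group_share[grouped$term_id == "A1"], 2 / 3)
  expect_equal(grouped$group_share[grouped$term_id == "B1"], 1 / 3)
})

test_that("category summaries name groups by lowest-p term, shares sum to 100", {
  bg <- sprintf("G%02d", 1:24)
  sets <- gsc(STRONG = term(bg[1:6], name = "strong path"),
              WEAK = term(bg[c(1:2, 20:23)], name = "weak path"),
              TWIN = term(bg[1:6], name = "strong twin"))
  query <- bg[1:6]
  rows <- hypergeom_enrich(query, sets, bg)
  grouped <- kappa_group(rows, sets, query)
  s <- summarize_categories(grouped)
  expect_equal(sum(s$share_pct[s$category == "kegg"]), 100)
  # the leading term of the strong group is the lowest-p member
  lead <- s$group_name[which.max(s$n_terms)]
  expect_true(lead %in% c("strong path", "strong twin"))
  expect_equal(s$min_p[which.max(s$n_terms)], min(rows$p))

  expect_warning(empty <- summarize_categories(grouped[0, ]), "no significant")
  expect_equal(nrow(empty), 0)

  single <- summarize_categories(kappa_group(rows[1, ], sets, query))
  expect_equal(single$share_pct, 100)
})

test_that("a planted over-sampled pathway attains the minimum p across seeds", {
  wins <- vapply(1:20, function(s) {
    run <- run_synthetic_study(small_params(), seed = s, enrich = TRUE)
    rows <- run$enrichment
    if (is.null(rows) || nrow(rows) == 0) return(NA)
    kegg <- rows[rows$category == "kegg", ]
    length(kegg$term_id) > 0 && kegg$term_id[which.min(kegg$p)] == "PATH001"
  }, logical(1))
  expect_gte(mean(wins, na.rm = TRUE), 0.9)
})
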