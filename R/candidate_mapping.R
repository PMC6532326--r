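#' Map candidate targets: ingredient targets intersected with disease genes
#'
#' A candidate target is a gene both reachable from the formula's
#' ingredients (present in the compendium's target universe) and associated
#' with the disease. Each candidate carries an evidence class: `validated`
#' if any validated association reaches it, else `predicted`.
#' An empty intersection is a warning, not a failure.
#'
#' @param c A `compendium`.
#' @param d A `disease_gene_set`.
#' @return A `candidate_set`: list with `candidates` (sorted symbols),
#'   `evidence_of` (named character vector), `interactors` (empty until
#'   [expand_interactors()]), `kept_edges` (empty edge data frame).
#' @export
map_candidates <- function(c, d) {
  cands <- sort(intersect(c$target_universe, d$genes))
  if (length(cands) == 0)
    warning("no overlap between ingredient targets and disease genes")
  structure(list(
    candidates = cands,
    evidence_of = c$gene_evidence[cands],
    interactors = character(),
    kept_edges = data.frame(a = character(), b = character(),
                            score = numeric(), stringsAsFactors = FALSE)
  ), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", length(x$candidates), "candidates (",
      sum(x$evidence_of == "validated"), "validated,",
      sum(x$evidence_of == "predicted"), "predicted ),",
      length(x$interactors), "interactors,",
      nrow(x$kept_edges), "kept edges\n")
  invisible(x)
}

#' Expand a candidate set with high-confidence interacting proteins
#'
#' Keeps PPI edges whose combined confidence score strictly exceeds
#' `score_min` and which touch at least one candidate; the non-candidate
#' endpoints of kept edges become the interactor set. With
#' `include_interactor_interactor = TRUE` (default, matching neighborhood
#' exports of STITCH/STRING-style services) above-threshold edges between
#' two interactors are also retained once both endpoints are in the network.
#'
#' @param cands A `candidate_set` from [map_candidates()].
#' @param edges Canonical scored edge data frame ([make_edge_set()] /
#'   [read_edge_table()]).
#' @param score_min Strict lower bound on the confidence score (default 0.9).
#' @param include_interactor_interactor Retain interactor-interactor edges
#'   (default TRUE).
#' @return The `candidate_set` with `interactors` and `kept_edges` filled.
#' @export
expand_interactors <- function(cands, edges, score_min = 0.9,
                               include_interactor_interactor = TRUE) {
  if (any(edges$score < 0 | edges$score > 1))
    stop("edge score outside [0,1]")
  hi <- edges[edges$score > score_min, , drop = FALSE]
  touch <- hi$a %in% cands$candidates | hi$b %in% cands$candidates
  kept <- hi[touch, , drop = FALSE]
  interactors <- sort(setdiff(c(kept$a, kept$b), cands$candidates))
  if (include_interactor_interactor) {
    both_int <- hi$a %in% interactors & hi$b %in% interactors
    kept <- rbind(kept, hi[both_int, , drop = FALSE])
    kept <- kept[order(kept$a, kept$b), , drop = FALSE]
  }
  rownames(kept) <- NULL
  cands$interactors <- interactors
  cands$kept_edges <- kept
  cands
}
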