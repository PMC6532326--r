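#' Filter predicted target associations by similarity and prediction score
#'
#' Predicted ingredient-target associations (3D-similarity based) are kept
#' only when `similarity > sim_min` and `prediction_score > score_min`, both
#' strict. Validated associations pass through untouched. Note the
#' similarity score of the upstream predictor can exceed 1, so a strict
#' lower bound of 1.0 is meaningful.
#'
#' @param assocs Association data frame as from [read_target_table()].
#' @param sim_min Strict lower bound on 3D structure similarity (default 1.0).
#' @param score_min Strict lower bound on prediction score (default 0).
#' @return The filtered association data frame.
#' @export
filter_predicted <- function(assocs, sim_min = 1.0, score_min = 0) {
  pred <- assocs$evidence == "predicted"
  if (any(pred & (is.na(assocs$similarity) | is.na(assocs$prediction_score))))
    stop("predicted association with missing similarity or prediction_score")
  keep <- !pred | (assocs$similarity > sim_min & assocs$prediction_score > score_min)
  out <- assocs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the ingredient-target compendium
#'
#' Deduplicates associations on (ingredient, gene); when the same pair is
#' reached by both evidence routes the validated association wins
#' (literature-curated evidence trumps structure-based prediction). Derives
#' the target universe, per-ingredient target sets, and the gene -> herbs
#' map obtained by composing gene -> ingredients -> herbs.
#'
#' @param validated,predicted_kept Association data frames (the predicted
#'   one already filtered by [filter_predicted()]).
#' @param ingredients An `ingredient_set` covering every association's
#'   ingredient.
#' @return A `compendium`: list with `associations` (ingredient, gene,
#'   evidence), `target_universe`, `per_ingredient` (named list of gene
#'   sets), `per_gene_herbs` (named list of herb sets), and `n_validated` /
#'   `n_predicted` gene counts by best evidence.
#' @export
build_compendium <- function(validated, predicted_kept, ingredients) {
  assoc <- rbind(
    validated[, c("ingredient", "gene", "evidence"), drop = FALSE],
    predicted_kept[, c("ingredient", "gene", "evidence"), drop = FALSE]
  )
  orphans <- setdiff(assoc$ingredient, ingredients$ingredient)
  if (length(orphans))
    stop("association(s) reference unknown ingredient(s): ",
         paste(utils::head(orphans, 5), collapse = ", "))
  if (nrow(assoc) > 0) {
    # validated first so duplicated() drops the predicted copy of a pair
    assoc <- assoc[order(assoc$evidence != "validated"), , drop = FALSE]
    assoc <- assoc[!duplicated(assoc[, c("ingredient", "gene")]), , drop = FALSE]
    assoc <- assoc[order(assoc$ingredient, assoc$gene), , drop = FALSE]
    rownames(assoc) <- NULL
  }
  universe <- sort(unique(assoc$gene))
  per_ingredient <- lapply(split(assoc$gene, assoc$ingredient), function(g)
    sort(unique(g)))
  herb_of <- stats::setNames(ingredients$herbs, ingredients$ingredient)
  per_gene_herbs <- lapply(split(assoc$ingredient, assoc$gene), function(ings)
    sort(unique(unlist(herb_of[unique(ings)]))))
  best <- tapply(assoc$evidence, assoc$gene,
                 function(e) if ("validated" %in% e) "validated" else "predicted")
  structure(list(
    associations = assoc,
    target_universe = universe,
    per_ingredient = per_ingredient,
    per_gene_herbs = per_gene_herbs,
    gene_evidence = stats::setNames(as.character(best), names(best)),
    n_validated = sum(best == "validated"),
    n_predicted = sum(best == "predicted"),
    ingredients = ingredients
  ), class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat("compendium:", nrow(x$associations), "associations,",
      length(x$target_universe), "targets (", x$n_validated, "validated,",
      x$n_predicted, "predicted ) across",
      length(x$per_ingredient), "ingredients\n")
  invisible(x)
}

#' Per-ingredient target coverage statistics
#'
#' For each ingredient, its number of targets and the percentage of the
#' whole target universe it covers, `100 * n_targets / |universe|`, rounded
#' to one decimal. Sorted by target count descending, ties broken by name.
#'
#' @param c A `compendium`.
#' @return Data frame with columns ingredient, n_targets, pct_of_universe.
#' @export
coverage_stats <- function(c) {
  if (length(c$target_universe) == 0) stop("empty compendium")
  n <- vapply(c$per_ingredient, length, integer(1))
  out <- data.frame(ingredient = names(n), n_targets = as.integer(n),
                    pct_of_universe = round(100 * n / length(c$target_universe), 1),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targets, out$ingredient), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bucket targets by the number of herbs reaching them
#'
#' A gene hit (via any ingredient) by k distinct herbs is assigned to bucket
#' k; only buckets with `k >= min_herbs` are returned. This is the
#' "common targets of at least n herbs" view of a multi-herb formula.
#'
#' @param c A `compendium`.
#' @param min_herbs Smallest herb count to report (>= 1).
#' @return Named list: bucket herb-count (as character) -> sorted gene set.
#' @export
common_targets_by_herb_count <- function(c, min_herbs = 1) {
  stopifnot(min_herbs >= 1)
  counts <- vapply(c$per_gene_herbs, length, integer(1))
  keep <- counts >= min_herbs
  buckets <- split(names(counts)[keep], counts[keep])
  lapply(buckets, sort)
}
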