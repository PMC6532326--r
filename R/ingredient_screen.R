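#' ADME screening of ingredients
#'
#' Keeps ingredients whose oral bioavailability (OB, percent) and
#' drug-likeness (DL) pass the screening thresholds. With
#' `inclusive = TRUE` (the default) the comparison is `>=`; with
#' `inclusive = FALSE` it is strict `>`. Screening is applied only to
#' records that carry ADME scores (TCMSP exports); curated sources without
#' scores should bypass this step.
#'
#' @param records An `ingredient_set`; every record must have non-missing
#'   ob and dl.
#' @param ob_min Minimum oral bioavailability in percent (default 30).
#' @param dl_min Minimum drug-likeness (default 0.18).
#' @param inclusive Use `>=` (TRUE, default) or strict `>` (FALSE).
#' @return The kept `ingredient_set`, input order preserved.
#' @export
#' @examples
#' s <- ingredient_set(c("a", "b"), list("RP", "RP"), ob = c(40, 10),
#'                     dl = c(0.3, 0.3))
#' screen_tcmsp(s)$ingredient
screen_tcmsp <- function(records, ob_min = 30, dl_min = 0.18, inclusive = TRUE) {
  stopifnot(ob_min >= 0, dl_min >= 0, dl_min <= 1)
  missing_scores <- is.na(records$ob) | is.na(records$dl)
  if (any(missing_scores))
    stop("ingredient(s) without ADME scores cannot be screened: ",
         paste(records$ingredient[missing_scores], collapse = ", "))
  keep <- if (inclusive)
    records$ob >= ob_min & records$dl >= dl_min
  else
    records$ob > ob_min & records$dl > dl_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge ingredient sets from two knowledge sources
#'
#' Union keyed by canonical ingredient name. Herb memberships are unioned;
#' an ingredient present in both inputs gets `source = "both"`; ADME scores
#' are taken from whichever record carries them (first input wins when both
#' do). The operation is commutative up to row order and idempotent.
#'
#' @param x,y `ingredient_set` objects (e.g. screened TCMSP and HIT).
#' @return Merged `ingredient_set`, sorted by ingredient name.
#' @export
merge_sources <- function(x, y) {
  all_ids <- sort(unique(c(x$ingredient, y$ingredient)))
  ix <- match(all_ids, x$ingredient)
  iy <- match(all_ids, y$ingredient)
  pick <- function(a, b) ifelse(is.na(a), b, a)
  src <- character(length(all_ids))
  for (k in seq_along(all_ids)) {
    sx <- if (!is.na(ix[k])) x$source[ix[k]] else NULL
    sy <- if (!is.na(iy[k])) y$source[iy[k]] else NULL
    s <- unique(c(sx, sy,
                  if (!is.null(sx) && !is.null(sy)) "both"))
    src[k] <- if ("both" %in% s || all(c("tcmsp", "hit") %in% s)) "both" else s[1]
  }
  ingredient_set(
    ingredient = all_ids,
    herbs = lapply(seq_along(all_ids), function(k)
      c(if (!is.na(ix[k])) x$herbs[[ix[k]]],
        if (!is.na(iy[k])) y$herbs[[iy[k]]])),
    ob = pick(ifelse(is.na(ix), NA, x$ob[ix]),
              ifelse(is.na(iy), NA, y$ob[iy])),
    dl = pick(ifelse(is.na(ix), NA, x$dl[ix]),
              ifelse(is.na(iy), NA, y$dl[iy])),
    source = src
  )
}

#' Herb-overlap table of merged ingredients
#'
#' One row per ingredient with its herb count and the herb codes, sorted by
#' herb count descending then ingredient name. With `overlap_only = TRUE`
#' (default) only ingredients shared by at least two herbs appear, matching
#' the usual presentation of multi-herb formulas.
#'
#' @param merged A merged `ingredient_set`.
#' @param overlap_only Drop single-herb ingredients (default TRUE).
#' @return Data frame with columns ingredient, herb_count, herbs
#'   (comma-joined codes).
#' @export
herb_overlap_table <- function(merged, overlap_only = TRUE) {
  counts <- lengths(merged$herbs)
  out <- data.frame(
    ingredient = merged$ingredient,
    herb_count = as.integer(counts),
    herbs = vapply(merged$herbs, paste, "", collapse = ", "),
    stringsAsFactors = FALSE
  )
  if (overlap_only) out <- out[out$herb_count >= 2, , drop = FALSE]
  out <- out[order(-out$herb_count, out$ingredient), , drop = FALSE]
  rownames(out) <- NULL
  out
}
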