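#' Hypergeometric over-representation analysis
#'
#' Tests each annotated gene set for over-representation in a query set
#' against a background universe. With N background genes, K of them in the
#' term, and a query of size n hitting k term genes, the p-value is the
#' hypergeometric upper tail P\[X >= k\]. Terms are intersected with the
#' background before testing; terms with k = 0 are omitted.
#' Benjamini-Hochberg adjustment is applied within each category
#' separately (pathways and molecular functions are distinct term systems).
#'
#' @param query Character vector of query genes (must lie in `background`).
#' @param sets A `gene_set_collection`.
#' @param background Character vector, the gene universe.
#' @return Data frame of enrichment rows: term_id, name, category, k, K, n,
#'   N, p, q; sorted by p ascending. Columns group_id/group_share are added
#'   by [kappa_group()].
#' @export
hypergeom_enrich <- function(query, sets, background) {
  query <- unique(canon_gene(query))
  background <- unique(canon_gene(background))
  if (length(query) == 0 || length(background) == 0)
    stop("query and background must be nonempty")
  stray <- setdiff(query, background)
  if (length(stray))
    stop("query gene(s) outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    term_genes <- intersect(canon_gene(sets[[id]]$genes), background)
    K <- length(term_genes)
    k <- length(intersect(term_genes, query))
    if (k == 0) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, name = sets[[id]]$name,
               category = sets[[id]]$category,
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), name = character(),
                      category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  out$q <- stats::ave(out$p, out$category,
                      FUN = function(p) stats::p.adjust(p, "BH"))
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two binary membership vectors
#'
#' Agreement beyond chance between two gene memberships over a common gene
#' panel. Identical vectors give kappa 1 (including the degenerate
#' all-in/all-out cases, where chance agreement is 1 by construction).
#'
#' @param x,y Logical vectors of equal length.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (identical(as.logical(x), as.logical(y))) return(1)
  n <- length(x)
  po <- mean(x == y)
  pe <- mean(x) * mean(y) + mean(!x) * mean(!y)
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Group enriched terms by kappa similarity of their gene memberships
#'
#' ClueGO-convention term grouping: each significant term is represented by
#' its binary membership vector over the union of query-hit genes; terms
#' with pairwise kappa >= `kappa_min` are linked and groups are the
#' connected components. Each group is labelled by its lowest-p
#' ("leading") term and `group_share` is the group's fraction of all
#' significant terms within its category.
#'
#' @param rows Significant enrichment rows (subset of [hypergeom_enrich()]
#'   output).
#' @param sets The `gene_set_collection` the rows were tested against.
#' @param query The query gene set used for the enrichment.
#' @param kappa_min Linking threshold on pairwise kappa (default 0.4,
#'   inclusive).
#' @return `rows` with columns group_id (leading term of the group) and
#'   group_share added; grouping is within category.
#' @export
kappa_group <- function(rows, sets, query, kappa_min = 0.4) {
  stopifnot(nrow(rows) >= 1)
  query <- unique(canon_gene(query))
  out <- rows
  out$group_id <- NA_character_
  out$group_share <- NA_real_
  for (cat in unique(rows$category)) {
    idx <- which(rows$category == cat)
    ids <- rows$term_id[idx]
    hit_genes <- sort(unique(unlist(lapply(ids, function(id)
      intersect(canon_gene(sets[[id]]$genes), query)))))
    memb <- vapply(ids, function(id) hit_genes %in% canon_gene(sets[[id]]$genes),
                   logical(length(hit_genes)))
    memb <- matrix(memb, nrow = length(hit_genes),
                   dimnames = list(hit_genes, ids))
    m <- length(ids)
    adj <- diag(TRUE, m)
    if (m > 1) {
      for (i in seq_len(m - 1)) for (j in (i + 1):m)
        adj[i, j] <- adj[j, i] <- cohen_kappa(memb[, i], memb[, j]) >= kappa_min
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    for (gid in unique(comp)) {
      members <- idx[comp == gid]
      lead <- members[which.min(rows$p[members])]
      out$group_id[members] <- rows$term_id[lead]
      out$group_share[members] <- length(members) / m
    }
  }
  out
}

#' Summarize grouped enrichment results per category
#'
#' One row per (category, group): the group label (name of its lowest-p
#' term), member count, member term ids, and the group's percentage share
#' of the category's significant terms. Shares sum to 100 within each
#' category. An empty input yields an empty summary with a warning.
#'
#' @param rows Grouped enrichment rows from [kappa_group()].
#' @return Data frame (category, group_id, group_name, n_terms, share_pct,
#'   members, min_p), sorted by category then share descending.
#' @export
summarize_categories <- function(rows) {
  if (nrow(rows) == 0) {
    warning("no significant terms to summarize")
    return(data.frame(category = character(), group_id = character(),
                      group_name = character(), n_terms = integer(),
                      share_pct = numeric(), members = character(),
                      min_p = numeric(), stringsAsFactors = FALSE))
  }
  key <- interaction(rows$category, rows$group_id, drop = TRUE)
  parts <- split(seq_len(nrow(rows)), key)
  out <- do.call(rbind, lapply(parts, function(i) {
    lead <- i[which.min(rows$p[i])]
    data.frame(category = rows$category[lead],
               group_id = rows$group_id[lead],
               group_name = rows$name[lead],
               n_terms = length(i),
               share_pct = 100 * rows$group_share[lead],
               members = paste(sort(rows$term_id[i]), collapse = ", "),
               min_p = min(rows$p[i]), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$category, -out$share_pct, out$min_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
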