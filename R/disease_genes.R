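#' Call differentially expressed genes from a two-group expression matrix
#'
#' Per-gene two-sided two-sample t test (Welch by default) on log2
#' intensities, case versus control. The linear fold change is computed from
#' the group means on the linear scale, `fc = 2^(mean_case - mean_control)`,
#' and the |FC| criterion is `max(fc, 1/fc) >= fc_min` (equivalently
#' `|log2fc| >= log2(fc_min)`). A gene is called `up` when significant with
#' `fc >= fc_min`, `down` when significant with `fc <= 1/fc_min`, otherwise
#' `ns`. Zero-variance genes get p = 1 (never an error). Benjamini-Hochberg
#' q-values are reported alongside but are not used for the call: the cut is
#' on the raw p, as is conventional for this style of screening analysis.
#'
#' @param m An `expression_matrix` (log2 intensities, >= 2 samples/group).
#' @param p_max Significance cut on the raw two-sided p (default 0.05,
#'   strict `<`).
#' @param fc_min Linear fold-change cut (default 1.5, inclusive `>=`).
#' @param var_equal FALSE (default) for Welch, TRUE for Student's t.
#' @return Data frame with columns gene, log2fc, fc, p, q, direction;
#'   one row per gene in input order.
#' @export
call_degs <- function(m, p_max = 0.05, fc_min = 1.5, var_equal = FALSE) {
  stopifnot(inherits(m, "expression_matrix"), p_max > 0, p_max <= 1, fc_min >= 1)
  case <- m$values[, m$group == "case", drop = FALSE]
  ctrl <- m$values[, m$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0] <- 1  # zero-variance genes: flat, never significant
  log2fc <- m1 - m2
  fc <- 2^log2fc
  sig <- p < p_max & pmax(fc, 1 / fc) >= fc_min
  direction <- rep("ns", length(p))
  direction[sig & fc >= fc_min] <- "up"
  direction[sig & fc <= 1 / fc_min] <- "down"
  data.frame(gene = m$genes, log2fc = unname(log2fc), fc = unname(fc),
             p = unname(p), q = unname(stats::p.adjust(p, "BH")),
             direction = direction, stringsAsFactors = FALSE)
}

#' Volcano-plot table of DEG results
#'
#' One plotting-ready row per gene (log2 fold change against -log10 p) with
#' the up/down/total DEG counts attached as attributes.
#'
#' @param degs Output of [call_degs()].
#' @return Data frame (gene, log2fc, neg_log10_p, direction) with
#'   attributes `n_up`, `n_down`, `n_deg`.
#' @export
volcano_table <- function(degs) {
  out <- data.frame(gene = degs$gene, log2fc = degs$log2fc,
                    neg_log10_p = -log10(degs$p),
                    direction = degs$direction, stringsAsFactors = FALSE)
  attr(out, "n_up") <- sum(degs$direction == "up")
  attr(out, "n_down") <- sum(degs$direction == "down")
  attr(out, "n_deg") <- sum(degs$direction != "ns")
  out
}

#' Merge DEG-derived and curated disease genes into one provenance-tagged set
#'
#' Union of the DEG gene list (tagged "deg") and each curated source's list
#' (tagged by source name); duplicates are removed and every gene keeps the
#' full set of sources that reported it.
#'
#' @param deg_genes Character vector of DEG symbols.
#' @param curated Named list of character vectors, one per source; names
#'   drawn from c("ttd", "drugbank", "kegg", "disgenet", "omim").
#' @return A `disease_gene_set`: list with `genes` (sorted unique symbols)
#'   and `provenance` (named list gene -> source tags).
#' @export
merge_disease_genes <- function(deg_genes, curated = list()) {
  allowed <- c("ttd", "drugbank", "kegg", "disgenet", "omim")
  if (length(curated) && !all(names(curated) %in% allowed))
    stop("unknown curated source(s): ",
         paste(setdiff(names(curated), allowed), collapse = ", "))
  tags <- c(list(deg = canon_gene(deg_genes)),
            lapply(curated, canon_gene))
  pairs <- data.frame(
    gene = unlist(tags, use.names = FALSE),
    src = rep(names(tags), lengths(tags)), stringsAsFactors = FALSE)
  prov <- lapply(split(pairs$src, pairs$gene), function(s) sort(unique(s)))
  structure(list(genes = sort(names(prov)), provenance = prov),
            class = "disease_gene_set")
}

#' @export
print.disease_gene_set <- function(x, ...) {
  src <- sort(table(unlist(x$provenance)), decreasing = TRUE)
  cat("disease_gene_set:", length(x$genes), "genes (",
      paste(sprintf("%s=%d", names(src), src), collapse = ", "), ")\n")
  invisible(x)
}
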