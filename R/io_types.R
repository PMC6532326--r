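#' Canonicalize ingredient names
#'
#' Ingredient identity across knowledge sources is by canonicalized name:
#' leading/trailing whitespace trimmed, internal whitespace collapsed to a
#' single space, lower-cased. Canonicalization is idempotent.
#'
#' @param x Character vector of raw ingredient names.
#' @return Character vector of canonical names.
#' @export
#' @examples
#' canon_name(c("  Beta-Sitosterol ", "beta-sitosterol"))
canon_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Canonicalize gene symbols
#'
#' Gene identity is by upper-cased symbol; no synonym resolution is attempted.
#'
#' @param x Character vector of gene symbols.
#' @return Upper-cased, trimmed symbols.
#' @export
canon_gene <- function(x) {
  toupper(gsub("\\s+", "", as.character(x)))
}

#' Construct an ingredient set
#'
#' An `ingredient_set` is a data frame with one row per distinct ingredient:
#' `ingredient` (canonical name), `herbs` (list column of herb codes),
#' `ob` (oral bioavailability, percent, may be NA), `dl` (drug-likeness in
#' \[0,1\], may be NA) and `source` (one of "tcmsp", "hit", "both").
#'
#' @param ingredient Character vector of canonical names (must be unique).
#' @param herbs List of character vectors, herb codes per ingredient.
#' @param ob,dl Numeric vectors (NA allowed).
#' @param source Character vector in c("tcmsp", "hit", "both").
#' @return An `ingredient_set` data frame.
#' @export
ingredient_set <- function(ingredient, herbs, ob = NA_real_, dl = NA_real_,
                           source = "tcmsp") {
  n <- length(ingredient)
  out <- data.frame(ingredient = as.character(ingredient),
                    ob = rep_len(as.numeric(ob), n),
                    dl = rep_len(as.numeric(dl), n),
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  out$herbs <- lapply(herbs, function(h) sort(unique(as.character(h))))
  out <- out[, c("ingredient", "herbs", "ob", "dl", "source")]
  class(out) <- c("ingredient_set", "data.frame")
  validate_ingredient_set(out)
}

#' @keywords internal
validate_ingredient_set <- function(x) {
  if (anyDuplicated(x$ingredient))
    stop("duplicate ingredient ids: ",
         paste(unique(x$ingredient[duplicated(x$ingredient)]), collapse = ", "))
  if (any(lengths(x$herbs) == 0))
    stop("ingredient with empty herb set: ",
         paste(x$ingredient[lengths(x$herbs) == 0], collapse = ", "))
  bad_ob <- !is.na(x$ob) & x$ob < 0
  if (any(bad_ob)) stop("negative ob for: ", paste(x$ingredient[bad_ob], collapse = ", "))
  bad_dl <- !is.na(x$dl) & (x$dl < 0 | x$dl > 1)
  if (any(bad_dl)) stop("dl outside [0,1] for: ", paste(x$ingredient[bad_dl], collapse = ", "))
  if (!all(x$source %in% c("tcmsp", "hit", "both")))
    stop("source must be one of tcmsp/hit/both")
  x
}

#' Read an ingredient table
#'
#' Reads a TSV with header columns `herb`, `ingredient`, `ob`, `dl` (the
#' latter two may be empty, as in literature-curated exports that carry no
#' ADME scores). Rows naming the same ingredient are merged: herb membership
#' is the union across rows, and the first non-missing ob/dl is kept.
#' Ingredient names are canonicalized via [canon_name()].
#'
#' @param path Path to the TSV file.
#' @param source_tag "tcmsp" or "hit"; stored on every record.
#' @return An `ingredient_set`.
#' @export
read_ingredient_table <- function(path, source_tag = c("tcmsp", "hit")) {
  source_tag <- match.arg(source_tag)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  required <- c("herb", "ingredient", "ob", "dl")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("ingredient table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) {
    return(ingredient_set(character(), list(), numeric(), numeric(), character()))
  }
  parse_num <- function(col, nm) {
    raw <- trimws(df[[col]])
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(out))
    if (length(bad))
      stop("non-numeric ", nm, " value '", raw[bad[1]], "' at line ",
           bad[1] + 1L, " of ", path)  # +1 for the header line
    out
  }
  ob <- parse_num("ob", "ob")
  dl <- parse_num("dl", "dl")
  name <- canon_name(df$ingredient)
  herb <- trimws(df$herb)
  idx <- split(seq_len(nrow(df)), name)
  ingredient_set(
    ingredient = names(idx),
    herbs = lapply(idx, function(i) herb[i]),
    ob = vapply(idx, function(i) {
      v <- ob[i]; if (all(is.na(v))) NA_real_ else v[!is.na(v)][1]
    }, numeric(1)),
    dl = vapply(idx, function(i) {
      v <- dl[i]; if (all(is.na(v))) NA_real_ else v[!is.na(v)][1]
    }, numeric(1)),
    source = source_tag
  )
}

#' Write an ingredient table
#'
#' Inverse of [read_ingredient_table()]: one row per (herb, ingredient) pair,
#' so that a read of the written file reproduces the set.
#'
#' @param x An `ingredient_set`.
#' @param path Output TSV path.
#' @export
write_ingredient_table <- function(x, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    data.frame(herb = x$herbs[[i]], ingredient = x$ingredient[i],
               ob = x$ob[i], dl = x$dl[i], stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(herb = character(), ingredient = character(),
                       ob = numeric(), dl = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ingredient-target association table
#'
#' TSV with header `ingredient`, `gene`, and for predicted associations
#' `similarity` and `prediction_score` columns. Validated associations must
#' leave the score columns empty; predicted associations must fill both.
#'
#' @param path Path to the TSV file.
#' @param evidence "validated" or "predicted".
#' @return Data frame with columns ingredient, gene, evidence, similarity,
#'   prediction_score.
#' @export
read_target_table <- function(path, evidence = c("validated", "predicted")) {
  evidence <- match.arg(evidence)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  required <- c("ingredient", "gene")
  if (evidence == "predicted") required <- c(required, "similarity", "prediction_score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("target table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    ingredient = canon_name(df$ingredient),
    gene = canon_gene(df$gene),
    evidence = evidence,
    similarity = if (evidence == "predicted")
      as.numeric(df$similarity) else NA_real_,
    prediction_score = if (evidence == "predicted")
      as.numeric(df$prediction_score) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(out$gene == ""))
    stop("empty gene symbol at line ",
         which(out$gene == "")[1] + 1L, " of ", path)
  if (evidence == "predicted" &&
      (anyNA(out$similarity) || anyNA(out$prediction_score)))
    stop("predicted association with missing similarity/prediction_score in ", path)
  out
}

#' Read a scored protein-protein interaction edge table
#'
#' TSV with header `a`, `b`, `score`. Edges are undirected: endpoints are
#' stored canonically sorted and duplicate edges are collapsed (keeping the
#' maximum score). Self-loops are rejected. STITCH-style integer combined
#' scores in 0-999 are divided by 1000 when `scores_0_999 = TRUE`.
#'
#' @param path Path to the TSV file.
#' @param scores_0_999 If TRUE, divide the score column by 1000 at load.
#' @return Data frame with columns a, b, score (a < b lexicographically).
#' @export
read_edge_table <- function(path, scores_0_999 = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c("a", "b", "score"), names(df))
  if (length(missing_cols))
    stop("edge table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  score <- as.numeric(df$score)
  if (scores_0_999) score <- score / 1000
  make_edge_set(canon_gene(df$a), canon_gene(df$b), score)
}

#' Build a canonical undirected scored edge set
#'
#' @param a,b Endpoint symbols.
#' @param score Numeric scores in \[0,1\].
#' @return Data frame (a, b, score) with a < b, no self-loops, no duplicates
#'   (max score kept on duplicates).
#' @export
make_edge_set <- function(a, b, score) {
  a <- as.character(a); b <- as.character(b)
  if (any(a == b))
    stop("self-loop edge on: ", paste(unique(a[a == b]), collapse = ", "))
  if (any(is.na(score) | score < 0 | score > 1))
    stop("edge score outside [0,1]")
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- tapply(score, key, max)
  parts <- strsplit(names(keep), "\r", fixed = TRUE)
  out <- data.frame(a = vapply(parts, `[`, "", 1),
                    b = vapply(parts, `[`, "", 2),
                    score = as.numeric(keep), stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: `term_id TAB description TAB gene1 TAB gene2 ...`.
#' Genes are upper-cased and deduplicated within each term.
#'
#' @param path Path to the GMT file.
#' @param category Category label attached to every term ("kegg" or
#'   "molecular_function").
#' @return A `gene_set_collection`: named list of terms, each a list with
#'   `name`, `category` and `genes`.
#' @export
read_gmt <- function(path, category = c("kegg", "molecular_function")) {
  category <- match.arg(category)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " of ", path, " has fewer than 3 fields")
    id <- f[1]
    if (!is.null(terms[[id]])) stop("duplicate GMT term id ", id, " in ", path)
    terms[[id]] <- list(name = f[2], category = category,
                        genes = unique(canon_gene(f[-(1:2)])))
  }
  structure(terms, class = "gene_set_collection")
}

#' Write gene sets in GMT format
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    t <- sets[[id]]
    paste(c(id, t$name, t$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a tripartite network
#'
#' Nodes are typed by layer (`ingredient`, `candidate_target`, `protein`);
#' edges are simple and undirected (self-loops forbidden, duplicates
#' collapsed, stored with endpoints canonically sorted).
#'
#' @param nodes Named character vector mapping node id to layer.
#' @param edges Two-column character matrix or data frame of endpoint ids.
#' @return A `tripartite_network` (list with `nodes` and `edges`).
#' @export
tripartite_network <- function(nodes, edges) {
  layers <- c("ingredient", "candidate_target", "protein")
  if (!all(nodes %in% layers))
    stop("node layer must be one of: ", paste(layers, collapse = ", "))
  if (anyDuplicated(names(nodes))) stop("duplicate node ids")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2 && length(edges) > 0) stop("edges must have two columns")
  if (nrow(edges) > 0) {
    mode(edges) <- "character"
    if (any(edges[, 1] == edges[, 2])) stop("self-loop in network edges")
    unknown <- setdiff(c(edges), names(nodes))
    if (length(unknown))
      stop("edge endpoint(s) absent from node set: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    lo <- pmin(edges[, 1], edges[, 2]); hi <- pmax(edges[, 1], edges[, 2])
    key <- !duplicated(paste(lo, hi, sep = "\r"))
    edges <- cbind(lo[key], hi[key])
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  } else {
    edges <- matrix(character(), ncol = 2)
  }
  colnames(edges) <- c("a", "b")
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  tab <- table(factor(x$nodes, levels = c("ingredient", "candidate_target", "protein")))
  cat("tripartite_network:", length(x$nodes), "nodes (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a tripartite network to an igraph graph
#'
#' @param net A `tripartite_network`.
#' @return An igraph undirected graph with a `layer` vertex attribute.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = names(net$nodes),
                            layer = unname(net$nodes))
  if (nrow(net$edges) > 0)
    g <- igraph::add_edges(g, t(net$edges))
  g
}

#' Write a network to disk
#'
#' Supported formats: `sif` (Cytoscape simple interaction file, relation
#' "pp"; isolated nodes emitted as single-field lines), `graphml` (node
#' attributes `layer`, `degree`, `is_key`), and `node_table` (TSV with
#' columns id, layer, degree, is_key).
#'
#' @param net A `tripartite_network`.
#' @param degrees Named integer vector of node degrees (defaults to degrees
#'   computed from `net`).
#' @param path Output path.
#' @param format One of "sif", "graphml", "node_table".
#' @param key_nodes Character vector of node ids flagged `is_key`.
#' @export
write_network <- function(net, degrees = NULL, path,
                          format = c("sif", "graphml", "node_table"),
                          key_nodes = character()) {
  format <- match.arg(format)
  if (is.null(degrees)) degrees <- node_degrees(net)
  degrees <- degrees[names(net$nodes)]
  degrees[is.na(degrees)] <- 0L
  names(degrees) <- names(net$nodes)
  if (format == "sif") {
    lines <- character()
    if (nrow(net$edges) > 0)
      lines <- paste(net$edges[, 1], "pp", net$edges[, 2])
    isolated <- setdiff(names(net$nodes), c(net$edges))
    writeLines(c(lines, isolated), path)
  } else if (format == "graphml") {
    g <- as_igraph(net)
    igraph::V(g)$degree <- as.integer(unname(degrees))
    igraph::V(g)$is_key <- as.integer(names(net$nodes) %in% key_nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    df <- data.frame(id = names(net$nodes), layer = unname(net$nodes),
                     degree = as.integer(unname(degrees)),
                     is_key = names(net$nodes) %in% key_nodes,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to a `sif` or `graphml` file.
#' @param format "sif" or "graphml".
#' @param layers Named character vector id -> layer; required for SIF (which
#'   does not carry layers); ignored for GraphML.
#' @return A `tripartite_network`.
#' @export
read_network <- function(path, format = c("sif", "graphml"), layers = NULL) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    edges <- do.call(rbind, lapply(parts[lengths(parts) >= 3],
                                   function(p) cbind(p[1], p[-(1:2)])))
    if (is.null(edges)) edges <- matrix(character(), ncol = 2)
    ids <- unique(c(unlist(lapply(parts, function(p) p[1])),
                    unlist(lapply(parts[lengths(parts) >= 3], function(p) p[-(1:2)]))))
    if (is.null(layers))
      stop("reading SIF requires a `layers` map (SIF carries no node types)")
    tripartite_network(layers[ids], edges)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- stats::setNames(igraph::V(g)$layer, igraph::V(g)$name)
    edges <- igraph::as_edgelist(g, names = TRUE)
    tripartite_network(nodes, edges)
  }
}

#' Read a two-group expression matrix
#'
#' The matrix TSV has gene symbols in the first column and one column of
#' log2 intensities per sample; the groups TSV has columns `sample` and
#' `group` with group labels "case" and "control".
#'
#' @param matrix_path Path to the genes x samples TSV.
#' @param groups_path Path to the sample-group TSV.
#' @return An `expression_matrix`: list with `values` (numeric matrix,
#'   genes x samples), `genes`, `samples`, `group`.
#' @export
read_expression_matrix <- function(matrix_path, groups_path) {
  df <- utils::read.delim(matrix_path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  genes <- canon_gene(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- genes
  gr <- utils::read.delim(groups_path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("sample", "group") %in% names(gr)))
    stop("groups table must have columns sample, group")
  group <- stats::setNames(gr$group, gr$sample)[colnames(values)]
  expression_matrix(values, group)
}

#' Construct an expression matrix container
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns.
#' @param group Character vector of "case"/"control" per column.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, group) {
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols")
  group <- unname(as.character(group))
  if (length(group) != ncol(values)) stop("one group label per sample required")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (any(table(factor(group, levels = c("case", "control"))) < 2))
    stop("each group needs at least 2 samples")
  structure(list(values = values, genes = rownames(values),
                 samples = colnames(values), group = group),
            class = "expression_matrix")
}

#' Write an expression matrix and its group table
#'
#' @param m An `expression_matrix`.
#' @param matrix_path,groups_path Output TSV paths.
#' @export
write_expression_matrix <- function(m, matrix_path, groups_path) {
  df <- data.frame(gene = m$genes, m$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = m$samples, group = m$group),
                     groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to the file.
#' @return Character vector of unique upper-cased symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  unique(canon_gene(x[nzchar(trimws(x))]))
}
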