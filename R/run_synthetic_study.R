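#' Run the whole inference chain on freshly generated synthetic data
#'
#' Convenience driver for simulation studies: generates every input in
#' memory under one seed ([gen_all()] substreams), then runs screening,
#' merging, compendium assembly, DEG calling, disease-gene merging,
#' candidate mapping, PPI expansion, network construction, key-node
#' selection and (optionally) enrichment, without touching disk. Used for
#' planted-truth recovery experiments where hundreds of replicates are run.
#'
#' @param params From [synth_params()].
#' @param seed Integer master seed.
#' @param settings Stage thresholds, see [pipeline_defaults()].
#' @param enrich Run the enrichment stage (default TRUE; skipping it saves
#'   time in recovery loops that only look at the network).
#' @return List: `report` (headline counts as in [run_pipeline()]), `keys`,
#'   `stats`, `net`, `candidates`, `degs`, `enrichment` (rows or NULL) and
#'   `ground_truth`.
#' @export
run_synthetic_study <- function(params = synth_params(), seed = 1,
                                settings = pipeline_defaults(),
                                enrich = TRUE) {
  s <- settings
  kb <- gen_knowledgebase(params, seed)
  ex <- gen_expression(params, seed)
  dz <- gen_disease_lists(params, seed)
  pg <- gen_ppi_and_genesets(params, seed)

  tcmsp <- ingredient_table_from_df(kb$tcmsp, "tcmsp")
  hit <- ingredient_table_from_df(kb$hit, "hit")
  kept <- screen_tcmsp(tcmsp, s$ob_min, s$dl_min, s$inclusive)
  merged <- merge_sources(kept, hit)

  pred_kept <- filter_predicted(kb$predicted, s$sim_min, s$pred_score_min)
  comp <- build_compendium(kb$validated, pred_kept, merged)

  degs <- call_degs(ex$matrix, s$p_max, s$fc_min, s$var_equal)
  dset <- merge_disease_genes(degs$gene[degs$direction != "ns"], dz$curated)

  cands <- map_candidates(comp, dset)
  cands <- expand_interactors(cands, pg$edges, s$ppi_score_min,
                              s$include_interactor_interactor)

  net <- build_network(cands, comp)
  stats <- network_stats(net)
  keys <- select_key_nodes(net, stats)

  enr <- NULL
  if (enrich && length(keys$key_targets_pooled) > 0) {
    sets <- c(unclass(pg$kegg), unclass(pg$mf))
    class(sets) <- "gene_set_collection"
    background <- union(comp$target_universe, cands$interactors)
    enr <- hypergeom_enrich(keys$key_targets_pooled, sets, background)
  }

  gt <- list(seed = seed,
             planted_hub_ingredients = kb$ground_truth$planted_hub_ingredients,
             planted_degs = ex$ground_truth$planted_degs,
             planted_enriched_terms = pg$ground_truth$planted_enriched_terms)
  list(
    report = list(
      n_active_ingredients = nrow(merged),
      n_targets = length(comp$target_universe),
      n_targets_validated = comp$n_validated,
      n_targets_predicted = comp$n_predicted,
      n_deg_up = sum(degs$direction == "up"),
      n_deg_down = sum(degs$direction == "down"),
      n_deg = sum(degs$direction != "ns"),
      n_disease_genes = length(dset$genes),
      n_candidates = length(cands$candidates),
      n_candidates_validated = sum(cands$evidence_of == "validated"),
      n_candidates_predicted = sum(cands$evidence_of == "predicted"),
      n_interactors = length(cands$interactors),
      n_nodes = stats$n_nodes,
      n_edges = stats$n_edges,
      mean_degree = stats$mean_degree,
      key_threshold = stats$key_threshold
    ),
    keys = keys, stats = stats, net = net, candidates = cands,
    degs = degs, compendium = comp, enrichment = enr, ground_truth = gt
  )
}

#' Build an ingredient set from a raw (herb, ingredient, ob, dl) data frame
#'
#' In-memory counterpart of [read_ingredient_table()] with the same merging
#' and canonicalization semantics.
#'
#' @param df Data frame with columns herb, ingredient, ob, dl (ob/dl may be
#'   empty strings or NA).
#' @param source_tag "tcmsp" or "hit".
#' @return An `ingredient_set`.
#' @export
ingredient_table_from_df <- function(df, source_tag = c("tcmsp", "hit")) {
  source_tag <- match.arg(source_tag)
  name <- canon_name(df$ingredient)
  herb <- trimws(as.character(df$herb))
  num <- function(x) suppressWarnings(as.numeric(as.character(x)))
  ob <- num(df$ob); dl <- num(df$dl)
  idx <- split(seq_len(nrow(df)), name)
  first_ok <- function(v, i) {
    v <- v[i]; if (all(is.na(v))) NA_real_ else v[!is.na(v)][1]
  }
  ingredient_set(
    ingredient = names(idx),
    herbs = lapply(idx, function(i) herb[i]),
    ob = vapply(idx, function(i) first_ok(ob, i), numeric(1)),
    dl = vapply(idx, function(i) first_ok(dl, i), numeric(1)),
    source = source_tag
  )
}
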