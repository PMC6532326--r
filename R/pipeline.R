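#' Default pipeline settings
#'
#' @return Named list of stage thresholds: ADME screen (`ob_min`, `dl_min`,
#'   `inclusive`), predicted-target filter (`sim_min`, `pred_score_min`),
#'   DEG calling (`p_max`, `fc_min`, `var_equal`), PPI expansion
#'   (`ppi_score_min`, `include_interactor_interactor`,
#'   `edge_scores_0_999`), and enrichment (`q_max`, `kappa_min`).
#' @export
pipeline_defaults <- function() {
  list(ob_min = 30, dl_min = 0.18, inclusive = TRUE,
       sim_min = 1.0, pred_score_min = 0,
       p_max = 0.05, fc_min = 1.5, var_equal = FALSE,
       ppi_score_min = 0.9, include_interactor_interactor = TRUE,
       edge_scores_0_999 = FALSE,
       q_max = 0.05, kappa_min = 0.4)
}

#' Validate a pipeline configuration
#'
#' A config is a list with `inputs` (paths: tcmsp, hit, validated,
#' predicted, expression, groups, edges, gmt_kegg, gmt_mf, and `curated`, a
#' named list of per-source gene-list paths), optional `settings` overriding
#' [pipeline_defaults()], and `out_dir`. A character scalar is treated as
#' the path of a YAML (or JSON) config file.
#'
#' @param config List or path to a YAML/JSON config file.
#' @return The validated config with defaults filled in.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs), !is.null(config$out_dir))
  required <- c("tcmsp", "hit", "validated", "predicted", "expression",
                "groups", "edges", "gmt_kegg", "gmt_mf")
  miss <- setdiff(required, names(config$inputs))
  if (length(miss))
    stop("config$inputs missing: ", paste(miss, collapse = ", "))
  paths <- c(unlist(config$inputs[required]), unlist(config$inputs$curated))
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  s <- pipeline_defaults()
  s[names(config$settings)] <- config$settings
  stopifnot(s$ob_min >= 0, s$dl_min >= 0, s$dl_min <= 1,
            s$p_max > 0, s$p_max <= 1, s$fc_min >= 1,
            s$ppi_score_min >= 0, s$ppi_score_min <= 1,
            s$q_max > 0, s$q_max <= 1)
  config$settings <- s
  config
}

#' Run the full network-pharmacology pipeline
#'
#' Executes ADME screening, source merging, target-compendium assembly,
#' DEG calling plus disease-gene merging, candidate mapping, PPI expansion,
#' tripartite network construction with key-node selection, and enrichment
#' of the pooled key targets with kappa grouping. Every intermediate table
#' is written under `out_dir` along with `report.json` carrying the
#' headline counts. The run is deterministic: identical inputs and settings
#' give identical outputs. A stage failure aborts with the stage name and
#' leaves a `FAILED` marker file beside the partial outputs.
#'
#' @param config List or YAML/JSON path; see [validate_pipeline_config()].
#' @return The run report (named list), invisibly written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  s <- cfg$settings
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  log_line <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage", name, ":", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  fp <- function(f) file.path(out_dir, f)
  wt <- function(df, f) utils::write.table(df, fp(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)

  merged <- stage("ingredient_screen", {
    tcmsp <- read_ingredient_table(cfg$inputs$tcmsp, "tcmsp")
    hit <- read_ingredient_table(cfg$inputs$hit, "hit")
    kept <- screen_tcmsp(tcmsp, s$ob_min, s$dl_min, s$inclusive)
    m <- merge_sources(kept, hit)
    write_ingredient_table(m, fp("merged_ingredients.tsv"))
    wt(herb_overlap_table(m), "herb_overlap.tsv")
    log_line("screen: ", nrow(tcmsp), " scored -> ", nrow(kept),
             " kept; +", nrow(hit), " curated = ", nrow(m), " active")
    list(merged = m, n_tcmsp = nrow(tcmsp), n_kept = nrow(kept),
         n_hit = nrow(hit))
  })

  comp <- stage("target_compendium", {
    validated <- read_target_table(cfg$inputs$validated, "validated")
    predicted <- read_target_table(cfg$inputs$predicted, "predicted")
    pred_kept <- filter_predicted(predicted, s$sim_min, s$pred_score_min)
    cc <- build_compendium(validated, pred_kept, merged$merged)
    wt(cc$associations, "compendium.tsv")
    wt(coverage_stats(cc), "coverage.tsv")
    buckets <- common_targets_by_herb_count(cc, 1)
    wt(data.frame(herb_count = rep(names(buckets), lengths(buckets)),
                  gene = unlist(buckets, use.names = FALSE)),
       "targets_by_herb_count.tsv")
    log_line("compendium: ", length(cc$target_universe), " targets (",
             cc$n_validated, " validated, ", cc$n_predicted, " predicted)")
    cc
  })

  disease <- stage("disease_genes", {
    m <- read_expression_matrix(cfg$inputs$expression, cfg$inputs$groups)
    degs <- call_degs(m, s$p_max, s$fc_min, s$var_equal)
    wt(degs, "degs.tsv")
    volcano <- volcano_table(degs)
    wt(volcano, "volcano.tsv")
    curated <- lapply(cfg$inputs$curated, read_gene_list)
    dset <- merge_disease_genes(degs$gene[degs$direction != "ns"], curated)
    wt(data.frame(gene = dset$genes,
                  sources = vapply(dset$provenance[dset$genes],
                                   paste, "", collapse = ",")),
       "disease_genes.tsv")
    log_line("degs: ", attr(volcano, "n_up"), " up + ",
             attr(volcano, "n_down"), " down = ", attr(volcano, "n_deg"),
             "; merged disease genes: ", length(dset$genes))
    list(volcano = volcano, set = dset,
         n_curated = length(unique(unlist(curated))))
  })

  cands <- stage("candidate_mapping", {
    ca <- map_candidates(comp, disease$set)
    edges <- read_edge_table(cfg$inputs$edges, s$edge_scores_0_999)
    ca <- expand_interactors(ca, edges, s$ppi_score_min,
                             s$include_interactor_interactor)
    wt(data.frame(gene = ca$candidates,
                  evidence = unname(ca$evidence_of)), "candidates.tsv")
    writeLines(ca$interactors, fp("interactors.txt"))
    wt(ca$kept_edges, "kept_edges.tsv")
    log_line("candidates: ", length(ca$candidates), " (",
             sum(ca$evidence_of == "validated"), " validated, ",
             sum(ca$evidence_of == "predicted"), " predicted); interactors: ",
             length(ca$interactors))
    ca
  })

  network <- stage("network_analysis", {
    net <- build_network(cands, comp)
    if (length(net$nodes) == 0) {
      warning("empty candidate set: network has no nodes")
      st <- structure(list(n_nodes = 0L, n_edges = 0L,
                           degrees = stats::setNames(integer(0), character(0)),
                           mean_degree = NA_real_, key_threshold = NA_real_),
                      class = "network_stats")
    } else {
      st <- network_stats(net)
    }
    keys <- select_key_nodes(net, st)
    write_network(net, st$degrees, fp("network.sif"), "sif")
    write_network(net, st$degrees, fp("network.graphml"), "graphml",
                  key_nodes = unlist(keys[c("key_ingredients",
                                            "key_targets_pooled")]))
    write_network(net, st$degrees, fp("network_nodes.tsv"), "node_table",
                  key_nodes = unlist(keys[c("key_ingredients",
                                            "key_targets_pooled")]))
    log_line("network: ", st$n_nodes, " nodes, ", st$n_edges,
             " edges, mean degree ", round(st$mean_degree, 3),
             "; key: ", length(keys$key_ingredients), " ingredients + ",
             length(keys$key_targets_pooled), " targets")
    list(net = net, stats = st, keys = keys)
  })

  enrich <- stage("enrichment", {
    query <- network$keys$key_targets_pooled
    background <- union(comp$target_universe, cands$interactors)
    if (length(query) == 0) {
      warning("no key targets; skipping enrichment")
      list(rows = NULL, summary = NULL)
    } else {
      sets <- c(unclass(read_gmt(cfg$inputs$gmt_kegg, "kegg")),
                unclass(read_gmt(cfg$inputs$gmt_mf, "molecular_function")))
      class(sets) <- "gene_set_collection"
      rows <- hypergeom_enrich(query, sets, background)
      sig <- rows[rows$q < s$q_max, , drop = FALSE]
      if (nrow(sig) > 0) {
        sig <- kappa_group(sig, sets, query, s$kappa_min)
        summary <- summarize_categories(sig)
      } else {
        summary <- summarize_categories(sig[0, ])
      }
      wt(rows, "enrichment.tsv")
      wt(summary, "enrichment_summary.tsv")
      log_line("enrichment: ", nrow(sig), " significant terms in ",
               length(unique(sig$group_id)), " groups")
      list(rows = rows, sig = sig, summary = summary)
    }
  })

  report <- list(
    settings = s,
    n_tcmsp_records = merged$n_tcmsp,
    n_tcmsp_kept = merged$n_kept,
    n_hit = merged$n_hit,
    n_active_ingredients = nrow(merged$merged),
    n_targets = length(comp$target_universe),
    n_targets_validated = comp$n_validated,
    n_targets_predicted = comp$n_predicted,
    n_deg_up = attr(disease$volcano, "n_up"),
    n_deg_down = attr(disease$volcano, "n_down"),
    n_deg = attr(disease$volcano, "n_deg"),
    n_curated_disease_genes = disease$n_curated,
    n_disease_genes = length(disease$set$genes),
    n_candidates = length(cands$candidates),
    n_candidates_validated = sum(cands$evidence_of == "validated"),
    n_candidates_predicted = sum(cands$evidence_of == "predicted"),
    n_interactors = length(cands$interactors),
    n_nodes = network$stats$n_nodes,
    n_edges = network$stats$n_edges,
    mean_degree = network$stats$mean_degree,
    key_threshold = network$stats$key_threshold,
    key_ingredients = network$keys$key_ingredients,
    key_targets = network$keys$key_targets_pooled,
    top_groups = if (!is.null(enrich$summary) && nrow(enrich$summary) > 0)
      enrich$summary$group_name[!duplicated(enrich$summary$category)]
      else character()
  )
  jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_line("pipeline complete")
  report
}
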