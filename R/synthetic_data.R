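#' Default parameters for the synthetic knowledgebase and study data
#'
#' The defaults are sized to a realistic 12-herb formula study: ~480 raw
#' ADME-scored ingredient rows of which ~130 pass the OB/DL screen, 39
#' curated ingredients without ADME scores, a ~1100-gene reachable target
#' universe yielding ~900 distinct targets, a 45-gene disease core from
#' which curated lists (5 sources, ~59 genes) and planted DEGs draw, a
#' 6-vs-6 two-group expression design with noise sd 0.3 and planted
#' |log2FC| = 1 (23 up, 28 down), and Beta-mixture PPI confidence scores
#' with a high mode above 0.9. One planted hub ingredient is wired to a
#' large target fan-out including most of the disease core.
#'
#' @param ... Named overrides of any default.
#' @return Named list of generation parameters.
#' @export
synth_params <- function(...) {
  p <- list(
    herbs = c("RP", "RC", "RCX", "CL", "RS", "CT", "SP", "PGS",
              "AgR", "RM", "SM", "OF"),
    herb_weights = c(35, 7, 22, 21, 21, 13, 4, 13, 22, 12, 13, 5),
    n_tcmsp = 480, n_hit = 39,
    overlap_prob = 0.05,            # chance of each extra herb membership
    ob_range = c(0, 60), dl_range = c(0, 0.4),
    n_universe = 1100,              # reachable target gene pool
    n_core = 45,                    # disease-prone core genes
    fanout_mean = 12,               # predicted targets per active ingredient
    fanout_validated = 9,           # validated targets per curated ingredient
    validated_core_frac = 0.15,     # curated targets drawn from the core
    decoy_mean = 2,                 # sub-threshold predicted rows per ingredient
    n_hubs = 1, hub_fanout_factor = 10, hub_core_frac = 0.6,
    n_curated = 59, n_curated_core = 28, n_sources_extra_prob = 0.25,
    n_genes_expr = 2000, n_per_group = 6, noise_sd = 0.3,
    baseline_mean = 7, baseline_sd = 1.5,
    n_up = 23, n_down = 28, planted_log2fc = 1,
    deg_core_up = 6, deg_core_down = 8,
    n_proteins = 300, ppi_core_edges_mean = 7, ppi_high_prob = 0.55,
    ppi_noise_edges = 300,
    n_kegg_terms = 12, kegg_term_size = 25, planted_kegg_core = 18,
    n_mf_terms = 8, mf_term_size = 15, planted_mf_core = 8
  )
  dots <- list(...)
  p[names(dots)] <- dots
  stopifnot(length(p$herbs) >= 2, p$n_tcmsp >= 1, p$n_per_group >= 2,
            p$n_core <= p$n_universe,
            p$deg_core_up + p$deg_core_down <= p$n_core - p$n_curated_core,
            p$deg_core_up <= p$n_up, p$deg_core_down <= p$n_down)
  p
}

# Derive a 32-bit substream seed so each generator stream is independent of
# the others and stable when new streams are added.
substream_seed <- function(seed, stream) {
  offset <- c(knowledgebase = 101, expression = 211, disease = 307,
              ppi = 401, genesets = 503)[[stream]]
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483647)
}

# Evaluate code under a seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

universe_genes <- function(p) sprintf("G%04d", seq_len(p$n_universe))
core_genes <- function(p) sprintf("G%04d", seq_len(p$n_core))
protein_pool <- function(p) sprintf("P%04d", seq_len(p$n_proteins))

#' Generate the synthetic ingredient and target knowledgebase
#'
#' Emulates the two ingredient sources (an ADME-scored systems-pharmacology
#' export and a curated literature source) and the two target-association
#' routes (validated and 3D-similarity predicted, the latter including
#' sub-threshold decoy rows that the similarity/score filter must remove).
#' Planted hub ingredients are guaranteed to pass the ADME screen and are
#' wired to `hub_core_frac` of the disease core plus a fan-out
#' `hub_fanout_factor` times the typical ingredient's.
#'
#' @param params From [synth_params()].
#' @param seed Integer seed; the stream is independent of the other
#'   generators.
#' @return List with `tcmsp` and `hit` (raw ingredient table data frames),
#'   `validated` and `predicted` (association data frames), and
#'   `ground_truth` (planted hub ids and generation metadata).
#' @export
gen_knowledgebase <- function(params = synth_params(), seed = 1) {
  p <- params
  with_seed(substream_seed(seed, "knowledgebase"), {
    uni <- universe_genes(p)
    core <- core_genes(p)
    hub_ids <- if (p$n_hubs > 0) sprintf("hubcompound-%02d", seq_len(p$n_hubs))
               else character()
    tcmsp_ids <- c(hub_ids, sprintf("compound-%04d", seq_len(p$n_tcmsp - p$n_hubs)))
    hit_ids <- sprintf("herbal-%04d", seq_len(p$n_hit))

    draw_herbs <- function(n) {
      lapply(seq_len(n), function(i) {
        first <- sample(p$herbs, 1, prob = p$herb_weights)
        extra <- p$herbs[stats::runif(length(p$herbs)) < p$overlap_prob]
        unique(c(first, extra))
      })
    }
    ob <- stats::runif(p$n_tcmsp, p$ob_range[1], p$ob_range[2])
    dl <- stats::runif(p$n_tcmsp, p$dl_range[1], p$dl_range[2])
    if (p$n_hubs > 0) {            # hubs always pass the default screen
      ob[seq_len(p$n_hubs)] <- stats::runif(p$n_hubs, 35, p$ob_range[2])
      dl[seq_len(p$n_hubs)] <- stats::runif(p$n_hubs, 0.25, p$dl_range[2])
    }
    tcmsp_herbs <- draw_herbs(p$n_tcmsp)
    tcmsp <- data.frame(
      herb = unlist(tcmsp_herbs),
      ingredient = rep(tcmsp_ids, lengths(tcmsp_herbs)),
      ob = round(rep(ob, lengths(tcmsp_herbs)), 2),
      dl = round(rep(dl, lengths(tcmsp_herbs)), 3),
      stringsAsFactors = FALSE)
    hit_herbs <- draw_herbs(p$n_hit)
    hit <- data.frame(
      herb = unlist(hit_herbs),
      ingredient = rep(hit_ids, lengths(hit_herbs)),
      ob = "", dl = "", stringsAsFactors = FALSE)

    kept <- tcmsp_ids[ob >= 30 & dl >= 0.18]
    active <- c(kept, hit_ids)

    # predicted (similarity-based) associations for every active ingredient
    pred_rows <- lapply(active, function(ing) {
      size <- 1 + stats::rpois(1, p$fanout_mean - 1)
      genes <- sample(uni, min(size, length(uni)))
      if (ing %in% hub_ids) {
        n_core_hit <- round(p$hub_core_frac * p$n_core)
        genes <- unique(c(sample(core, n_core_hit),
                          sample(uni, min(length(uni),
                                          p$hub_fanout_factor * p$fanout_mean))))
      }
      good <- data.frame(ingredient = ing, gene = genes,
                         similarity = round(stats::runif(length(genes), 1.05, 2), 3),
                         prediction_score = round(stats::runif(length(genes), 0.05, 1), 3),
                         stringsAsFactors = FALSE)
      n_decoy <- stats::rpois(1, p$decoy_mean)
      if (n_decoy == 0) return(good)
      fail_sim <- stats::runif(n_decoy) < 0.5
      decoy <- data.frame(
        ingredient = ing, gene = sample(uni, n_decoy),
        similarity = round(ifelse(fail_sim, stats::runif(n_decoy, 0.2, 1.0),
                                  stats::runif(n_decoy, 1.05, 2)), 3),
        prediction_score = round(ifelse(fail_sim, stats::runif(n_decoy, 0.05, 1),
                                        stats::runif(n_decoy, -0.5, 0)), 3),
        stringsAsFactors = FALSE)
      rbind(good, decoy)
    })
    predicted <- do.call(rbind, pred_rows)
    predicted$evidence <- "predicted"

    # validated associations for the curated ingredients, enriched for core
    val_rows <- lapply(hit_ids, function(ing) {
      size <- 1 + stats::rpois(1, p$fanout_validated - 1)
      from_core <- stats::rbinom(1, size, p$validated_core_frac)
      genes <- unique(c(sample(core, min(from_core, length(core))),
                        sample(uni, size - from_core)))
      data.frame(ingredient = ing, gene = genes, stringsAsFactors = FALSE)
    })
    validated <- do.call(rbind, val_rows)
    validated$evidence <- "validated"
    validated$similarity <- NA_real_
    validated$prediction_score <- NA_real_
    predicted <- predicted[, c("ingredient", "gene", "evidence",
                               "similarity", "prediction_score")]
    validated <- validated[, names(predicted)]

    list(tcmsp = tcmsp, hit = hit,
         validated = validated, predicted = predicted,
         ground_truth = list(planted_hub_ingredients = hub_ids,
                             n_tcmsp_kept_expected = length(kept),
                             seed = seed))
  })
}

#' Generate a synthetic two-group expression matrix with planted DEGs
#'
#' Log2 intensities are a per-gene baseline ~ N(baseline_mean,
#' baseline_sd^2), plus the planted group shift for DEG genes in case
#' samples, plus iid noise N(0, noise_sd^2). A subset of planted DEGs
#' falls in the disease core of the target universe (so they can become
#' candidate targets downstream); the rest are expression-only symbols.
#'
#' @param params From [synth_params()].
#' @param seed Integer seed (independent stream).
#' @return List with `matrix` (an `expression_matrix`) and `ground_truth`
#'   (`planted_degs`: named log2fc vector).
#' @export
gen_expression <- function(params = synth_params(), seed = 1) {
  p <- params
  with_seed(substream_seed(seed, "expression"), {
    core <- core_genes(p)
    deg_pool_core <- setdiff(core, core[seq_len(p$n_curated_core)])
    core_up <- sample(deg_pool_core, p$deg_core_up)
    core_down <- sample(setdiff(deg_pool_core, core_up), p$deg_core_down)
    n_e_up <- p$n_up - p$deg_core_up
    n_e_down <- p$n_down - p$deg_core_down
    e_ids <- sprintf("E%04d", seq_len(max(p$n_genes_expr, n_e_up + n_e_down)))
    e_up <- e_ids[seq_len(n_e_up)]
    e_down <- e_ids[n_e_up + seq_len(n_e_down)]
    up <- c(core_up, e_up); down <- c(core_down, e_down)

    uni <- universe_genes(p)
    panel <- unique(c(core, up, down,
                      sample(setdiff(uni, core),
                             min(length(uni) - p$n_core,
                                 round(p$n_genes_expr / 2) - p$n_core)),
                      e_ids))
    panel <- panel[seq_len(min(length(panel), p$n_genes_expr))]
    # ensure all planted genes survived the truncation
    panel <- unique(c(up, down, panel))[seq_len(p$n_genes_expr)]

    n <- 2 * p$n_per_group
    samples <- c(sprintf("case_%02d", seq_len(p$n_per_group)),
                 sprintf("ctrl_%02d", seq_len(p$n_per_group)))
    group <- rep(c("case", "control"), each = p$n_per_group)
    baseline <- stats::rnorm(length(panel), p$baseline_mean, p$baseline_sd)
    shift <- stats::setNames(numeric(length(panel)), panel)
    shift[up] <- p$planted_log2fc
    shift[down] <- -p$planted_log2fc
    values <- matrix(baseline, nrow = length(panel), ncol = n) +
      outer(shift, as.numeric(group == "case")) +
      matrix(stats::rnorm(length(panel) * n, 0, p$noise_sd),
             nrow = length(panel))
    dimnames(values) <- list(panel, samples)
    list(matrix = expression_matrix(values, group),
         ground_truth = list(planted_degs = shift[shift != 0], seed = seed))
  })
}

#' Generate curated disease-gene lists across five sources
#'
#' Draws `n_curated` distinct disease genes, `n_curated_core` of them from
#' the disease core of the target universe (so they can become candidates)
#' and the rest disease-only symbols, then assigns each gene to one or more
#' of the five source databases.
#'
#' @param params From [synth_params()].
#' @param seed Integer seed (independent stream).
#' @return List with `curated` (named list source -> gene vector) and
#'   `ground_truth`.
#' @export
gen_disease_lists <- function(params = synth_params(), seed = 1) {
  p <- params
  with_seed(substream_seed(seed, "disease"), {
    core <- core_genes(p)
    genes <- c(sample(core, p$n_curated_core),
               sprintf("D%04d", seq_len(p$n_curated - p$n_curated_core)))
    sources <- c("ttd", "drugbank", "kegg", "disgenet", "omim")
    assign_n <- 1 + stats::rbinom(length(genes), 2, p$n_sources_extra_prob)
    memb <- lapply(seq_along(genes), function(i) sample(sources, assign_n[i]))
    curated <- stats::setNames(lapply(sources, function(s)
      sort(genes[vapply(memb, function(m) s %in% m, logical(1))])), sources)
    curated <- curated[lengths(curated) > 0]
    list(curated = curated,
         ground_truth = list(curated_genes = sort(genes), seed = seed))
  })
}

#' Generate the synthetic PPI edge table and annotation gene sets
#'
#' PPI confidence scores follow a two-component Beta mixture: a low mode
#' (Beta(2,6)) for background pairs and a high mode (Beta(14,1.2)) placing
#' substantial mass above the 0.9 confidence cut. Core disease genes get a
#' Poisson number of partners drawn mostly from a dedicated protein pool,
#' plus uniform noise edges. One pathway term and one molecular-function
#' term are planted by over-sampling core genes into their memberships;
#' decoy terms sample the universe uniformly.
#'
#' @param params From [synth_params()].
#' @param seed Integer seed (independent stream).
#' @return List with `edges` (canonical scored edge set), `kegg` and `mf`
#'   (`gene_set_collection`s), and `ground_truth` (planted term ids).
#' @export
gen_ppi_and_genesets <- function(params = synth_params(), seed = 1) {
  p <- params
  with_seed(substream_seed(seed, "ppi"), {
    uni <- universe_genes(p)
    core <- core_genes(p)
    prot <- protein_pool(p)
    rbeta_mix <- function(n) {
      hi <- stats::runif(n) < p$ppi_high_prob
      ifelse(hi, stats::rbeta(n, 14, 1.2), stats::rbeta(n, 2, 6))
    }
    a <- character(); b <- character()
    for (g in core) {
      k <- 1 + stats::rpois(1, p$ppi_core_edges_mean - 1)
      from_pool <- stats::runif(k) < 0.8
      partners <- ifelse(from_pool, sample(prot, k, replace = TRUE),
                         sample(setdiff(uni, g), k, replace = TRUE))
      a <- c(a, rep(g, k)); b <- c(b, partners)
    }
    na <- p$ppi_noise_edges
    pairs <- matrix(sample(uni, 2 * na, replace = TRUE), ncol = 2)
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    a <- c(a, pairs[, 1]); b <- c(b, pairs[, 2])
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    edges <- make_edge_set(a, b, pmin(pmax(rbeta_mix(length(a)), 0), 1))

    sample_term <- function(size, core_n = 0) {
      pool <- c(uni, prot)
      genes <- sample(pool, size)
      if (core_n > 0)
        genes <- unique(c(sample(core, core_n), sample(pool, size - core_n)))
      genes
    }
    kegg <- list()
    for (i in seq_len(p$n_kegg_terms)) {
      id <- sprintf("PATH%03d", i)
      core_n <- if (i == 1) p$planted_kegg_core else 0
      kegg[[id]] <- list(name = if (i == 1) "planted glycation signaling"
                                else sprintf("decoy pathway %d", i),
                         category = "kegg",
                         genes = sample_term(p$kegg_term_size, core_n))
    }
    mf <- list()
    for (i in seq_len(p$n_mf_terms)) {
      id <- sprintf("MF%03d", i)
      core_n <- if (i == 1) p$planted_mf_core else 0
      mf[[id]] <- list(name = if (i == 1) "planted kinase activity"
                              else sprintf("decoy function %d", i),
                       category = "molecular_function",
                       genes = sample_term(p$mf_term_size, core_n))
    }
    list(edges = edges,
         kegg = structure(kegg, class = "gene_set_collection"),
         mf = structure(mf, class = "gene_set_collection"),
         ground_truth = list(planted_enriched_terms = c("PATH001", "MF001"),
                             seed = seed))
  })
}

#' Generate every pipeline input, optionally writing them to disk
#'
#' Runs all four generators under independent substreams of one seed and,
#' when `out_dir` is given, writes the TSV/GMT inputs plus a
#' `ground_truth.json` manifest so a run is fully reproducible from disk.
#'
#' @param params From [synth_params()].
#' @param seed Integer master seed.
#' @param out_dir Optional output directory (created if missing).
#' @return List with all generated objects and a merged `ground_truth`.
#' @export
gen_all <- function(params = synth_params(), seed = 1, out_dir = NULL) {
  kb <- gen_knowledgebase(params, seed)
  ex <- gen_expression(params, seed)
  dz <- gen_disease_lists(params, seed)
  pg <- gen_ppi_and_genesets(params, seed)
  gt <- list(seed = seed,
             planted_hub_ingredients = kb$ground_truth$planted_hub_ingredients,
             planted_degs = as.list(ex$ground_truth$planted_degs),
             planted_enriched_terms = pg$ground_truth$planted_enriched_terms,
             curated_genes = dz$ground_truth$curated_genes,
             params = params)
  out <- list(knowledgebase = kb, expression = ex, disease = dz, ppi = pg,
              ground_truth = gt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    utils::write.table(kb$tcmsp, fp("tcmsp_ingredients.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(kb$hit, fp("hit_ingredients.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(kb$validated[, c("ingredient", "gene")],
                       fp("validated_targets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(kb$predicted[, c("ingredient", "gene", "similarity",
                                        "prediction_score")],
                       fp("predicted_targets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_expression_matrix(ex$matrix, fp("expression.tsv"), fp("groups.tsv"))
    for (s in names(dz$curated))
      writeLines(dz$curated[[s]], fp(paste0("disease_", s, ".txt")))
    utils::write.table(pg$edges, fp("ppi_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gmt(pg$kegg, fp("pathways.gmt"))
    write_gmt(pg$mf, fp("molecular_functions.gmt"))
    jsonlite::write_json(gt, fp("ground_truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  out
}
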