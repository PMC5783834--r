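# End-to-end orchestration: synthetic data -> probe re-annotation ->
# differential expression -> subpathway mining -> network assembly -> RWR
# prioritization -> key module -> ceRNA calling, with a machine-readable
# run report.

#' Pipeline configuration
#'
#' Bundles the synthetic-study configuration with every stage parameter.
#' Interface outputs are written as TSV/JSON when `out_dir` is given; with
#' `resume = TRUE` a stage whose cached result exists under `out_dir/cache`
#' is loaded instead of recomputed.
#'
#' @param synth a [synth_config()]
#' @param k,min_subpathway_size,alpha_subpathway subpathway mining/enrichment
#'   parameters
#' @param fc_threshold,p_threshold,sam_B differential-expression parameters
#' @param r_threshold co-expression calling threshold
#' @param rwr_r,epsilon,n_perm,alpha_rwr,top_n RWR parameters
#' @param n_randomizations degree-randomization iterations (0 skips the test)
#' @param n_submodules submodules for the bidirectional clustering
#' @param min_score,max_energy ceRNA binding filters
#' @param out_dir optional output directory
#' @param resume reuse cached stage results under `out_dir`
#' @param seed seed for the analysis-side randomness (permutations,
#'   randomizations); the generator uses `synth$rng_seed`
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(synth = synth_config(), k = 4,
                            min_subpathway_size = 3L, alpha_subpathway = 0.05,
                            fc_threshold = 2, p_threshold = 0.05, sam_B = 1000,
                            r_threshold = 0.8, rwr_r = 0.7, epsilon = 1e-10,
                            n_perm = 1000, alpha_rwr = 0.05, top_n = 20,
                            n_randomizations = 0, n_submodules = 4L,
                            min_score = 160, max_energy = -20,
                            out_dir = NULL, resume = FALSE, seed = 1L) {
  structure(list(
    synth = synth, k = k, min_subpathway_size = min_subpathway_size,
    alpha_subpathway = check_fraction(alpha_subpathway, "alpha_subpathway", open = TRUE),
    fc_threshold = fc_threshold,
    p_threshold = check_fraction(p_threshold, "p_threshold", open = TRUE),
    sam_B = check_count(sam_B, "sam_B"),
    r_threshold = check_fraction(r_threshold, "r_threshold", open = TRUE),
    rwr_r = check_fraction(rwr_r, "rwr_r", open = TRUE),
    epsilon = epsilon, n_perm = check_count(n_perm, "n_perm"),
    alpha_rwr = check_fraction(alpha_rwr, "alpha_rwr", open = TRUE),
    top_n = check_count(top_n, "top_n"),
    n_randomizations = check_count(n_randomizations, "n_randomizations", min = 0L),
    n_submodules = check_count(n_submodules, "n_submodules"),
    min_score = min_score, max_energy = max_energy,
    out_dir = out_dir, resume = isTRUE(resume),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "pipeline_config")
}

# Run one named stage, using the rds cache under out_dir/cache when resuming.
run_stage <- function(name, cfg, compute) {
  if (!is.null(cfg$out_dir)) {
    cache_dir <- file.path(cfg$out_dir, "cache")
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    cache <- file.path(cache_dir, paste0(name, ".rds"))
    if (cfg$resume && file.exists(cache)) return(readRDS(cache))
    res <- compute()
    saveRDS(res, cache)
    return(res)
  }
  compute()
}

#' Run the complete analysis pipeline on a synthetic study
#'
#' Executes generation, probe re-annotation, differential expression,
#' subpathway mining and fusion, heterogeneous-network assembly, RWR
#' prioritization with permutation significance, key-module extraction with
#' bidirectional clustering, and ceRNA calling. Two runs with an identical
#' configuration produce identical reports.
#'
#' @param cfg a [pipeline_config()]
#' @return a `pipeline_result` list with every stage's result and a `report`
#'   list of counts, parameters and planted-truth recovery metrics
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  data <- run_stage("synth", cfg, function() synth_dataset(cfg$synth))

  reann <- run_stage("reannotation", cfg, function() filter_probes(data$probes))
  expr <- run_stage("expression", cfg, function() {
    collapse_to_features(data$probe_expression, reann) |> log2_transform()
  })

  de <- run_stage("diffexpr", cfg, function() {
    sam_de(expr, data$phenotype, B = cfg$sam_B, seed = derive_seed(cfg$seed, 10L),
           fc_threshold = cfg$fc_threshold, p_threshold = cfg$p_threshold)
  })
  de_pcgs <- de$feature_id[de$is_de & de$biotype == "pcg"]
  de_lncs <- de$feature_id[de$is_de & de$biotype == "lncrna"]

  subp <- run_stage("subpathway", cfg, function() {
    find_subpathways(data$pathways, de_pcgs, k = cfg$k,
                     min_size = cfg$min_subpathway_size)
  })
  sig_subp <- select_significant(subp, alpha = cfg$alpha_subpathway)
  fused <- fuse_subpathways(sig_subp)

  pairs <- run_stage("coexpression", cfg, function() {
    coexpression_pairs(expr, de_pcgs, de_lncs, r_threshold = cfg$r_threshold)
  })
  seeds_in <- intersect(data$truth$seed_genes, igraph::V(fused)$name)
  net <- assemble_chlpn(fused, pairs, seeds = data$truth$seed_genes)

  rand_test <- NULL
  if (cfg$n_randomizations > 0) {
    rand_test <- run_stage("randomization", cfg, function() {
      randomization_degree_test(expr, fused, de_pcgs, de_lncs,
                                n_iter = cfg$n_randomizations,
                                r_threshold = cfg$r_threshold,
                                seed = derive_seed(cfg$seed, 20L))
    })
  }
  pl_fit <- tryCatch(powerlaw_fit(net), error = function(e) NULL)

  rwr <- run_stage("rwr", cfg, function() {
    permutation_significance(net, seeds_in, n_perm = cfg$n_perm, r = cfg$rwr_r,
                             epsilon = cfg$epsilon,
                             seed = derive_seed(cfg$seed, 30L))
  })
  selected <- rank_and_select(rwr, alpha = cfg$alpha_rwr, top_n = cfg$top_n)
  sep <- score_separation_test(rwr, alpha = cfg$alpha_rwr)

  module <- NULL
  submodules <- NULL
  if (length(selected) > 0) {
    module <- extract_module(net, selected, seeds = data$truth$seed_genes)
    feats <- c(module$lncrnas, module$pcgs)
    if (length(feats) >= cfg$n_submodules) {
      submodules <- bicluster(expr, feats, n_submodules = cfg$n_submodules)
    }
  }

  cerna <- run_stage("cerna", cfg, function() {
    shared_mirna_pairs(
      filter_bindings(data$mirna$lncrna, cfg$min_score, cfg$max_energy),
      filter_bindings(data$mirna$gene, cfg$min_score, cfg$max_energy),
      expr, r_threshold = cfg$r_threshold
    )
  })

  truth <- data$truth
  risk <- truth$planted_risk_lncrnas
  report <- list(
    parameters = cfg[setdiff(names(cfg), c("synth", "out_dir", "resume"))],
    synth_parameters = unclass(cfg$synth),
    counts = list(
      n_features_kept = nrow(reann$features_kept),
      n_de_pcg = length(de_pcgs),
      n_de_lncrna = length(de_lncs),
      n_subpathways = nrow(subp),
      n_significant_subpathways = nrow(sig_subp),
      n_network_pcg = sum(igraph::V(net)$type == "pcg"),
      n_network_lncrna = sum(igraph::V(net)$type == "lncrna"),
      n_network_edges = igraph::ecount(net),
      n_seeds_in_network = length(seeds_in),
      n_significant_lncrna = sum(rwr$lncrna$p_emp < cfg$alpha_rwr),
      n_selected_lncrna = length(selected),
      n_module_pcg = if (is.null(module)) 0L else length(module$pcgs),
      n_cerna_pairs = sum(cerna$passes)
    ),
    statistics = list(
      powerlaw_slope = if (is.null(pl_fit)) NA_real_ else pl_fit$slope,
      powerlaw_r_squared = if (is.null(pl_fit)) NA_real_ else pl_fit$r_squared,
      score_separation_p = sep$p_value,
      module_avg_degree = if (is.null(module)) NA_real_ else module$avg_degree_module,
      rest_avg_degree = if (is.null(module)) NA_real_ else module$avg_degree_rest,
      module_degree_p = if (is.null(module)) NA_real_ else module$p_degree,
      randomization_p_pcg = if (is.null(rand_test)) NA_real_ else rand_test$p_pcg,
      randomization_p_lnc = if (is.null(rand_test)) NA_real_ else rand_test$p_lnc
    ),
    truth_recovery = list(
      de_pcg_recall = mean(truth$planted_de_pcgs %in% de_pcgs),
      de_lncrna_recall = mean(truth$planted_de_lncrnas %in% de_lncs),
      risk_lncrna_in_network = mean(risk %in% igraph::V(net)$name),
      risk_lncrna_selected = mean(risk %in% selected),
      cerna_pair_recall = mean(paste(truth$planted_cerna_pairs$lncrna_id,
                                     truth$planted_cerna_pairs$gene_id) %in%
                                 paste(cerna$lncrna_id[cerna$passes],
                                       cerna$gene_id[cerna$passes]))
    )
  )

  result <- structure(list(
    data = data, reannotation = reann, expression = expr, de = de,
    subpathways = subp, significant_subpathways = sig_subp, fused = fused,
    coexpression = pairs, network = net, powerlaw = pl_fit,
    randomization = rand_test, rwr = rwr, selected_lncrnas = selected,
    module = module, submodules = submodules, cerna = cerna, report = report
  ), class = "pipeline_result")

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg$out_dir)
  result
}

# Write the interface TSV/JSON outputs of a pipeline run.
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$reannotation$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(result$reannotation$report, file.path(dir, "filter_report.tsv"))
  write_expression_tsv(result$expression, file.path(dir, "expression_features.tsv"))
  readr::write_tsv(result$de, file.path(dir, "de_table.tsv"))
  subp_flat <- result$subpathways |>
    mutate(genes = purrr::map_chr(.data$members, paste, collapse = ";")) |>
    select("pathway_id", "subpathway_id", "genes", "size", "de_overlap", "p_hyper")
  readr::write_tsv(subp_flat, file.path(dir, "subpathways.tsv"))
  write_network_tsv(result$network, file.path(dir, "chlpn_edges.tsv"),
                    file.path(dir, "chlpn_nodes.tsv"))
  readr::write_tsv(tidy(result$rwr), file.path(dir, "rwr_ranking.tsv"))
  if (!is.null(result$module)) {
    readr::write_tsv(tidy(result$module), file.path(dir, "module_nodes.tsv"))
    readr::write_tsv(result$module$induced_edges, file.path(dir, "module_edges.tsv"))
  }
  if (!is.null(result$submodules)) {
    readr::write_tsv(tidy(result$submodules), file.path(dir, "submodules.tsv"))
  }
  readr::write_tsv(result$cerna, file.path(dir, "cerna_pairs.tsv"))
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(dir)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks that every field required by `inst/extdata/report-schema.json` is
#' present with the declared type.
#'
#' @param report the `report` element of a `pipeline_result` (or the parsed
#'   `report.json`)
#' @return `TRUE` invisibly; errors describe the first violation
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "lncwalk"))
  for (section in names(schema$required)) {
    if (is.null(report[[section]])) abort(sprintf("report missing section '%s'", section))
    for (field in unlist(schema$required[[section]])) {
      val <- report[[section]][[field]]
      if (is.null(val)) {
        abort(sprintf("report section '%s' missing field '%s'", section, field))
      }
      if (!is.na(val) && !is.numeric(val) && !is.logical(val)) {
        abort(sprintf("report field '%s/%s' must be numeric", section, field))
      }
    }
  }
  invisible(TRUE)
}
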